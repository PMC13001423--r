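# Published in-distribution benchmark results (%) for sequence-based
# protein-ligand binding predictors: binary prediction and binding-site
# localization (Binding Residue Hit Rate at K). Means over 5-fold CV.
model	acc	auprc	auroc	f1	brhr1	brhr3	brhr5
MolTrans	88.6	93.7	95.1	88.1	10.9	17.7	22.4
TransformerCPI	89.1	90.8	95.4	88.5	10.9	16.7	21.7
HyperAttentionDTI	84.1	92.8	95.5	88.5	12.3	17.7	20.8
PerceiverCPI	86.6	92.6	96.9	82.2	10.6	13.9	19.9
CAT-DTI	88.1	92.5	96.8	87.0	12.2	14.8	22.1
DrugBAN	89.3	94.3	97.6	87.5	15.7	23.9	31.4
GraphBAN	88.9	94.4	97.8	88.5	16.1	22.9	30.4
interaction-supervised	91.2	95.4	99.3	90.5	55.6	69.5	74.6
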
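# crossbind

Sequence-based protein–ligand binding prediction that explains itself:
`crossbind` couples a rule-based geometric annotator of non-covalent
interactions with a cross-attention model whose attention heads are
*supervised by physical interaction maps*, so the model jointly predicts

1. **whether** a protein and a ligand bind (a probability `p`),
2. **where** they bind (binding-site residues), and
3. **how** they bind (per-type residue–atom interaction maps).

It is aimed at computational chemists and structural bioinformaticians who
want mechanistically interpretable binding predictions from sequence alone,
plus the machinery to build the training labels from 3D complexes.

## The model

**Annotation (ground truth construction).** Given a complex structure
(PDB/mmCIF), the binding pocket is the set of residues within a radius
(default 10 Å) of any ligand heavy atom. Six non-covalent interaction
classes — hydrogen bonds, salt bridges, van der Waals, hydrophobic
contacts, π-π stacking and cation-π — are detected by type-specific
distance windows and optional angular filters. A contact at distance `d`
inside its window `[d_min, d_cut]` gets strength

```
A_raw(d) = 1                          for d <= d_min
         = linear from 1 to 1e-6      on  [d_min, d_cut]
         = 0 (no contact)             for d > d_cut
```

yielding, per type `t`, an `m x n` map `A^(t)` over `m` ligand heavy atoms
and `n` protein residues. The per-type maps aggregate element-wise (max)
into an overall map whose nonzero columns define the residue-level
binding-site labels. Binding labels come from affinity stratification:
affinity ≤ −7 kcal/mol is positive, ≥ −5 kcal/mol negative, moderate
affinities are excluded.

**Prediction.** Frozen encoders embed the protein (residue tokens,
`P ∈ R^{n×h}`) and ligand (atom tokens, `D ∈ R^{m×h}`). An interaction
module with `H = 8` attention heads — six tied to the interaction types,
two capturing overall binding — computes bidirectional cross-attention

```
Â_pd^(t) = softmax(Q_p^(t) K_d^(t)ᵀ / sqrt(h_t)),   Â_dp^(t) = softmax(Q_d^(t) K_p^(t)ᵀ / sqrt(h_t))
```

together with per-head self-attention; fused tokens
`P*^(t) = ½(P_sa^(t) + Â_pd^(t) V_d^(t))` (and symmetrically for the
ligand) are concatenated, projected, mean-pooled and classified by a small
MLP. Training minimizes

```
L = (1 − λ) · BCE(p, y) + λ · L_att,      λ = 0.3 by default
```

where `L_att` is a weighted KL divergence aligning each supervised head's
attention (globally renormalized over residue–atom cells) with the
corresponding normalized ground-truth map, each cell weighted by
`log(1 + A_raw)`. Pairs without interaction annotations fall back to the
classification loss alone.

**Evaluation.** Besides Acc/AUROC/AUPRC/F1, the package implements
BRHR@K (fraction of pairs whose Top-K ranked residues hit a true binding
residue), IHR@K (Top-K residue–atom cells hitting a true contact of a
type), and similarity-controlled split construction along the protein axis
(Needleman–Wunsch global identity) or ligand axis (Tanimoto over ECFP),
with a post-hoc audit that no train–test pair exceeds the threshold.

## Worked example

Build a toy complex with three planted contacts, annotate it, and look at
the maps:

```r
library(crossbind)

spec <- synthetic_complex_spec(
  n = 12, m = 12,
  contacts = data.frame(
    type = c("hbond", "salt_bridge", "pipi"),
    i    = c(1, 2, 6),      # ligand atom indices (pipi plants a 6-ring at 6..11)
    j    = c(2, 5, 9),      # protein residue positions
    dist = c(3.0, 4.5, 4.0)),
  seed = 7)
mc  <- make_complex(spec)
ann <- annotate_complex(mc$cx)
ann
#> interaction_maps: m = 12 ligand atoms x n = 12 residues
#>   hbond        1 contacts
#>   salt_bridge  1 contacts
#>   vdw          0 contacts
#>   hydrophobic  0 contacts
#>   pipi         1 contacts
#>   cation_pi    0 contacts
#>   binding residues: 3
ann$contacts
#>          type i j   d angle  strength
#> 1       hbond 1 2 3.0    NA 0.5000005
#> 2 salt_bridge 2 5 4.5    NA 0.4000006
#> 3        pipi 6 9 4.0     0 0.7500003
```

The hydrogen bond planted at 3.0 Å sits halfway through its 2.5–3.5 Å
window, so its strength is the linear midpoint `(1 + 1e-6)/2 ≈ 0.5`; the
π-stack at 4.0 Å in a 3.5–5.5 Å window decays to 0.75. Exactly the three
planted residues (2, 5, 9) are labeled as binding site:

```r
localize_pocket(mc$cx, 10)
#> [1] 2 5 9
```

Similarity utilities used for split construction:

```r
protein_similarity("AGWV", "AGYV")       # NW identity, match 1/mismatch 0/gap -1
#> [1] 75
ligand_similarity("CCO", "c1ccccc1")     # Tanimoto over 2048-bit radius-2 ECFP
#> [1] 0
```

Training on a synthetic planted-contact corpus (see
`?recovery_experiment` for the full supervised-vs-unsupervised
comparison):

```r
ds  <- make_dataset(sample_pair_specs(100, n = 30, m = 8, seed = 1), seed = 1)
fit <- train(ds, model_config(h = 64, lambda = 0.3, epochs = 250, lr = 1e-2))
pr  <- predict_pair(fit, ds[[1]]$P, ds[[1]]$D)
pr$p                        # binding probability
pr$sites$residue_scores     # per-residue binding-site scores
pr$sites$type_maps$hbond    # predicted m x n hydrogen-bond map
```

A command-line interface wrapping the same functions is installed at
`inst/scripts/crossbind` with subcommands `annotate`, `synth`, `train`,
`predict`, `evaluate` and `split`; every run writes a resolved-config
snapshot next to its outputs.

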
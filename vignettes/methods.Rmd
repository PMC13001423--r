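---
title: "Methods: interaction-supervised attention for protein-ligand binding"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: interaction-supervised attention for protein-ligand binding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crossbind)
```

# Overview

`crossbind` has two halves that meet in the loss function. The
*annotation* half turns a 3D protein–ligand complex into six
interaction-type-specific residue–atom strength maps plus residue-level
binding-site labels. The *model* half is a cross-attention network over
frozen sequence embeddings whose attention heads are trained to reproduce
those physical maps while a classifier head predicts binding. This
vignette documents the assumptions, the tunable constants, the numerical
choices, and what the synthetic test bed does and does not demonstrate.

# The annotation engine

## Chemistry perception

The input is a plain coordinate file, so chemistry is perceived from atom
names, elements and geometry, not from bond orders:

* **Hydrogen bonds** pair ligand N/O atoms with protein N/O atoms at
  donor–acceptor distance 2.5–3.5 Å. When hydrogens are present (within
  1.25 Å of a heavy atom), at least one D–H...A angle must reach 120°;
  structures without hydrogens — the common case for X-ray models — use
  the distance-only fallback.
* **Salt bridges** pair ligand nitrogens (treated as cation candidates)
  or oxygens (anion candidates) with oppositely charged residue group
  centroids (ARG/LYS/HIS positive, ASP/GLU negative) at 3.0–5.5 Å.
  Treating HIS as charged is a deliberate, permissive choice; it can be
  removed by editing the group table. Ligand charge perception from
  elements alone is crude, and callers with real protonation knowledge
  can pass explicit atom lists.
* **Hydrophobic contacts**: ligand carbon to side-chain carbon,
  3.3–4.0 Å.
* **van der Waals**: any heavy-atom pair within the sum of vdW radii
  ± 0.5 Å.
* **π-π stacking**: ring-centroid distance 3.5–5.5 Å with interplanar
  angle ≤ 30° (parallel) or 60–90° (T-shaped). Protein rings come from
  residue-name templates (PHE/TYR/TRP/HIS); ligand rings are detected as
  planar 5/6-cycles of C/N atoms on a distance-derived bond graph (bond
  cutoff 1.75 Å, out-of-plane tolerance 0.15 Å).
* **cation-π**: cation to ring centroid 3.5–6.0 Å, in both directions
  (ligand cation to protein ring, protein cation group to ligand ring).

All constants live in a `rule_config` object, are logged with every CLI
output, and are the package's own defaults in the tradition of geometric
interaction profilers; they are not claimed to reproduce any specific
published pipeline's supplementary values.

## Strength decay and map assembly

Distances map to strengths by a piecewise-linear decay: 1 at or below
`d_min`, descending to the floor `1e-6` exactly at `d_cut`, and 0 beyond.
Placing the strong endpoint at the short-distance end encodes "closer
contacts are stronger"; the nonzero floor keeps "weak contact" distinct
from "no contact", so every map entry is either 0 or in `[1e-6, 1]`.

Ring-mediated contacts are attributed to the ligand ring atom nearest the
partner centroid, ties broken toward the lower atom index. One contact
per (atom, residue, type) is kept, at the minimum realizing distance.

Two precedence rules make the construction unambiguous
(specific-over-generic, in the spirit of established profilers):

* a van der Waals contact is suppressed at any (i, j) cell that already
  carries a specific type — nearly every polar or apolar contact also
  satisfies the generic vdW window, and double-counting it would be
  noise, not signal;
* hydrophobic contacts are suppressed at cells covered by a ring-mediated
  interaction, extended to *all* atoms of the participating ligand ring —
  a stacked aromatic ring otherwise re-registers as a ring of spurious
  carbon–carbon contacts.

Per-type maps aggregate into the overall map by element-wise maximum.
Maximum (rather than sum) preserves the `[1e-6, 1]` range invariant and
reads as "strength of the strongest force acting on this pair"; a
sum-then-clip variant is available behind the `aggregation` config key.
Binding-site labels are the columns of the overall map with any nonzero
entry.

## Structure handling

Parsing is delegated to `bio3d` (PDB and mmCIF). Alternate locations keep
the highest-occupancy conformer (ties broken by altloc identifier).
Ligand candidacy excludes waters, a configurable blocklist of ions,
buffers and glycan units, and requires `auto` selection to be unambiguous.
Multi-chain proteins are concatenated in chain order into one token
sequence — the model consumes a single sequence — with chain boundaries
recorded in the index map. Ligand "units" are heavy atoms (not line-
notation tokens): heavy atoms are what the geometric annotation is
defined on, and the choice is recorded here because the map dimension `m`
depends on it.

# The interaction model

## Architecture

Frozen encoders produce `P (n x h)` and `D (m x h)`. Full-width
projections `W_q, W_k, W_v (h x h)` per modality are sliced into `H = 8`
heads of width `h_t = h/8` (the standard multi-head convention). Each
head computes bidirectional cross-attention and per-modality
self-attention with `1/sqrt(h_t)` scaling; fused tokens are the average
of the self-attended tokens and the cross-attended partner values, halved
to keep magnitudes comparable. Heads concatenate and project through
`W_po, W_do (h x d)`; the fused dimension `d` defaults to `h` (the value
is not architecturally constrained; keeping it at `h` avoids an arbitrary
bottleneck). Mean-pooled ligand and protein vectors concatenate to the
pair vector `F (2d)`, classified by a two-hidden-layer ReLU MLP with a
sigmoid output (widths 64/32 by default — a deliberately lightweight
head).

## Supervision

Six heads are tied, in order, to hydrogen bonds, salt bridges, van der
Waals, hydrophobic, π-π and cation-π; two further heads capture overall
binding. The alignment loss for a supervised head is a weighted KL
divergence between the ground-truth map and the predicted attention,
both renormalized *globally* over all residue–atom cells to discrete
distributions, with cell weights `log(1 + A_raw)` emphasizing strong
contacts. Natural logarithms are used throughout. Three choices here were
genuinely open and are resolved as follows:

* **Direction.** Attention is row-stochastic, so the two directions carry
  different information. The loss is applied symmetrically to the
  ligand-to-protein attention `A_dp` and the transposed
  protein-to-ligand attention `A_pd`, averaged — avoiding an arbitrary
  direction bias.
* **Overall heads.** Both overall heads are supervised by the overall
  map by default (`supervise_overall = FALSE` restores typed-only
  supervision). Supervising them gives the residue-score pathway, which
  reads the overall heads, a direct training signal.
* **Normalization floor.** Predicted distributions are clamped at
  `1e-12` before logarithms; ground-truth zero cells contribute exactly
  zero (`0 · log 0 := 0`).

Supervised heads whose ground-truth map is all zero are skipped (with a
warning); pairs with no interaction annotation at all train on the
classification loss alone. The combined objective is the convex
combination `(1 − λ) L_cls + λ L_att` with `λ = 0.3` by default.

## Optimization and determinism

Training is minibatch Adam (default lr 2e-3 for generic use; the recovery
experiment uses lr 1e-2 for 250 epochs, batch size 10) on the interaction-module
projections, output projections and MLP head only — encoder outputs are
inputs, never parameters, which is what "frozen" means operationally
here. Gradients are analytic (hand-derived backpropagation through the
softmax attention, fusion, pooling, MLP and both loss terms) and are
verified against central finite differences in the test suite at relative
tolerance 1e-4. All randomness (initialization, batch shuffling, corpus
generation) flows from explicit seeds through a restore-on-exit RNG
helper, so a training run is bit-reproducible and does not perturb the
caller's RNG stream.

Degenerate inputs: single-token sequences give `[[1]]` attention;
empty sequences and mismatched hidden dimensions raise errors; `λ`
outside `[0, 1]` is a configuration error.

## Site and type read-out

Per-type predicted maps are the `A_dp` matrices of the typed heads. The
residue score of position `j` is the maximum over ligand atoms of the
mean of the two overall heads' `A_dp`; ranking ties break toward the
lower residue index (determinism). BRHR@K and IHR@K then measure Top-K
hits against the labels; both are monotone non-decreasing in K by
construction.

# Similarity-controlled evaluation

Ligand similarity is Tanimoto over radius-2, 2048-bit
extended-connectivity fingerprints. The Morgan relabelling loop is
implemented in the package on ChemmineR/OpenBabel-parsed graphs (initial
invariants: atomic number, heavy degree, total bond order, formal charge,
ring membership); it follows the standard construction but its bit
positions are not interchangeable with any other toolkit's — fingerprints
must be compared within the package, which is all that split construction
requires. Protein similarity is Needleman–Wunsch global identity
(Biostrings; match 1, mismatch 0, linear gap −1, identity = identical
columns / alignment length, in percent), the gap penalty chosen as the
smallest integer penalty that makes gaps non-free.

Splits cluster entities connected by similarity strictly above the
threshold (connected components = single linkage at the threshold) and
assign clusters whole, so a full pairwise audit of train-vs-test
similarity can never exceed the threshold; the audit is still run and
reported because it is cheap and catches regressions. The realized peak
and mean cross similarities are both recorded — protein-axis results are
conventionally summarized by peak, ligand-axis by mean. An infeasible
threshold (everything in one cluster) is an error naming the blocking
cluster, not a silent degenerate split. In-distribution evaluation uses
stratified random 5-folds.

# The synthetic test bed

## Geometry

`make_complex()` realizes planted contacts as toy geometry: residues are
small name-correct templates (SER for hydrogen bonds, ASP for salt
bridges, LEU for hydrophobic, GLY backbone oxygen for vdW, PHE for the
two aromatic types, ALA filler) on a 15 Å lattice — far beyond every
detection window — with the partner ligand atom placed on the outward
normal at the exact target distance, and a benzene-like hexagon for
π-stacks offset 0.35 Å so the designated ring atom is strictly nearest.
Because of the lattice spacing and the precedence rules, annotating the
emitted structure recovers exactly the planted contact list, with
strengths equal to the decayed target distances to 1e-6 — a closed-loop
property the test suite exercises per type and against an independent
brute-force scan.

## Embedding corpora and what they show

`make_dataset()` builds training pairs without geometry: maps come
analytically from the planted distances, and token embeddings from the
deterministic hash encoder (each (token, position) maps to a reproducible
unit vector — a stand-in exercising the pluggable-encoder interface, not
a pretrained model). For every planted contact a fresh seeded unit
direction is added (strength β = 1.5) to both partner embeddings,
followed by Gaussian noise (σ = 0.1): interacting tokens share a latent
direction the attention can learn to detect, because a bilinear form
close to the identity makes correlated tokens attend to each other — and
that generalizes to held-out pairs with fresh directions.

The recovery experiment trains on 100 pairs (balanced labels, 1–3
contacts per positive — matching the "fewer than three annotated contacts
on average" sparsity of real annotation — n = 30 residues, m = 8 ligand
atoms, h = 64) and evaluates BRHR@1 on 40 held-out positives against the
uniform-random baseline `n_true_residues / n`, comparing λ = 0.3 with a
λ = 0 run from the same initialization. These sizes keep the full
experiment deterministic and a few minutes long; they are scaled-down
study conditions, not the benchmark scale of real corpora.

What passing shows: the supervised objective, gradients, and read-out are
wired correctly end-to-end, and attention supervision — not binding
labels — is what localizes interactions. What it does not show: that the
model reaches any particular accuracy on real proteins and ligands, where
frozen embeddings are not contact-informed by construction, sequences are
an order of magnitude longer, and contact chemistry is not separable by a
single latent direction. The synthetic corpus also has no similarity
structure, so it says nothing about out-of-distribution generalization.

# Known limitations

* Chemistry perception is name/element-based: no protonation states, no
  formal-charge perception beyond the file's annotations, no halogen
  bonds, water bridges or metal coordination.
* SELFIES strings are carried as opaque annotations; the implemented
  ligand line-notation pathway is SMILES.
* The in-package ECFP is internally consistent but not bit-compatible
  with other toolkits.
* No pretrained encoder weights ship with the package; the encoder
  registry is the integration point for real embedding models.
* Benchmark-scale training (hundreds of residues, GPU-scale corpora) is
  out of scope for the plain-R implementation; the design target is
  correctness and auditability at test scale.
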
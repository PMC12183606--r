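---
title: "Interaction graphs and hybrid affinity prediction: methods"
author: "plaig"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Interaction graphs and hybrid affinity prediction: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plaig)
```

## The problem

Given a protein and a ligand docked into its binding site, we want the
binding affinity as pKd/pKi = −log10(Kd/Ki in molar); higher means tighter
binding. The affinity is governed both by the specific chemical contacts
across the interface — hydrogen bonds, salt bridges, aromatic stacking,
hydrophobic packing, metal coordination — and by how well the two shapes
fit. plaig therefore represents a docked complex as a graph whose nodes are
atoms, whose edges are either ligand covalent bonds or geometric
protein–ligand contacts annotated with the contact types and Coulomb
energies, and which carries two global physicochemical summaries (ligand
and pocket). A hybrid regressor — an edge-conditioned message-passing
network followed by a stacking ensemble on its graph-level embeddings —
maps the graph to an affinity.

## From files to a pocket

`parse_protein_pdb()` reads fixed-column PDB (model 1 only, waters removed,
alternate locations resolved to the highest-occupancy copy, first on ties;
insertion codes are ignored with a message). `parse_ligand()` reads MOL2
(bonds and SYBYL types from the file), PDBQT (partial charges from the
charge column; torsion-tree records are ignored — only coordinates and
charges are consumed) or plain PDB. For formats without a bond block, bonds
are perceived with a deterministic rule: two atoms bond when their distance
is at most 1.3 × the sum of their covalent radii (and above a 0.4 Å clash
floor). The factor 1.3 is the usual tolerance for idealized and
slightly distorted geometries; the radii table ships with the package.

`extract_pocket()` keeps every residue with at least one atom within 10 Å
of any ligand atom — residues are kept whole, never split, and metal ions
and cofactors count as single-atom residues. Distances include hydrogens
when present (`heavy_only = TRUE` flips this; the convention in the
literature is often unstated, so both are exposed).

Partial charges are Gasteiger PEOE: charges seeded from formal charges and
iteratively equalized along bonds with damping 0.5^n for six iterations,
using the standard electronegativity coefficients per element and
hybridization. The transfer is antisymmetric, so the total molecular charge
is conserved exactly; elements outside the coefficient table (noble gases,
metal ions) keep charge 0 with a warning. Pocket-side aromaticity,
hybridization and formal charges come from residue templates (Phe/Tyr/
Trp/His rings; Lys/Arg positive and Asp/Glu negative side-chain groups;
divalent/monovalent metal ions), the standard approach for structures
without explicit chemistry records.

## Interaction detection

Nine contact categories are detected between the pocket and the ligand.
The generic contact cutoff (3 Å by default — the sweet spot in the 2–5 Å
range between capturing genuine polar contacts and keeping the graphs
sparse) bounds close-contact creation and the hydrogen-bond
donor–acceptor distance; every other
category carries its own cap, all packaged as an editable rule table
(`interaction_rules()`, `inst/extdata/interaction_rules.json`):

| category | rule |
|---|---|
| close_contact | any ligand–pocket pair ≤ cutoff |
| hydrogen_bond | donor N/O/S with ≥1 explicit H, acceptor N/O, D···A ≤ cutoff, D–H···A ≥ 140° |
| halogen_bond | ligand F/Cl/Br/I (bonded to C) to pocket O/N/S, ≤ cutoff, C–X···A ≥ 140° |
| hydrophobic | C···C ≤ 4.0 Å, both carbons bonded only to C/H/halogen |
| metal | ligand N/O/S to pocket metal ion ≤ 3.5 Å |
| salt_bridge | formally positive group atom to negative group atom ≤ 5.5 Å |
| cation_pi | cation to aromatic ring centroid ≤ 6.0 Å |
| pi_pi | ring centroids ≤ 7.2 Å, acute inter-normal angle ≤ 30° |
| t_stack | ring centroids ≤ 5.0 Å, inter-normal angle 60–120° |

Every contact stores the Coulomb energy 332.06·q1·q2/r kcal/mol (dielectric
1) of its atom pair. For ring-mediated categories the stored pair is the
closest (ligand member, pocket member) pair — ties broken deterministically
by lowest ligand then pocket index — and the stored distance is the
criterion distance (centroid–centroid or cation–centroid). Explicit
hydrogens are required for donors: protonation is upstream preparation, not
something this package invents. Metal ions are excluded from the cation-π
cation side, since metal coordination is its own category.

The detector is deliberately rule-table-driven so that a brute-force
re-implementation (all atom pairs, all ring pairs, plain loops) can be held
against it; the test suite does exactly that on dozens of randomized
fixtures and requires exact set equality.

## Features and the complex graph

The feature schema is frozen (`feature_schema()`): 40 node features
(atomic number; 22-way residue one-hot — 20 amino acids, OTHER, LIG; 8-way
hybridization one-hot; degree; aromaticity; hydrogen count; mass; formal
charge; Gasteiger charge; raw xyz), 11 edge features (electrostatic energy;
8 interaction flags; bond type, 0 for a protein–ligand contact edge and
1/2/3/4 for single/double/triple/aromatic ligand bonds; distance), 88
global ligand descriptors and 74 global pocket descriptors (composition,
charge statistics and histograms, hydrogen-bonding capacity, ring
statistics, additive logP/TPSA estimates, rotatable bonds, connectivity
indices, gyration/span/surface-area estimates; the pocket adds residue
composition and Kyte–Doolittle hydropathy). The one-hot vocabularies and
descriptor orders are fixed so the printed dimensionalities 40/11/88/74
hold for every complex.

Scaling follows the scheme the representation was designed with: z-scores
for Gasteiger charges, electrostatic energies and both global blocks;
min–max for masses and edge distances. All statistics are
training-set-wide (not per-graph), so every graph shares one range;
out-of-sample min–max values are clamped to [0, 1] — the trained range is
authoritative. A `scaled` flag guards against double transformation, and
constant features pass through with one summary warning. Coordinates enter
the nodes raw (absolute, in Å): the representation is deliberately not
translation-invariant, which is a known limitation of this family of
models; `center_coords = TRUE` exists for experimentation and is off by
default.

Graph assembly (`build_graph()`): nodes are all ligand atoms plus the
pocket atoms within the cutoff of any ligand atom; edges are the ligand's
covalent bonds plus exactly one edge per (ligand atom, pocket atom) pair
named by any contact, with all of that pair's category flags on the single
edge. There are no pocket–pocket edges, so graphs stay sparse. One
resolution worth recording: ring-mediated categories can legitimately
reference a pocket member atom slightly beyond the 3 Å node cutoff (their
own caps reach to 7.2 Å), so the node set also admits pocket atoms named
by a contact — otherwise such an edge would dangle. Node order is
canonical (ligand atoms in file order, then pocket atoms by chain, residue,
index) and edges are sorted, so identical inputs give identical graphs.
The JSON graph container serializes all matrices as full-precision decimal
strings (`%.17g`), making the round trip bit-exact.

PCA of the global blocks (`pca_elbow()`) is available for exploration —
the elbow is the smallest component count whose next marginal gain falls
below 1% of total variance — but is not part of the default pipeline:
reduced descriptor blocks tend to generalize worse to out-of-distribution
complexes than the full, frozen blocks, so the default model keeps all
88 + 74 descriptors and leaves PCA as a reporting tool
(`plaig_cli("pca-report", ...)`).

## The hybrid model

The network (`train_gnn()`) is written directly on matrix algebra with
hand-derived gradients:

* L = 4 message-passing layers (40 → H, then H → H ×3, H = 256 by
  default). A layer computes messages as a learned linear function of the
  source node vector and the 11-d edge vector, aggregates incoming
  messages by mean, adds a learned self-loop term and bias, then ReLU.
  Edges are undirected: messages pass both ways.
* Global mean pooling over nodes; in parallel the ligand-global (88) and
  pocket-global (74) vectors each pass through their own H-unit ReLU
  layer; the three H-d streams are concatenated and passed through a final
  H-unit ReLU layer — that activation is the graph's *embedding* — then
  dropout (rate 0.2, training only) and a linear scalar head.
* Loss is mean absolute error; the optimizer is Adagrad
  (per-parameter accumulated squared gradients) at learning rate 0.001,
  batches of 32, a fixed 50 epochs, no early stopping. Everything —
  initialization (Glorot uniform), shuffling, dropout masks — is driven by
  one seed, so runs are bit-reproducible.
* The scalar head's bias is initialized at the mean training target.
  Under MAE the gradient magnitude is constant, so a zero-initialized
  offset costs many epochs of drift before the model fits deviations; the
  mean is the MAE-optimal constant and a standard, data-independent
  starting point.

Mean aggregation and mean pooling make predictions invariant to node
permutations (tested to 1e-5). Ablation variants are input masks applied
consistently at training and inference: `no_interactions` zeroes the
energy slot and the 8 flags on every edge; `no_globals` zeroes both global
vectors and bypasses their branches; `atoms_only` applies both.

The stacking stage (`train_stacking()`) fits a random forest and a
gradient-boosted tree ensemble (500 trees each, library defaults
otherwise — the tuning grid deliberately covers only network
hyperparameters) on the embeddings, then a ridge-regularized linear
meta-learner (λ = 1e-3, intercept unpenalized) on their out-of-fold
predictions from an internal 5-fold split, and refits the bases on all
data. The prediction is meta(rf(e), xgb(e)) on the embedding e. The whole
model — scaler, network weights, both ensembles (the booster as raw
bytes) — persists as one artifact with exact prediction round-trip.

Hyperparameter search (`tune_gnn()`) minimizes the negative mean 5-fold CV
Pearson correlation over the standard grid (hidden channels 64/128/256,
2–5 layers, dropout 0.2–0.5, learning rate 0.001–0.05, batch 32–256,
50–100 epochs) with a budget of 20 evaluations: the first half explores
random draws, the second half perturbs the incumbent one dimension at a
time — a simple sequential strategy that needs no surrogate model at this
budget. The CV objective evaluates the network stage; the full trial log is
attached to the returned configuration.

## Evaluation

`eval_metrics()` reports PCC, MSE, MAE, R² = 1 − SSres/SStot, and a
median-split AUC: predictions as scores against the binarization
actual > median(actual), ties to the low class, computed by the
tie-averaged rank statistic. `crossvalidate()` defaults to repeated random
80:20 splits — the literature convention "10-fold cross-validation with an
80:20 split" is internally inconsistent (classic 10-fold implies 90:10),
so both stated numbers are honored by repetition, with classic k-fold
behind `method = "kfold"`. `remove_outliers()` drops complexes whose
prediction residual exceeds 3 standard deviations, as a single pass with
statistics computed once on the full input (the one-shot training-set
filter); iterated re-filtering would be a different procedure and is not
the default. `active_decoy_report()` scores active/decoy discrimination by
ROC AUC, a Welch two-sample t-test on the group means (the unequal-variance
form, since group sizes and spreads differ in screening data), and
classification rates at the pKd 6 (1 µM) activity cutoff.
`dg_to_pkd()` converts a docking free energy via Kd = exp(ΔG/RT),
R = 1.9872×10⁻³ kcal/(mol·K), T = 298 K, pKd = −log10 Kd; it is strictly
decreasing in ΔG and exactly inverted by `pkd_to_dg()`.

## The synthetic generator: what it does and does not show

`make_complex()` builds docked complexes from independent *sites*: each
planted interaction couples a small ligand probe group with one rigid
idealized pocket residue placed at the exact geometry of its category,
with margins of at least 0.2 Å / 10° inside every threshold. Sites occupy
dodecahedron vertices 12 Å from the origin; adjacent directions subtend
41.8°, which keeps all cross-site atom pairs outside every rule threshold.
Residue templates are built so that non-bonded atoms stay well outside the
bond-perception limit, and each category uses its own residue type
(Ser, Thr, Ala, Zn, Asp, Lys, Phe, Tyr, Gly), so a complex's pocket
composition reflects its planted counts. Ground truth is enumerated from
the template-declared atom roles on the file-rounded coordinates —
independently of the detector's perception machinery — and the
generator→parser→detector closure is exact, also under small jitter
(the truth tracks the jittered coordinates). Two geometric notes: π-stacks
are planted at 4.3/4.4 Å centroid separation so that ring carbons stay
outside the 4.0 Å hydrophobic cap (at van-der-Waals stacking distance,
stacked aromatic carbons genuinely satisfy both rules); and edge-on
T-stacks unavoidably bring ring carbons within hydrophobic range, so those
contacts are part of the declared truth.

`make_dataset()` draws per-kind counts uniformly from 0..2 and sets
pKd = 4 + Σ βk·countk + N(0, 0.3), with effects between 0.3 (hydrophobic)
and 0.8 (metal) pKd units per contact — chemically plausible magnitudes
spanning weak packing to strong coordination — and `close_contact` as a
zero-effect distractor. The affinity range (≈4–11) and the noise scale are
in the range of experimental affinity data. Every complex is run through
the real pipeline (parse → charges → detect → graph), not through any
shortcut.

What passing these tests shows: the geometry engine, featurization, graph
assembly, learning machinery and evaluation code are correct and the whole
chain is learnable end to end. What it does not show: performance on real
complexes. Real pockets are conformationally coupled, ligands are
connected drug-like molecules, interactions are not independent, affinity
is not linear in contact counts, and noise is not homoscedastic Gaussian.
The synthetic study is a correctness and recoverability harness, not a
benchmark.

## Problem sizes and numerical choices

The packaged study sizes were chosen so the full chain runs comfortably on
one CPU: the parameter-recovery experiment uses 500 complexes with a
400/100 split and a reduced-width network (64 channels, 20 epochs) — the
planted linear signal saturates well before the full 256/50 configuration
would. The noise ceiling PCC ≈ 0.97 for σ = 0.3 is reported alongside the
achieved held-out PCC. Degenerate inputs are handled explicitly: constant
features pass through scaling with a warning; constant actual values make
PCC/R²/AUC NaN with a warning rather than an error; sd-zero residuals
disable the outlier filter; an empty pocket neighbourhood still builds a
ligand-only graph (with a warning); rank-deficient PCA inputs cap the
component count at the rank. Ties are broken deterministically everywhere
(first-minimum scans in index order), so identical inputs always give
identical outputs.

## Known limitations

Absolute coordinates make the learned model sensitive to rigid motions of
the complex (the detector itself is rigid-motion invariant; tested).
Donor detection needs explicit hydrogens. Pocket chemistry comes from
residue templates, so exotic cofactors fall back to conservative defaults
(charge 0, no aromaticity). The Gasteiger scheme covers the common organic
elements; metals keep their formal charge out of the equalization. The
stacking stage needs at least 50 training complexes; below that the bare
network is the fallback (`stack = FALSE`).
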
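# plaig

Interaction-based graph representations of docked protein–ligand complexes
and hybrid GNN/ensemble prediction of binding affinity, in R.

## What it does, and for whom

Structure-based drug-discovery pipelines dock a ligand into a protein
pocket and then need a number: how tightly does it bind? plaig predicts
that number as the pKd/pKi = −log10(Kd/Ki in molar) of the docked complex.
It is written for computational chemists and method developers who have
docked poses (PDB protein, MOL2/PDB/PDBQT ligand) and want an
interaction-aware rescoring model they can train, inspect and extend
entirely in R.

The model works on a graph of the binding interface:

* **nodes** — all ligand atoms plus the pocket atoms within 3 Å of the
  ligand, each carrying 40 features (atomic number, residue one-hot,
  hybridization one-hot, degree, aromaticity, H count, mass, formal and
  Gasteiger charge, xyz);
* **edges** — ligand covalent bonds and protein–ligand contacts, each
  carrying 11 features: the Coulomb energy 332.06·q₁q₂/r kcal/mol, eight
  0/1 flags for the detected interaction categories (hydrogen bond,
  halogen bond, hydrophobic, metal, π–π, T-stack, salt bridge, cation–π),
  the bond type, and the distance;
* **global vectors** — 88 ligand and 74 pocket physicochemical/topological
  descriptors.

A four-layer edge-conditioned message-passing network (hidden width 256,
mean pooling, MAE loss, Adagrad, 50 epochs) produces a 256-d embedding per
complex; a stacking ensemble — random forest + gradient-boosted trees with
a ridge meta-learner — fit on those embeddings gives the final prediction:

    pKd ≈ meta( rf(embed(G)), xgb(embed(G)) )

Everything upstream is included: pocket extraction (residues within 10 Å
of the ligand), native parsers for the three file formats, Gasteiger PEOE
partial charges, a rule-table-driven geometric interaction detector,
evaluation utilities (repeated-split CV, median-split AUC, active/decoy
ROC at the 1 µM cutoff, 3σ residual outlier filtering, ΔG→Kd conversion),
and a synthetic-complex generator with exact interaction ground truth so
the entire chain is testable without any external download.

## Worked example

Generate a synthetic docked complex with planted interactions, run it
through the pipeline, and inspect what the detector finds:

```r
library(plaig)

spec <- fixture_spec(c(hydrogen_bond = 2, salt_bridge = 1, pi_pi = 1),
                     seed = 1)
cx <- make_complex(spec)
paths <- write_complex(cx, tempdir(), "demo")

ligand <- assign_partial_charges(parse_ligand(paths["ligand"], "mol2"))
pocket <- assign_partial_charges(parse_protein_pdb(paths["protein"]))
ints <- detect_interactions(pocket, ligand, cutoff = 3.0)
print(ints)
#> <plaig_interactions> 8 contacts (cutoff 3.00 A)
#> close_contact hydrogen_bond         pi_pi   salt_bridge
#>             4             2             1             1

build_graph(pocket, ligand, ints, id = "demo")
#> <plaig_graph> 'demo': 18 nodes (14 ligand), 17 edges
```

The two planted hydrogen bonds, the salt bridge and the π-stack are found
exactly (the four close contacts are the donor/acceptor pairs within 3 Å);
the graph has the 14 ligand atoms plus the 4 pocket atoms in contact
range, with 40/11/88/74-dimensional features.

Train the hybrid model on a small synthetic study and evaluate held-out
predictions:

```r
ds <- make_dataset(dataset_spec(n = 150, seed = 7))   # pKd = 4 + Σ βk·countk + N(0, 0.3)
cfg <- gnn_config(hidden_channels = 64, epochs = 15, seed = 42)
model <- train_affinity_model(ds$graphs[1:120], cfg)
pred <- predict(model, ds$graphs[121:150])
eval_metrics(pred, ds$targets[121:150])
#> PCC 0.893 | MSE 0.187 | MAE 0.351 | R2 0.762 | AUC 0.938 (n=30)
```

A held-out Pearson correlation of 0.89 against a noise ceiling of ≈0.97
(σ = 0.3 on a signal of variance ≈1.6) shows the model recovering most of
the planted linear affinity signal from the graphs alone. Converting a
docking free energy to the same scale:

```r
dg_to_pkd(-9.56)
#>   delta_g           Kd      pKd
#> 1   -9.56 9.748304e-08 7.011071
```

A command-line entry point wraps the same functions
(`extract-pocket`, `interactions`, `featurize`, `train`, `predict`,
`evaluate`, `tune`, `pca-report`, `make-fixtures`):

```sh
Rscript "$(Rscript -e 'cat(system.file("cli","plaig.R",package="plaig"))')" \
  extract-pocket --protein protein.pdb --ligand ligand.mol2 --radius 10 --out pocket.pdb
```

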
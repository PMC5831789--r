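# gpcrbind

Predicting which small-molecule ligands bind which G-protein coupled
receptors (GPCRs), using only a ligand's 2D structure and a receptor's
amino-acid sequence — no 3D structures, no docking, no similarity to known
binders. The package is aimed at computational chemists and bioinformaticians
who have SMILES strings, receptor sequences and a table of known binding
pairs, and want a reproducible feature-based classifier plus the tooling to
evaluate it honestly.

## The method

Each **ligand** is parsed from canonical SMILES into a heavy-atom molecular
graph and summarized by:

* **Hub codes** — every atom bonded to ≥ 3 heavy neighbors (a branching
  point) is encoded with its satellites as a canonical string, e.g. the
  neopentane center is `C-C-C-C-C` and a toluene ipso carbon is `C-C:C:C`
  (satellites sorted by element, then bond symbol `-` < `=` < `#` < `:`).
* **Cycle codes** — a minimum cycle basis of the ring system (fused systems
  give the chemically expected small rings: naphthalene yields two 6-rings,
  never the 10-atom envelope). Each ring is encoded as the lexicographically
  smallest rotation/direction of its element/bond string, e.g. benzene is
  `C:C:C:C:C:C:`.
* ***4chars*** — molecular weight, XlogP, hydrogen-bond donor and acceptor
  counts (supplied from a physicochemical table when available; MW/HBD/HBA
  computed from the graph otherwise, with an approximate additive XlogP
  fallback).

Ligand vectors count each vocabulary hub/cycle code; corpora are first
filtered to drug-like weight (strictly 150 < MW < 500).

Each **receptor** sequence is summarized by amino-acid composition (20),
dipeptide composition (400) and exact overlapping occurrence counts of a
supplied motif list; motifs whose total count over the corpus is ≤ 1 are
excluded as uninformative.

Known binding pairs are labeled positive; an equal number of **negative
pairs** is drawn uniformly (seeded) from the receptor × ligand cross-product
excluding known positives. The concatenated receptor ‖ ligand vectors feed a
classifier — random forest by default, with SVM, naive Bayes, CART and
neural-network adapters — evaluated by stratified k-fold cross-validation
with the package's own rank-statistic ROC/AUC (Mann–Whitney with ½ for
ties; the threshold-swept curve's trapezoidal area equals it). Feature-set
tags (`MF`, `1AAF`, `2AAF`, `4chars`, `Hub`, `Cycle`) make the full 7 × 7
ablation grid a pure column selection.

A **synthetic-data module** generates valence-legal molecules from a
constructive grammar with exactly known hub/cycle ground truth, receptor
sequences with planted motifs, and binding tables governed by a planted
logistic rule — so every stage of the pipeline is testable at desk scale
without downloads.

## Worked example

```r
library(gpcrbind)

g <- parse_smiles("CC(C)(C)c1ccc(O)cc1")   # 4-tert-butylphenol
g
#> <molgraph> 11 atoms, 11 bonds, 1 component(s): CC(C)(C)c1ccc(O)cc1

find_hubs(g)                                # atoms with >= 3 heavy neighbors
#> [1] 2 5 8
encode_hub(g, 2)                            # the tert-butyl quaternary carbon
#> [1] "C-C-C-C-C"
vapply(find_cycles(g), function(r) encode_cycle(g, r), "")
#> [1] "C:C:C:C:C:C:"
round(compute_fourchars(g), 2)
#>     MW  XlogP    HBD    HBA
#> 150.22   2.32   1.00   1.00
```

The hub indices are the quaternary carbon (2), the ipso carbon (5) and the
hydroxyl-bearing ring carbon (8); the single ring is the benzene code, and
the phenol gives one donor and one acceptor.

A small end-to-end run on synthetic data:

```r
corp <- generate_binding_corpus(
  synthetic_spec(n_receptors = 10, n_ligands = 300, n_pos = 150, seed = 1))
ds <- corpus_dataset(corp)
ds
#> <binding_dataset> 300 pairs (150 positive), 480 features [1AAF, 2AAF, MF, Hub, Cycle, 4chars]
cross_validate(ds, "random_forest", k = 5, seed = 1)
#> <cv_report> random_forest, 5-fold, all features: mean AUC 0.9040, mean accuracy 0.8167
```

The mean AUC of 0.90 reflects the corpus's planted binding rule: the
classifier recovers the ring-size and branching preferences (plus receptor
motif counts) that generated the labels.

The same pipeline is scriptable from a shell via the bundled entry point
(`inst/cli/gpcrbind`): `simulate`, `featurize-ligands`,
`featurize-receptors`, `build-dataset`, `evaluate` and `predict`
subcommands, each writing a `manifest.json` that suffices to re-run it
bit-identically.

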
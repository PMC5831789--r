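Package: gpcrbind
Title: GPCR-Ligand Binding Prediction from Hub and Cycle Structural Features
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts binding between G-protein coupled receptors (GPCRs) and
    small-molecule ligands without 3D structure. Ligands are parsed from a
    supported subset of SMILES into heavy-atom molecular graphs; canonical
    string encodings of "hub" atoms (highly connected atoms with their bonded
    satellites) and ring "cycles" (a minimum cycle basis) are counted as
    structural features alongside four physicochemical descriptors (molecular
    weight, XlogP, hydrogen-bond donors and acceptors). Receptors are
    featurized by amino-acid and dipeptide composition and exact-match motif
    occurrence counts. The package builds labeled datasets by seeded uniform
    negative-pair sampling, trains classifiers (random forest by default; SVM,
    naive Bayes, CART and neural-network adapters), runs stratified k-fold
    cross-validation over feature-set combinations, and computes ROC curves
    and AUC with its own rank-statistic implementation. A synthetic-data
    generator emits valence-legal molecules with known hub/cycle ground truth,
    receptor sequences with planted motifs, and binding tables governed by a
    planted rule, so the whole pipeline is testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    e1071,
    jsonlite,
    nnet,
    ranger,
    rpart,
    stats,
    utils
Suggests:
    igraph,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
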
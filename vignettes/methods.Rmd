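---
title: "Hub and cycle features for GPCR–ligand binding prediction: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hub and cycle features for GPCR-ligand binding prediction: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The prediction problem

GPCRs are the largest family of drug targets, and for most receptor–ligand
pairs no co-crystal structure exists. `gpcrbind` predicts binding from the
two cheapest descriptions available: the ligand's canonical SMILES string
and the receptor's amino-acid sequence. The working hypothesis is that
binding propensity is partly encoded in *local and global ligand topology*
(branching points and rings) and in *short receptor sequence motifs*, and
that a flexible classifier over count features of these can separate binding
from non-binding pairs without any 3D information.

# Ligand representation

## The SMILES subset and the valence model

`parse_smiles()` supports the organic subset (B, C, N, O, P, S, F, Cl, Br,
I; aromatic b, c, n, o, p, s), bracket atoms with element, charge and
explicit hydrogen count, bond symbols `- = # :`, branches, ring closures
(`1`–`9`, `%nn`) and the `.` component separator. Stereo markers and
isotopes carry no information for count-based topology features, so they are
discarded (strict mode refuses them instead). Hydrogens are never graph
nodes: canonical SMILES leave them implicit, and all degree-based features
use heavy atoms only.

Implicit hydrogens on organic-subset atoms follow
`max(0, floor(valence + charge − bond_order_sum))` with aromatic bonds
contributing 1.5 (benzene carbons get exactly one H). The `+charge` term
gives the standard effective valences (ammonium nitrogen 4, alkoxide oxygen
1). Bracket atoms use their written H count — zero if absent, which is
standard SMILES semantics. These assignments only matter for the
physicochemical descriptors; the structural codes never consult hydrogens.

Aromatic systems are kept as a distinct `:` bond type rather than
kekulized. Kekulization would force an arbitrary alternation choice and make
codes depend on it; keeping aromaticity explicit makes every encoding
deterministic.

## Hubs

A *hub* is an atom with at least `min_satellites` heavy-atom neighbors. The
threshold is exposed everywhere and defaults to **3**. The defining phrase —
an atom "connected to more than 3" others — is ambiguous between degree ≥ 3
and degree ≥ 4; at degree ≥ 4 a typical drug-like ligand contains almost no
hubs (only quaternary centers and similar), while the worked examples in the
source material show ~8 hubs in one ligand, which is only plausible at
degree ≥ 3. We therefore read "more than 3 nodes involved in the
connection" (the hub plus ≥ 3 satellites), default to 3, and leave the
parameter tunable.

A hub's code is its element followed by one (bond symbol, element) pair per
satellite. "Clockwise" orderings are undefined on an abstract graph, so the
pairs are sorted canonically — satellite element first (byte-wise string
order, so `Br < C < Cl < N < O`), then bond symbol by the precedence
`- < = < # < :`. String equality of codes is then exactly structural
equality of hub neighborhoods.

## Cycles

Ring features use a **minimum cycle basis**: exactly
`bonds − atoms + components` rings (the circuit rank), chosen
smallest-first. Depth-first-search fundamental cycles alone are
start-order-dependent and can return a fused system's large envelope; the
minimum basis returns the chemically expected small rings (two 6-rings for
naphthalene) and is deterministic. Candidates are the shortest cycles
through each bond (breadth-first search in the graph minus that bond, ties
broken toward smaller atom indices); a greedy pass keeps candidates that are
independent over GF(2), and in the rare case the candidates do not span the
cycle space the basis is completed with spanning-tree fundamental cycles.

A ring's code lists elements and connecting bonds around the ring,
including the closing bond. Among all rotations and both directions the
lexicographically smallest candidate (same ordering as for hubs) is
returned, which in particular starts at the alphabetically first element.
The code is invariant to how the ring was discovered or supplied — a
property the test suite checks by brute-force enumeration of all rotations.

## Physicochemical descriptors

The four descriptors (molecular weight, XlogP, H-bond donors, H-bond
acceptors) are taken from a user-supplied physicochemical table whenever one
is given, since XlogP is defined by a specific published model that this
package does not reimplement. Otherwise MW (standard atomic weights plus
1.008 per hydrogen), HBD (N/O atoms carrying ≥ 1 H) and HBA (all N/O atoms)
are computed from the graph, and XlogP falls back to a crude additive
atom-contribution estimate whose output is flagged `approximate` (strict
mode refuses the fallback). Corpora are filtered to 150 < MW < 500 with
*strict* inequalities — records at exactly 150 or 500 are excluded — since
lighter records are typically ions and heavier ones peptides.

# Receptor representation

Counts, not proportions: amino-acid composition (20, alphabetical),
overlapping dipeptide composition (400, lexicographic) and exact overlapping
occurrences of each motif string. Tree ensembles are scale-insensitive, and
counts are the literal reading of "frequency" here; `normalize = TRUE`
divides by (length, length − 1) for users who want composition. Motif
matching is literal substring matching — motif *discovery* (e.g. MEME) is
out of scope and motifs arrive as consensus strings. A corpus-level filter
excludes motifs whose **total count over all receptors is ≤ 1**: a motif
seen at most once cannot co-vary with anything. (The alternative reading —
exclude motifs occurring exactly once in *every* receptor — would exclude
almost nothing and is implausible.) Non-standard residues (X and friends)
are an error in strict mode; lenient mode keeps them in place so they break
dipeptide windows and motif matches but are never counted.

# Dataset construction

Positives are drawn uniformly without replacement from the known binding
table. Negatives are drawn uniformly from the receptor × ligand
cross-product excluding known positives, without duplicates, by exact
sampling of the eligible cells with a seeded RNG; if fewer eligible cells
exist than requested the error states the achievable maximum. The original
negative-sampling procedure this reconstructs was not printed in full; the
uniform-exclusion scheme is the simplest procedure consistent with its
description, and the usual caveat applies that sampled negatives may contain
unknown true positives (no correction is attempted). Assembled rows are
receptor vector ‖ ligand vector with tag-prefixed column names, so any
feature-set combination of the 7 × 7 ablation grid is a column selection.

# Classification and evaluation

AUC is computed as the Mann–Whitney rank statistic with ties contributing ½
— the probability a random positive outscores a random negative — and the
ROC curve is a threshold sweep over unique scores from (0, 0) to (1, 1).
The two agree to machine precision (the trapezoidal area of the swept curve
*is* the rank statistic), and the test suite checks both this identity and
agreement with an independent reference implementation.

The classifier adapters expose one contract — a probability-like score —
over standard implementations: random forest (`ranger`, probability forest,
single-threaded and seeded for reproducibility), SVM and naive Bayes
(`e1071`), CART (`rpart`) and a single-hidden-layer network (`nnet`).
Hyperparameters are the backends' defaults and are recorded in every
report; zero-variance columns are dropped for the scale-sensitive learners.
Cross-validation uses stratified folds (seeded per-class shuffling, dealt
round-robin) — plain k-fold can produce degenerate folds at desk scale —
and reports both per-fold AUC and accuracy at a 0.5 threshold, since both
metrics are conventional for this task. Mean AUC is averaged over folds;
when several datasets are evaluated, averaging over datasets (rather than
pooling folds) is the implemented aggregation.

# The synthetic-data generator

The generator exists so that every pipeline stage has an executable ground
truth. Three design points matter:

**Molecules are built constructively, not sampled as strings.** Random
SMILES strings essentially never parse; instead molecules are assembled
from a grammar of chain units and ring units (benzene, pyridine,
cyclohexane, cyclopentane, oxolane, occasional fused 6-6 pairs) joined by
single bonds and decorated with substituents, under an explicit valence
ledger. Because construction is explicit, the exact hub and cycle codes are
recorded *by construction* (via a small construction-side canonicalizer,
separate from the featurization path), and the central round-trip test
demands that parsing the emitted SMILES and featurizing recovers them
exactly, for 100% of molecules.

**The planted rule is descriptor-blind by design.** Binding propensity is
`plogis(steepness · z)`, where `z` is the standardized weighted sum of
specific ligand code counts and receptor motif counts. The default rule
favors five-membered carbocycles, penalizes six-membered carbocycles and
rewards sp3 branching hubs: pure-carbon ring-size and branching signals are
nearly invisible to MW/XlogP/HBD/HBA (one CH2 of weight), so the
structure-vs-descriptor ablation measures genuine structural information
rather than a heteroatom proxy. An early design that weighted
pyridine-vs-benzene content leaked into XlogP and HBA and was discarded for
exactly that reason. Receptor-side weights on planted motifs make both
halves of the concatenated vector informative.

**Pair-level cross-validation can reward memorization.** When a ligand
occurs in many pairs, stratified pair-level CV places the same ligand in
training and test folds, and a forest can identify it from its near-unique
molecular weight alone — an entity-leakage effect that equally affects
real dense interaction tables. The default corpus therefore keeps the
ligand pool large relative to the pair count (2,000 ligands, 40 receptors,
1,000 positive + 1,000 negative pairs), so each ligand appears in about one
pair and CV measures generalization over ligands. Positives are sampled
proportional to propensity and negatives proportional to its complement
(the planted rule governs non-binding too); labels are then flipped with
probability `noise`, so `noise = 0.5` destroys all signal and CV AUC must
sit at chance, while `noise = 0` with the default rule (steepness 10,
measured Bayes ceiling near 0.99 using the true propensities as scores)
leaves ample headroom for the forest.

What the generator does *not* emulate: chemical realism beyond valence
legality (no tautomers, charges, stereochemistry or drug-likeness), sequence
homology among receptors, and any correlation structure between receptor
family and ligand chemistry. Passing the synthetic benchmarks therefore
shows the pipeline's *mechanics* are correct and that the classifier can
recover a planted structural signal at realistic feature dimensions — not
that comparable AUCs will be reached on any particular real corpus.

# Numerical choices and degenerate inputs

* All randomness flows from explicit integer seeds through one local-RNG
  helper that restores the caller's RNG state; stage seeds derive from the
  root seed arithmetically (kept inside 32-bit range).
* Code-string comparisons use byte-wise (C-locale) ordering everywhere, so
  vocabularies and canonical codes are locale-independent.
* Empty graphs, acyclic graphs, empty vocabularies and empty motif lists
  are all legal and produce empty (not missing) feature blocks.
* Ties in `predict_pairs()` rankings break by (receptor ID, ligand ID) so
  output files are reproducible byte for byte.
* Errors are classed conditions (`gpcr_parse_error`, `gpcr_capacity_error`,
  `gpcr_shape_error`, …) so callers and the CLI can distinguish usage from
  domain failures; parse errors name the offending position.

# Problem sizes

The bundled evaluations run at desk scale, chosen so a full check of the
pipeline completes in minutes on one CPU: 1,000 generated molecules for the
round-trip check, 2,000-pair corpora (10-fold CV) for the planted-signal,
label-noise and ablation benchmarks, and 100 random score sets for the
ROC-identity check. The corpus dimensions are a deliberate down-scaling of
a realistic application (thousands of receptors, hundreds of thousands of
ligands and pairs); nothing in the implementation is specific to these
sizes.

# Known limitations

* The SMILES subset excludes multi-character bracket organics beyond the
  supported table (no Se/Si/metals) and does not kekulize; codes from
  kekulized and aromatic spellings of the same molecule differ. Use one
  canonical convention per corpus.
* The fallback XlogP is a labeled approximation suitable only for filling a
  missing column; supply database values for real work.
* Negative sampling assumes unlabeled pairs are negative (standard
  positive–unlabeled caveat).
* The hub-threshold reading (degree ≥ 3) is calibrated against a published
  worked example whose structure record must be fetched separately; the
  threshold remains a parameter should a different reading be wanted.
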
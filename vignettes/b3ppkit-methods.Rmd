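---
title: "Composition-based prediction of blood-brain barrier penetrating peptides: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Composition-based prediction of blood-brain barrier penetrating peptides: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(b3ppkit)
```

## The problem

The blood-brain barrier (BBB) blocks most drugs from reaching brain tissue.
Short peptides that cross it — blood-brain barrier penetrating peptides
(B3PPs) — are of interest both as therapeutics and as delivery vehicles,
and experimentally validated B3PPs are rare enough that sequence-based
screening is the practical first filter. `b3ppkit` treats B3PP recognition
as a binary sequence-classification problem over peptides of 6-30
residues: encode each peptide as a fixed-length composition-based
descriptor vector, select the discriminative descriptors, fit standard
classifiers, and expose the fitted model through predict / design / scan
application modules.

## The descriptor vector

Every peptide maps to a pinned, ordered vector of **9,189 descriptors**
across fifteen composition-based families:

| family | size | content |
|--------|-----:|---------|
| AAC    |   20 | amino-acid composition, percent (Sens-style `count/L x 100`) |
| DPC    |  400 | overlapping dipeptide composition, percent |
| TPC    | 8000 | overlapping tripeptide composition, percent |
| ABC    |    9 | atom (C,H,N,O,S) fractions and bond-type composition |
| RRI    |   20 | residue-repeat information, `sum(run^2)/L` per residue |
| DDOR   |   20 | squared gaps between successive occurrences, `/k` |
| SE     |    1 | Shannon entropy of the residue distribution (bits) |
| SER    |   20 | per-residue entropy terms `-p log2 p` |
| SEP    |   25 | binary entropy of 25 physicochemical property fractions |
| CTD    |  343 | conjoint-triad composition over a 7-class alphabet |
| CeTD   |  147 | composition/transition/distribution, 7 attributes x 3 classes |
| PAAC   |   24 | Chou pseudo amino-acid composition, lambda = 4 |
| APAAC  |   28 | amphiphilic pseudo amino-acid composition, lambda = 4 |
| QSO    |   86 | quasi-sequence-order, two distance matrices, lag 23 |
| SOCN   |   46 | sequence-order coupling numbers, two matrices, lag 23 |

The total of 9,189 is the package's contract; `feature_manifest()`
enumerates every name in order and the manifest version is embedded in
every trained bundle. The decomposition itself — which lambda and lag
values close the books at 9,189 — is pinned by this package: lambda = 4
for PAAC/APAAC and lag 23 for QSO/SOCN, with lags or lambdas that exceed a
peptide's length contributing exact zeros. Composition-like families
(AAC, DPC, TPC, CeTD) are reported as percentages; PAAC/APAAC/QSO use
their conventional unit-sum normalization.

Two families have no universally printed closed form, so the package
fixes simple, brute-force-checkable ones: RRI is the sum of squared
maximal run lengths of a residue divided by sequence length, and DDOR is
the sum of squared gaps between successive occurrences divided by the
occurrence count (zero for residues seen fewer than twice).

### Property tables and distance matrices

All lookup tables ship as versioned plain-text files under
`inst/extdata/`; changing any table bumps the manifest version.

* **Atom/bond counts** per residue were computed once from the canonical
  free-amino-acid structures (SMILES) and frozen. The ABC block reports
  the five atom fractions (summing to 1), the bond density (total bonds
  per atom), and the single/double/aromatic fractions of total bonds.
  The "total bonds" component is defined as a density because a
  total/total fraction would be identically 1.
* **SEP** uses 25 binary properties: the 21 class indicators of the
  seven CeTD attributes (hydrophobicity, van der Waals volume, polarity,
  polarizability, charge, secondary-structure propensity, solvent
  accessibility; three classes each) plus aromatic, aliphatic, tiny and
  sulfur-containing.
* **QSO/SOCN** need two inter-residue distance matrices. The chemical
  one is the Grantham distance, recomputed from its published closed
  form over residue composition, polarity and volume (constants 1.833,
  0.1018, 0.000399, scale 50.723; spot-checked against published
  entries). The physicochemical one is defined by this package: the
  Euclidean distance between residues over the three standardized Chou
  scales (hydrophobicity, hydrophilicity, side-chain mass) — the same
  scales that drive PAAC — so the two matrices probe chemistry and
  physicochemistry respectively. Both are max-normalized to [0, 1]
  before use so the two coupling blocks live on comparable scales
  (raw Grantham values reach 215, and SOCN squares them).

## Feature selection and ranking

Selection follows the sparse-linear-model recipe: an **L1-penalized
linear support-vector classifier with squared-hinge loss**,

$$\min_{w,b}\; \lVert w\rVert_1 + C \sum_i \max(0,\, 1 - y_i(x_i^\top w + b))^2,$$

fitted on z-scored columns (training-split statistics only; constant
columns dropped). Features with non-zero coefficients survive. The
solver is FISTA (accelerated proximal gradient) with an unpenalized
intercept, a Lipschitz step from power iteration, a 10,000-iteration cap
and a relative objective tolerance of 1e-9; soft-thresholding yields
exact zeros, so "selected" is unambiguous. Because the penalty is fixed
and the loss scales with `C`, smaller `C` means fewer survivors — the
count is non-increasing as `C` decreases, and the default is `C = 0.01`.
No installed R package fits this objective (glmnet covers logistic and
least-squares losses only), so the solver is authored here; it was
verified during development to reproduce the support of an independent
implementation of the same objective on identical inputs.

Survivors are then ranked by **split counts in a gradient-boosted tree
ensemble** (xgboost; 100 rounds, depth 6, learning rate 0.1): a
feature's importance is the number of splits that use it across all
trees, ties broken by manifest order, and `top_k()` truncates the
ranking (default 80, saturating at the number selected).

## Classifiers and evaluation protocol

Seven families are wrapped behind one interface, all emitting
positive-class probabilities in [0, 1]: random forest (500 trees,
sqrt(p) features per split), CART decision tree, ridge logistic
regression (lambda = 1/n), k-nearest neighbours (k = 5, vote fraction),
Gaussian naive Bayes, gradient boosting (300 rounds, depth 6, learning
rate 0.1) and an RBF support-vector classifier with Platt-scaled
probabilities. These hyperparameters are pinned defaults chosen for
reproducibility, not tuned values. Classification uses a 0.5 threshold
by default; every bundle records its threshold and `predict()` accepts
an override.

Evaluation follows the standard two-level protocol: a stratified
**80:20** split (training size `floor(0.8 n)` per class — a
deterministic rounding rule), stratified **5-fold cross-validation** on
the training split (internal validation), then a final fit on the full
training split scored on the held-out 20% (external validation).
Reported metrics are sensitivity, specificity and accuracy (percent),
the Matthews correlation coefficient, and AUROC computed by the
Mann-Whitney rank-sum equivalence with midrank tie handling. MCC is
defined as 0 only when one of its denominator factors is genuinely zero;
an all-wrong classifier correctly scores -1. Feature selection defaults
to the training split only (leakage-safe); `select_on = "all"` is
available for protocol comparison but inflates external estimates and
permutation nulls, which is exactly why it is not the default.

Degenerate-input contracts are explicit: an empty selected-feature set
degrades the downstream model to a constant 0.5 scorer (so permutation
nulls remain well defined and AUROC lands on 0.5 by the tie convention);
sequences shorter than k give zero k-mer blocks with a warning; lags
beyond the sequence length are exact zeros.

## The synthetic data generator

`generate_dataset()` emulates the one robust, reproducible property of
real B3PP collections: compositional enrichment of arginine, tyrosine,
glycine and lysine relative to background. Positives draw residues
i.i.d. with R/Y/G/K up-weighted by `bias_strength` (default 3, i.e. a
biased-residue fraction of 12/28 vs 4/20 under uniform); negatives are
uniform; lengths are uniform on 6-30; sequences are unique within and
across classes; generation is a pure function of the configuration.
`bias_strength = 1` produces exchangeable classes and serves as the
permutation null. An optional positional mode plants a fixed N-terminal
R-Y-G motif to exercise the positional-enrichment analysis separately
from the compositional machinery.

What the generator does **not** emulate: real B3PP sequence families and
their phylogenetic redundancy, cell-penetrating-peptide motifs,
positional preferences beyond the optional planted motif, length
distributions of curated databases, and any higher-order dependence
between residues. Tests passing on this generator therefore demonstrate
that the pipeline recovers planted compositional signal and is honest
under label permutation — not that any particular accuracy will transfer
to curated B3PP data. Published headline numbers (~85% accuracy, AUROC
~0.93 for the random-forest model on curated data) are properties of the
deposited datasets, which this package deliberately does not fetch.

At the reference study conditions used throughout the test suite
(bias 3, 200 peptides per class, generator seed 7; pipeline `C = 0.01`,
top-20, random forest), external AUROC sits near 0.9 with a validation
set of 80 peptides — close enough to the boundary that individual seeds
land on either side (the L1 step at `C = 0.01` keeps only ~5-9
composite composition features at this sample size, which caps the
downstream forest). The test suite pins the package-default seeds and
reports whatever they produce; the permutation null stays in
[0.35, 0.65] across all tested shuffles.

## Application modules

* **predict** scores any validated peptide set with a trained bundle;
  peptides outside the 6-30 training window are scored with a warning.
* **design** enumerates the parent plus all `19 L` single-residue
  substitutions (insertions/deletions are out of scope), scores each and
  sorts by score with deterministic tie-breaking (position, then
  residue). Exhaustive single-site substitution is the convention of
  this tool family; multi-site enumeration explodes combinatorially.
* **scan** slides a window of width `w` (default 15, the midpoint of the
  training length regime) across a protein at step 1 — maximally
  overlapping, 1-based inclusive coordinates — and scores each window
  with the same code path as predict, so the scores agree bit for bit.
* **composition/logo analyses**: `composition_compare()` averages
  per-peptide AAC by set; `tsl_prepare()` builds the terminal 10-mers
  (first five plus last five residues, overlap permitted down to length
  5 — the one place the length-5 floor applies, training always
  requiring 6); `tsl_enrichment()` runs per-cell two-proportion tests
  (pooled chi-square, or Fisher's exact test when an expected count
  drops below 5) at alpha = 0.05 without multiplicity correction by
  default, matching common logo-tool practice. Note that 200 uncorrected
  cells imply ~alpha x 200 false flags on null data by construction; the
  `bonferroni = TRUE` flag is the escape hatch when a clean null logo
  matters.

## Problem sizes and runtime choices

The test suite and the acceptance script are sized to run comfortably on
one CPU: the reference dataset is 200 peptides per class (featurization
~1 ms per peptide after table caching), selection problems up to
400 x 9,189, permutation nulls over 10 shuffles, and the
combinatorial checks over every training length 6-30. These sizes were
chosen as the smallest at which the statistical checks are meaningful.

## Known limitations

* The per-family decomposition of the 9,189-dimensional vector is
  normative for this package; other composition toolkits partition the
  same total differently, so descriptor values are comparable across
  runs of this package but not across toolkits.
* The physicochemical QSO/SOCN distance matrix is package-defined (see
  above); bundles record the manifest version so scores are never mixed
  across table revisions.
* Classifier hyperparameters are fixed defaults; no tuning framework is
  provided, by design.
* Only the 20 standard amino acids are supported: modified or
  D-residues are a hard validation error, not a silent skip, because
  every descriptor family assumes the 20-letter alphabet.
* Near-duplicate (as opposed to exact-duplicate) sequences between
  classes are not detected; only exact-match cross-class duplicates are
  removed during dataset assembly.
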
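# b3ppkit

Sequence-based prediction, design and scanning of **blood-brain barrier
penetrating peptides (B3PPs)** — short peptides (6-30 residues) that can
cross the blood-brain barrier and carry drug cargo into brain tissue.

The package implements the full composition-descriptor classification
pipeline for this problem, for computational peptide/drug-discovery
scientists who want a reproducible, scriptable alternative to web-server
predictors:

1. **Featurize.** Each peptide is encoded as a pinned, ordered vector of
   **9,189 descriptors** across fifteen composition-based families —
   amino-acid / dipeptide / tripeptide composition (AAC, DPC, TPC), atom
   and bond composition (ABC), residue-repeat and residue-distance
   statistics (RRI, DDOR), Shannon-entropy families (SE, SER, SEP),
   conjoint-triad (CTD) and composition/transition/distribution (CeTD)
   descriptors, pseudo and amphiphilic pseudo amino-acid composition
   (PAAC, APAAC), and quasi-sequence-order descriptors with
   sequence-order coupling numbers (QSO, SOCN).
2. **Select.** An L1-penalized linear SVC (squared hinge, default
   `C = 0.01`) keeps the descriptors with non-zero coefficients:

   min over (w, b) of ||w||_1 + C * sum_i max(0, 1 - y_i (x_i' w + b))^2

3. **Rank.** Survivors are ranked by gradient-boosted-tree split counts
   and truncated to the top k (default 80).
4. **Train and evaluate.** Seven classifier families (RF, DT, LR, KNN,
   GNB, XGB, SVC) under a stratified 80:20 split with 5-fold
   cross-validation, reporting Sens/Spec/Acc (percent), MCC and AUROC.
5. **Apply.** `predict` scores peptide sets; `design` enumerates and
   scores all single-residue analogs of a parent peptide; `scan` slides
   a window across a protein to localize candidate B3PP regions; plus
   compositional (mean AAC) and positional (two-sample-logo) analyses.

A synthetic labelled-dataset generator (positives enriched in R/Y/G/K,
the compositional signature reported for real B3PPs, versus uniform
negatives) makes the whole pipeline testable without any external
download. The curated benchmark datasets themselves are deliberately not
fetched; published accuracies on them are not reproduced here.

## Worked example

```r
library(b3ppkit)

ds  <- generate_dataset(n_pos = 200, n_neg = 200, seed = 7)
fit <- b3pp_pipeline(ds, C = 0.01, top_k = 20, model = "rf", seed = 1)

fit$selection
#> b3pp_selection: 6 features selected (C = 0.01); ranked by split count
fit$report
#> b3pp_eval_report (rf, threshold 0.5)
#> internal (5-fold mean):  Sens 85.00  Spec 78.75  Acc 81.88  MCC 0.64  AUROC 0.89
#> external (held-out 20%): Sens 75.00  Spec 85.00  Acc 80.00  MCC 0.60  AUROC 0.90
head(fit$selection$ranking, 4)
#>              feature importance
#> 1 CeTD_vdw_volume_C3        420
#> 2              AAC_G        312
#> 3     CeTD_charge_C1        292
#> 4              AAC_Y        284
```

The internal row is the mean over the five cross-validation folds of the
training split; the external row is the held-out 20%. At `C = 0.01` the
L1 step keeps six descriptors, led by composite composition features
that absorb the R/Y/G/K signal (CeTD_charge_C1 is the K+R fraction;
CeTD_vdw_volume_C3 the large-side-chain fraction including K, R and Y).

Scoring new peptides, and designing improved analogs:

```r
q <- peptide_set(c("q1", "q2"), c("RRYYGGKKRRYY", "LLIIVVFFAAMM"))
predict(fit$bundle, q)
#>   id          seq score    label
#> 1 q1 RRYYGGKKRRYY 0.958 positive
#> 2 q2 LLIIVVFFAAMM 0.000 negative

head(design_analogs("ACDEFGHIKL", fit$bundle), 3)
#>         analog position residue score
#> 85  ACDEKGHIKL        5       K  0.76
#> 91  ACDERGHIKL        5       R  0.76
#> 123 ACDEFGKIKL        7       K  0.76
```

The analog table contains all 19 x 10 + 1 = 191 rows (parent plus every
single-residue substitution), best score first — here, substitutions
toward lysine/arginine raise the predicted penetration score, as the
compositional signal would suggest. `scan_protein(protein, fit$bundle,
w = 15)` produces the analogous table over all sliding windows of a
protein.

A thin command-line front end covering the same operations is installed
as `exec/b3ppkit` (`b3ppkit synth`, `featurize`, `train`, `predict`,
`design`, `scan`, `logo`).

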
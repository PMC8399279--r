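Package: b3ppkit
Title: Composition-Based Prediction and Design of Blood-Brain Barrier
    Penetrating Peptides
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Toolkit for predicting blood-brain barrier penetrating
    peptides (B3PPs) from sequence alone. Computes a pinned
    9,189-dimensional composition-based descriptor vector over fifteen
    feature families (amino-acid, dipeptide and tripeptide composition,
    atom/bond composition, residue-repeat and residue-distance statistics,
    Shannon entropy families, conjoint-triad and
    composition/transition/distribution descriptors, pseudo and
    amphiphilic pseudo amino-acid composition, quasi-sequence-order and
    sequence-order coupling numbers), selects discriminative descriptors
    with an L1-penalized linear support-vector classifier, ranks survivors
    by gradient-boosted-tree split usage, trains and evaluates seven
    classifier families under an 80:20 split with stratified 5-fold
    cross-validation, and exposes predict, design (single-residue
    mutagenesis) and scan (sliding-window) application modules together
    with compositional and positional (two-sample-logo) analyses and a
    synthetic labelled-dataset generator.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    class,
    e1071,
    glmnet,
    randomForest,
    rpart,
    stats,
    utils,
    xgboost
Suggests:
    jsonlite,
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
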
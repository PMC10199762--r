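Package: epitopr
Title: Linear B-Cell Epitope Featurization and Classification Toolkit
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Featurization and interpretable classification of linear
    (continuous) B-cell epitopes from peptide sequences. Implements
    graph-based sequence signatures (labeled residue-pair counts at
    incremental sequence-distance cutoffs), amino-acid-triplet (AAT)
    antigenicity-ratio scales, composition/transition/distribution (CTD)
    physicochemical descriptors, propensity-scale profile statistics and
    organism-taxonomy one-hot encoding; an IEDB-style dataset curation
    pipeline (assay-evidence, length, dual-class, organism and
    sequence-redundancy filters plus a stratified train/test split);
    greedy forward feature selection, cross-validated training of
    tree-ensemble and additive classifiers, imbalance-robust metrics
    (MCC, ROC AUC, F1, balanced accuracy) and feature-importance
    reporting; and a synthetic IEDB-like fixture generator with
    controllable planted signal.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    ranger,
    xgboost,
    e1071,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    optparse
Config/testthat/edition: 3
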
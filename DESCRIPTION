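Package: essMiR
Title: Essential microRNA Prediction from Sequence and Structure Features
    with Gradient-Boosted Trees
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Predicts whether a pre-miRNA hairpin is an essential miRNA
    gene from its primary sequence and secondary structure. Implements
    five feature encoders (k-mer frequencies, mismatch counts,
    gap-weighted subsequence sums, secondary-structure triplet
    composition, and pseudo distance-structure-status-pair composition),
    Gini-criterion classification trees, a gradient-boosted tree
    ensemble, leave-one-out and repeated stratified k-fold
    cross-validation, sequential grid-search calibration, and a
    deterministic synthetic-data generator for end-to-end testing.
    Secondary structures are obtained from user-supplied dot-bracket
    files or the ViennaRNA RNAfold program.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    S4Vectors,
    xgboost,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    rpart,
    pROC
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
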
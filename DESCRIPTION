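Package: enfusion
Title: Stacked Multivariate Fusion for Enhancer Sequence Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies enhancer elements in fixed-length DNA fragments by
    fusing two complementary sequence representations: a high-dimensional
    multi-source biological feature block (positional gapped k-m-tuple pair
    counts, pseudo k-tuple nucleotide composition, and nucleotide
    physicochemical properties) refined by boosted-tree impurity-based
    feature selection, and dynamic semantic features produced by a k-mer
    transformer embedder followed by a convolutional BiLSTM network with
    attention pooling. Final calls are made by a hard-voting ensemble of a
    support vector machine, a random forest, and a cascade (deep) forest.
    Includes evaluation utilities (ACC, MCC, SN, SP, AUC, stratified
    cross-validation, grid search) and a position-weight-matrix based
    simulator that plants motifs in synthetic fragments so the whole
    pipeline can be exercised without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    e1071,
    jsonlite,
    pROC,
    randomForest,
    Rcpp,
    stats,
    tools,
    utils,
    xgboost
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
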
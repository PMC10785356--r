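Package: pathact
Title: Pathway Activity Inference and Robustness Evaluation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers per-sample pathway activity from gene expression matrices
    with seven schemes spanning gene-set methods (signed z-score aggregation,
    all-member z-score, singular-value decomposition, and a Kolmogorov-Smirnov
    -like enrichment walk) and pathway-topology methods built on a directed
    random walk with restart over gene interaction networks (plain,
    edge-reweighted, and entropy-initialised variants). Provides two
    robustness evaluations: cross-validated reproducibility power of
    pathway-level t-statistics with its coefficient of variation, and
    AUC-gated greedy forward selection of pathway markers with naive Bayes,
    k-nearest-neighbour and ridge-logistic classifiers, followed by
    marker-frequency ranking and offline literature-index validation counts.
    Includes readers and writers for GCT, CLS, GMT and SIF files and a
    synthetic benchmark generator that plants differentially expressed genes
    in designated risk pathways.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    e1071,
    class,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    igraph,
    optparse
Config/testthat/edition: 3
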
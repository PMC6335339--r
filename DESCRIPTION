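Package: strucnet
Title: Group Analysis of Structural Brain Connectomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for group-level analysis of streamline-count weighted
    structural brain networks: weighted graph-theory metrics (strength,
    global/local efficiency, characteristic path length, clustering) with
    small-world ratios against degree-preserving random-network nulls;
    covariate-adjusted ANCOVA group statistics with false-discovery-rate
    correction and partial correlations against clinical scores; the
    network-based statistic (NBS) with permutation family-wise error control;
    backbone/hub identification with rich-club, feeder and local edge
    decomposition; F-score-ranked RBF support-vector-machine classification
    under leave-one-out cross-validation with ROC analysis; and a synthetic
    cohort generator that emulates a three-group clinical connectome study
    with planted edge-weight effects for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    e1071,
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
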
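Package: enhancerwalk
Title: Sequence-Based Enhancer Prediction from DNA Random-Walk Features
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts enhancer activity from DNA sequence alone. Sequences
    are encoded as a one-dimensional purine/pyrimidine random walk; the
    feature vector combines overlapping k-mer counts (k = 1..6, 5460
    features) with eight statistical and nonlinear descriptors of the walk
    (standard deviation, detrended fluctuation analysis exponent,
    autocorrelations at lags 100/200/300, sample entropy, rescaled-range
    Hurst exponent, and the distinct-value ratio). Classifiers are PCA
    followed by bagged decision trees or RUSBoost for class-imbalanced
    training sets. Includes FASTA/BED input handling, GC- and
    length-matched null sequence generation, a synthetic labeled-sequence
    simulator, group-comparison reports, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    data.table,
    e1071,
    jsonlite,
    optparse,
    Rcpp,
    rlang,
    rpart,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    pracma,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
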
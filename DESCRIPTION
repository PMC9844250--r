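Package: dircon
Title: Instantaneous Directed Connectivity Estimation from Multivariate
    Time Series via Self-Attention
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Estimates per-timepoint (window-size-1) directed connectivity
    graphs between nodes of multivariate biological time series (e.g. fMRI
    component or ROI time-courses) with an interpretable deep architecture:
    a shared bidirectional LSTM encodes each node's series, per-timepoint
    self-attention yields row-stochastic directed connectivity matrices, a
    global temporal attention module weights timepoints, and a classifier
    operates on the aggregated connectivity matrix alone.  Includes seeded
    fold-wise training with early stopping, vector-autoregressive synthetic
    benchmarks with known directed ground truth, and downstream analyses:
    Pearson-correlation connectivity baselines, regularized logistic
    comparisons, network-block group statistics, dynamic connectivity
    states by k-means, and temporal-attention experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    glmnet,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    jsonlite,
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
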
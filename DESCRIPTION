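Package: tpdcflow
Title: Time-Varying Partial Directed Coherence Analysis of Brain Network Time Series
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Directed functional-connectivity analysis for multivariate
    BOLD-like time series. Estimates time-varying multivariate autoregressive
    models with a dual extended Kalman filter, derives band-averaged temporal
    partial directed coherence (TPDC) matrices, thresholds connections with
    subject-level block-shuffle bootstraps and group-level permutation nulls,
    classifies disease stage from flattened connectivity features with a
    random forest, and correlates connectivity with clinical scores. Includes
    a synthetic cohort generator with known directed coupling templates and
    planted clinical correlations, and a config-driven end-to-end pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    randomForest,
    pROC,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
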
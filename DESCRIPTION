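Package: subsetIV
Title: Best-Subset Selection of Invalid Instruments for Causal Inference
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimation of linear causal effects with instrumental variables
    when an unknown subset of the candidate instruments is invalid (has a
    direct effect on the outcome). Implements a best-subset instrumental
    variable estimator that selects the invalid set under an l0 cardinality
    constraint via a hard-thresholding discrete first-order algorithm with
    exhaustive-enumeration certification and data-driven big-M coefficient
    bounds for mixed-integer formulations, together with comparator
    estimators (OLS, naive and oracle two-stage least squares, a Lasso-type
    selector, and summary-statistic median and mode estimators),
    instrument diagnostics (Sargan J test, first-stage F, signal-to-noise
    calibration), and a seeded Monte Carlo benchmarking harness.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    glmnet,
    jsonlite,
    Rcpp,
    stats,
    utils,
    withr
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
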
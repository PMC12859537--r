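Package: modtune
Title: Modified Cross-Validation and Bootstrap Tuning for Penalized
    Risk Prediction Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for developing clinical risk prediction models with
    binary outcomes when the sample size is close to the recommended
    minimum. Fits logistic regression by maximum likelihood, Firth's
    bias-reduced likelihood with intercept correction, bootstrap uniform
    shrinkage, and Ridge/Lasso penalized likelihood; selects the penalty
    tuning parameter by standard k-fold cross-validation, by a modified
    cross-validation that tunes on bootstrap pseudo-datasets inflated to
    size n*k/(k-1) so every cross-validation training fold has the
    original sample size, and by bootstrap tuning. Includes validation
    metrics (calibration slope and intercept, C-statistic, Brier score,
    root mean square prediction error), a synthetic data generator with
    block-correlated multivariate normal covariates calibrated to a
    target prevalence and C-statistic, and a Monte Carlo simulation
    engine for comparing methods and finding recommended sample sizes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    withr,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    glmnet,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
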
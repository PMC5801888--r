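Package: privlr
Title: Robust Differentially Private Bayesian Linear Regression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Differentially private Bayesian linear regression by Laplace
    perturbation of clipped sufficient statistics. Outliers are projected to
    data-driven bounds before the three sufficient statistics (n*xx, n*xy,
    n*yy) are released under a split epsilon budget, which keeps the noise
    needed for a given privacy level small and makes the estimator
    asymptotically efficient. Includes the conjugate fixed-precision
    posterior, a hierarchical Gamma-prior posterior via Gibbs sampling,
    auxiliary-synthetic-data grid searches for tuning the budget split and
    projection thresholds, generators for synthetic and drug-sensitivity-like
    benchmark data, and a Monte Carlo cross-validation experiment driver.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
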
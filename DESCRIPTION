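Package: sgtlm
Title: Skew Generalized t-Link Mixed Models for Clustered Binary Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Fits generalized linear mixed models for clustered binary
    outcomes with skew generalized t link functions and skew-t distributed
    random effects.  The model family nests the probit, skew-probit,
    t-link and skew-t-link mixed models.  Maximum likelihood estimation
    uses an EM algorithm accelerated by parameter expansion (PX-EM), with
    empirical-information standard errors, empirical Bayes prediction of
    cluster random effects and scale-mixing weights for outlier
    detection, and a Monte Carlo simulation engine for performance
    experiments (bias, RMSE, coverage, information criteria).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    mvtnorm,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    numDeriv,
    pracma,
    jsonlite
Config/testthat/edition: 3
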
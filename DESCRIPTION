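Package: noisestab
Title: Noise-Stability Models for Automatic Item Generation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Measurement models for validating automatic item generators
    under cross-classified (every subject sees every incidental item
    realization) and two-level (incidentals nested in subjects) sampling
    designs. Provides a synthetic response-table simulator with the models'
    exact statistical structure, a blocked conjugate Gibbs sampler for
    Bayesian estimation of both models with free factor loadings,
    variance-decomposition consistency coefficients (RCon, L2Con, L1Con)
    with equal-tailed credibility intervals, posterior predictive checking
    via a likelihood discrepancy, posterior contrasts within and across
    models, Gelman-Rubin convergence diagnostics, and a command-line
    pipeline for end-to-end simulation studies.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    coda
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
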
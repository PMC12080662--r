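Package: emadsem
Title: Residual Dynamic Structural Equation Models for Ecological
    Momentary Assessment Time Series
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and Bayesian analysis of intensive longitudinal
    (ecological momentary assessment) data with a two-level residual
    dynamic structural equation model: a random-intercept cross-lagged
    panel model with first-order autoregressive and cross-lagged paths
    and three alternative specifications of the contemporaneous (lag-0)
    association (undirected residual covariance or a directed path in
    either direction).  Estimation is by Gibbs sampling with
    within-sampler imputation of the missing slots of a uniform hourly
    time grid, with potential-scale-reduction convergence monitoring,
    within-person standardization, deviance information criterion model
    comparison, random slopes and random residual variances, person-level
    moderation with a joint Wald test, and trivariate symptom-split
    models.  Includes an experience-sampling schedule generator, interview
    severity scoring, momentary composite scores, and a synthetic data
    generator matching the assumed data-generating process.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    MASS,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
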
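Package: tpddm
Title: Hierarchical Drift-Diffusion Modelling of Temporal Preparation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and hierarchical Bayesian estimation of two-boundary
    drift-diffusion models for variable-foreperiod reaction-time tasks.
    Provides a synthetic-cohort generator for the blocked 2x2
    foreperiod-duration by foreperiod-variability design with truncated
    Gaussian foreperiods, an exact Wiener first-passage-time likelihood with
    adaptive dual series expansions, Metropolis-within-Gibbs samplers for
    three model variants in which boundary separation and/or drift rate vary
    with temporal predictability, deviance information criterion model
    comparison, Gelman-Rubin diagnostics, posterior predictive checks,
    posterior-overlap group inference, and the companion behavioural analyses
    (median-absolute-deviation outlier filtering, per-subject Poisson and
    linear regressions, group-level frequentist tests).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
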
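Package: cd4cvl
Title: Bayesian Mixed-Effects Modelling of CD4 Response to Antiretroviral
    Therapy with Cumulative Viral Load
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for modelling longitudinal CD4 count response to
    antiretroviral therapy (ART) as a function of cumulative log viral load
    (cVL2), a copy-year metric of exposure to detectable viremia. Provides
    the trapezoidal cVL2 metric with a missing-visit bridging rule; Bayesian
    linear ("slope") and logistic ("asymptote") mixed-effects models with
    quadratic or cubic B-spline time bases and Gaussian or skew-normal
    random effects and errors, fitted by MCMC with within-chain imputation
    of missing baseline covariates and outcomes; informative-prior
    elicitation from published historical estimates; conditional-DIC model
    comparison; Brooks-Gelman-Rubin and Monte Carlo error diagnostics;
    stratified posterior-predictive trajectory summaries; and a synthetic
    cohort generator that emulates a sub-Saharan African ART cohort for
    calibration and testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    rjags,
    coda,
    splines,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
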
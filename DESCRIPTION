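Package: utkmipd
Title: Model-Informed Precision Dosing for Ustekinumab in Plaque Psoriasis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Population pharmacokinetic/pharmacodynamic modelling and
    model-informed precision dosing (MIPD) of subcutaneous ustekinumab in
    moderate-to-severe plaque psoriasis. Implements an analytic two-compartment
    first-order-absorption PK model, an indirect-response PASI turnover model
    with Imax inhibition of lesion progression, marginal maximum-likelihood
    nonlinear mixed-effects estimation of the population PD parameters with
    the B2 baseline method, Metropolis-Hastings sampling of individual
    conditional parameter distributions, clone-based stochastic simulation of
    candidate dosing regimens, probability-of-target computation for absolute
    PASI <= 1, dose-regimen selection under a 90% attainment rule, annual drug
    cost arithmetic, and a synthetic-cohort generator so the whole pipeline is
    testable without patient-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
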
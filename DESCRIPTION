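Package: vancneo
Title: Population Pharmacokinetics and Dose Optimisation of Vancomycin in
    Very-Low-Birth-Weight Neonates
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for population pharmacokinetic analysis of vancomycin in
    very-low-birth-weight (VLBW) neonates built around a one-compartment
    intravenous-infusion model with allometric weight scaling, sigmoidal
    postmenstrual-age maturation of clearance and a serum-creatinine effect.
    Provides a virtual-cohort generator with reference-guided neonatal dosing
    and sparse steady-state trough sampling, Laplace-approximation nonlinear
    mixed-effects estimation with likelihood-ratio covariate selection and
    bootstrap uncertainty, visual predictive check and normalized prediction
    distribution error diagnostics, and a Monte Carlo dosing engine that
    tabulates probability of target attainment by postmenstrual-age and
    creatinine subgroup and emits dose recommendations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    graphics,
    jsonlite,
    MASS,
    stats,
    tools,
    utils,
    yaml
Suggests:
    deSolve,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
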
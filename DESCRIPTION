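Package: gabapk
Title: Population Pharmacokinetics of Gabapentin from Therapeutic Drug
    Monitoring Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Nonlinear mixed-effects modelling of sparse gabapentin
    therapeutic drug monitoring (TDM) concentrations. Implements a
    one-compartment oral model with saturable dose-dependent
    bioavailability, a stochastic approximation EM (SAEM) estimation
    engine with importance-sampling and adaptive Gauss-Hermite
    likelihoods, clinical-question-ordered stepwise covariate selection,
    nonparametric bootstrap and visual predictive checks, and a
    synthetic TDM cohort generator for simulation-based validation.
    Includes clinical covariate calculators (Devine ideal body weight,
    Janmahasatian lean body weight, MDRD eGFR, Cockcroft-Gault
    creatinine clearance, acute kidney injury and obesity flags).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    deSolve,
    ggplot2,
    jsonlite,
    pracma,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
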
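Package: frailsim
Title: Individual-Level Microsimulation for Frailty Cost-Effectiveness Modelling
Version: 0.1.0
Authors@R: person("frailsim", "developers", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for building and exercising an individual-level
    discrete-time state-transition model of frailty progression in older
    people. Includes a Delphi consensus classifier for selecting model
    health events and patient attributes, frailty measurement (deficit
    accumulation index and physical phenotype), logistic per-cycle risk
    equations with maximum-likelihood fitting and parameter recovery,
    a microsimulation engine with event memory and common random numbers,
    health-economic outputs (discounted QALYs, costs, ICERs, probabilistic
    sensitivity analysis with cost-effectiveness acceptability curves), a
    synthetic longitudinal ageing-panel generator, and a Markov cohort
    oracle for cross-model validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
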
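# Illustrative ground-truth parameters for the consensus structure. These are
# the synthetic world's "true" values used by the panel generator, the
# worked examples and the tests; they are plausible in sign and rough
# magnitude (risks rise with age, frailty and event history; death risk has a
# log-linear age term so mortality grows over a lifetime horizon) but are not
# estimates from any dataset.

#' Illustrative risk parameters for the default structure
#'
#' Per-cycle logistic risk equations for the seven consensus events and a
#' frailty transition matrix with predominantly forward (worsening) drift.
#' Frailty enters as phenotype-category indicators; hip fracture and hospital
#' admission risks carry their history-counter terms (the model's memory).
#'
#' @return a [risk_params()] covering [default_structure()].
#' @export
default_risk_params <- function() {
  eqs <- list(
    death = risk_equation("death", c(
      "(Intercept)" = -10.0, age = 0.095,
      frailty_pre_frail = 0.35, frailty_frail = 0.9)),
    hip_fracture = risk_equation("hip_fracture", c(
      "(Intercept)" = -7.5, age = 0.04, gender = 0.3,
      frailty_pre_frail = 0.4, frailty_frail = 0.9,
      previous_fractures = 0.6)),
    falls = risk_equation("falls", c(
      "(Intercept)" = -4.5, age = 0.03,
      frailty_pre_frail = 0.5, frailty_frail = 1.1)),
    residential_care = risk_equation("residential_care", c(
      "(Intercept)" = -9.0, age = 0.07,
      frailty_pre_frail = 0.5, frailty_frail = 1.3)),
    hospital_admission = risk_equation("hospital_admission", c(
      "(Intercept)" = -5.0, age = 0.035,
      frailty_pre_frail = 0.45, frailty_frail = 1.0,
      previous_hospital_admissions = 0.35)),
    physical_disability = risk_equation("physical_disability", c(
      "(Intercept)" = -7.0, age = 0.05,
      frailty_pre_frail = 0.6, frailty_frail = 1.4)),
    delirium = risk_equation("delirium", c(
      "(Intercept)" = -6.5, age = 0.04,
      frailty_pre_frail = 0.5, frailty_frail = 1.2)))
  trans <- frailty_transition_model(rbind(
    c(0.85, 0.13, 0.02),
    c(0.08, 0.77, 0.15),
    c(0.01, 0.07, 0.92)))
  risk_params(eqs, trans)
}
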
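# Shared fixtures: a reduced "mini world" (three events, four attributes)
# with ground-truth coefficients inside [-2, 2], used for parameter-recovery
# and validation-loop tests, plus small builders for Delphi responses.

mini_structure <- function() {
  model_structure(
    events = list(
      health_event("fall", "recurrent", history_counter = "prev_falls"),
      health_event("admission", "recurrent"),
      health_event("death", "absorbing")),
    attributes = list(
      patient_attribute("age", "continuous", time_varying = TRUE),
      patient_attribute("gender", "binary"),
      patient_attribute("frailty_status", "categorical", time_varying = TRUE),
      patient_attribute("prev_falls", "count", time_varying = TRUE)),
    edges = data.frame(
      attribute = c("frailty_status", "frailty_status", "frailty_status",
                    "gender", "prev_falls", "gender"),
      event = c("fall", "admission", "death", "fall", "fall", "admission")))
}

mini_params <- function() {
  risk_params(
    equations = list(
      death = risk_equation("death", c(
        "(Intercept)" = -2.0, frailty_pre_frail = 0.3, frailty_frail = 0.7)),
      fall = risk_equation("fall", c(
        "(Intercept)" = -1.5, gender = 0.5, frailty_pre_frail = 0.4,
        frailty_frail = 0.8, prev_falls = 0.6)),
      admission = risk_equation("admission", c(
        "(Intercept)" = -1.8, gender = 0.4, frailty_pre_frail = 0.3,
        frailty_frail = 0.9))),
    frailty_model = frailty_transition_model(rbind(
      c(0.80, 0.15, 0.05),
      c(0.10, 0.70, 0.20),
      c(0.05, 0.15, 0.80))))
}

mini_cohort_spec <- function(n, seed = NULL) {
  cohort_spec(
    n = n,
    marginals = list(
      age = marginal("uniform", min = 65, max = 90),
      gender = marginal("binary", p = 0.5),
      frailty_status = marginal("categorical", levels = frailty_levels,
                                probs = c(0.40, 0.35, 0.25)),
      prev_falls = marginal("poisson", lambda = 0.3)),
    seed = seed)
}

mini_cohort <- function(n, seed = NULL) generate_cohort(mini_cohort_spec(n, seed))

# a single-absorbing-state world with a constant per-cycle death probability
death_only_structure <- function() {
  model_structure(
    events = list(health_event("death", "absorbing")),
    attributes = list(
      patient_attribute("age", "continuous", time_varying = TRUE),
      patient_attribute("frailty_status", "categorical", time_varying = TRUE)),
    edges = data.frame(attribute = "frailty_status", event = "death"))
}

death_only_params <- function(q) {
  risk_params(list(death = risk_equation("death", c("(Intercept)" = qlogis(q)))),
              frailty_transition_model(diag(3)))
}

constant_cohort <- function(n, age = 65, frailty = "non_frail") {
  data.frame(age = rep(age, n), frailty_status = rep(frailty, n))
}

illustrative_um_mini <- function() {
  utility_model(baseline = c(non_frail = 0.85, pre_frail = 0.70, frail = 0.50),
                event_decrements = c(fall = 0.90, admission = 0.85))
}

illustrative_cm_mini <- function() {
  cost_model(event_costs = c(fall = 1000, admission = 5000),
             frailty_costs = c(non_frail = 200, pre_frail = 800, frail = 2500))
}

# Delphi response-table builder: one row per panellist score
make_responses <- function(...) {
  specs <- list(...)
  rows <- lapply(specs, function(sp) {
    do.call(rbind, lapply(names(sp$scores), function(key) {
      parts <- strsplit(key, "_r")[[1]]
      data.frame(choice_name = sp$name, choice_kind = sp$kind,
                 aspect = parts[1], panellist_id = seq_along(sp$scores[[key]]),
                 round = as.integer(parts[2]), score = sp$scores[[key]])
    }))
  })
  do.call(rbind, rows)
}

# canonical 9-member score vectors for each agreement band
scores_acceptable <- c(5, 5, 5, 4, 4, 4, 4, 4, 5)       # mean 4.44, frac 1
scores_moderate <- c(4, 4, 4, 4, 4, 4, 3, 3, 3)         # mean 3.67, frac 6/9
scores_unacceptable <- c(2, 2, 2, 3, 3, 2, 1, 1, 2)     # mean 2.0, frac 0
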
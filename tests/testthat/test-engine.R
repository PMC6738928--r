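test_that("no-risk limit: everyone survives to max_age with full life-years", {
  co <- constant_cohort(20, age = 65)
  sim <- simulate_cohort(co, death_only_structure(), death_only_params(1e-15),
                         scenario(), sim_config(seed = 1, max_age = 110))
  expect_true(all(is.na(sim$death_cycle)))
  expect_true(all(sim$life_years == 45))
})

test_that("certain death: exactly one cycle recorded", {
  co <- constant_cohort(10)
  p <- risk_params(list(death = risk_equation("death", c("(Intercept)" = 40))),
                   frailty_transition_model(diag(3)))
  sim <- simulate_cohort(co, death_only_structure(), p,
                         scenario(), sim_config(seed = 1))
  expect_true(all(sim$cycles_entered == 1))
  expect_true(all(sim$death_cycle == 1))
  expect_true(all(sim$life_years == 0))
  traj <- trajectory(sim, 3)
  expect_equal(nrow(traj), 1)
  expect_true(traj$died)
})

test_that("geometric closed form: mean cycles survived is 1/q", {
  n <- 20000
  q <- 0.25
  sim <- simulate_cohort(constant_cohort(n), death_only_structure(),
                         death_only_params(q), scenario(),
                         sim_config(seed = 2, max_age = 110))
  mc_se <- sd(sim$cycles_entered) / sqrt(n)
  expect_lt(abs(mean(sim$cycles_entered) - 1 / q), 3 * mc_se)
})

test_that("a sampled event increments its history counter by exactly one", {
  co <- mini_cohort(300, seed = 81)
  sim <- simulate_cohort(co, mini_structure(), mini_params(), scenario(),
                         sim_config(n_cycles = 8, seed = 82, max_age = 1e6))
  hits <- 0
  for (i in seq_len(sim$n)) {
    traj <- trajectory(sim, i)
    lived <- which(!traj$died)
    for (t in lived[-length(lived)]) {
      expect_equal(traj$prev_falls[t + 1] - traj$prev_falls[t],
                   as.numeric(traj$fall[t]))
      hits <- hits + traj$fall[t]
    }
    if (i > 50 && hits > 20) break
  }
  expect_gt(hits, 0)  # the assertion above actually exercised fall cycles
})

test_that("memory: prior fractures raise the modelled fracture risk", {
  eq <- mini_params()$equations$fall  # prev_falls coefficient 0.6 > 0
  s0 <- c(gender = 1, frailty_pre_frail = 0, frailty_frail = 1, prev_falls = 0)
  s1 <- replace(s0, "prev_falls", 1)
  expect_gt(cycle_probability(linear_predictor(eq, s1)),
            cycle_probability(linear_predictor(eq, s0)))
  # and realised in simulation: fall rate is higher among those with history
  co <- mini_cohort(4000, seed = 91)
  pn <- generate_panel(co, mini_structure(), mini_params(), waves = 6, seed = 92)
  surv <- pn[pn$death == 0, ]
  r_hist <- mean(surv$fall[surv$prev_falls >= 1])
  r_none <- mean(surv$fall[surv$prev_falls == 0])
  expect_gt(r_hist, r_none)
})

test_that("conservation: every individual is in exactly one state per cycle", {
  co <- mini_cohort(500, seed = 95)
  sim <- simulate_cohort(co, mini_structure(), mini_params(), scenario(),
                         sim_config(n_cycles = 10, seed = 96, max_age = 1e6))
  dead_so_far <- rep(FALSE, sim$n)
  for (t in seq_len(sim$n_cycles)) {
    expect_equal(sum(sim$entered[, t]) + sum(dead_so_far), sim$n)
    expect_true(all(sim$frailty[sim$entered[, t], t] %in% 1:3))
    dead_so_far <- dead_so_far | sim$died[, t]
  }
})

test_that("same seed reproduces identical aggregates; MC error scales as 1/sqrt(n)", {
  co <- mini_cohort(400, seed = 97)
  cfg <- sim_config(n_cycles = 5, seed = 98, max_age = 1e6)
  s1 <- simulate_cohort(co, mini_structure(), mini_params(), scenario(), cfg)
  s2 <- simulate_cohort(co, mini_structure(), mini_params(), scenario(), cfg)
  expect_identical(s1$life_years, s2$life_years)
  expect_identical(s1$events$fall, s2$events$fall)

  se_at <- function(n) {
    sim <- simulate_cohort(constant_cohort(n), death_only_structure(),
                           death_only_params(0.25), scenario(),
                           sim_config(seed = 99, max_age = 110))
    sd(sim$cycles_entered) / sqrt(n)
  }
  ratio <- se_at(2000) / se_at(8000)
  expect_gt(ratio, 1.6)  # doubling-twice should roughly double precision
  expect_lt(ratio, 2.5)
})

test_that("validation errors: missing attributes, empty cohort, bad frailty", {
  co <- mini_cohort(5, seed = 1)
  expect_error(simulate_cohort(co[, setdiff(names(co), "gender")],
                               mini_structure(), mini_params()),
               "lacks attributes")
  expect_error(simulate_cohort(co[0, ], mini_structure(), mini_params()),
               "non-empty")
  bad <- co; bad$frailty_status <- "very_frail"
  expect_error(simulate_cohort(bad, mini_structure(), mini_params()),
               "frailty_status")
  p <- mini_params(); p$equations$fall <- NULL
  expect_error(simulate_cohort(co, mini_structure(), p), "lack equations")
})

test_that("self-comparison under common random numbers is exactly zero", {
  co <- mini_cohort(300, seed = 101)
  cmp <- run_comparison(co, mini_structure(), mini_params(),
                        scenario("usual_care"), scenario("usual_care_too"),
                        illustrative_um_mini(), illustrative_cm_mini(),
                        sim_config(n_cycles = 10, seed = 102, max_age = 1e6))
  expect_identical(cmp$incremental$delta_cost, 0)
  expect_identical(cmp$incremental$delta_qaly, 0)
  expect_equal(cmp$incremental$label, "equal effectiveness")
  expect_true(is.na(cmp$incremental$icer))
})

test_that("halving worsening transitions does not lower QALYs", {
  co <- mini_cohort(2000, seed = 103)
  intervention <- scenario("frailty_program", intervention = TRUE,
                           worsening_multiplier = 0.5)
  cmp <- run_comparison(co, mini_structure(), mini_params(),
                        scenario(), intervention,
                        illustrative_um_mini(), illustrative_cm_mini(),
                        sim_config(n_cycles = 10, seed = 104, max_age = 1e6),
                        discount_rate = 0)
  expect_gte(cmp$incremental$delta_qaly, -3 * cmp$incremental$se_delta_qaly)
})

test_that("zero-effect intervention with one-off cost: incremental cost is discounted cost", {
  co <- mini_cohort(250, seed = 105)
  priced <- scenario("priced", intervention = TRUE, one_off_cost = 1234)
  cmp <- run_comparison(co, mini_structure(), mini_params(),
                        scenario(), priced,
                        illustrative_um_mini(), illustrative_cm_mini(),
                        sim_config(n_cycles = 6, seed = 106, max_age = 1e6))
  expect_equal(cmp$incremental$delta_cost, 1234)  # charged at t = 0
  expect_identical(cmp$incremental$delta_qaly, 0)
})

test_that("two-cycle expectation matches exhaustive path enumeration", {
  # memoryless 3-category world; enumeration over (death, transition) paths
  u <- c(non_frail = 0.8, pre_frail = 0.6, frail = 0.4)
  q <- c(0.05, 0.10, 0.20)
  Tm <- rbind(c(0.7, 0.25, 0.05), c(0.1, 0.6, 0.3), c(0.05, 0.15, 0.8))
  expected_qalys <- function(c0, worsen = 1) {
    Teff <- frailsim:::effective_transition_matrix(
      frailty_transition_model(Tm), worsening_multiplier = worsen)
    (1 - q[c0]) * (u[c0] + sum(Teff[c0, ] * (1 - q) * u))
  }
  params <- risk_params(
    list(death = risk_equation("death", c(
      "(Intercept)" = qlogis(q[1]),
      frailty_pre_frail = qlogis(q[2]) - qlogis(q[1]),
      frailty_frail = qlogis(q[3]) - qlogis(q[1])))),
    frailty_transition_model(Tm))
  um <- utility_model(baseline = u)
  cm <- cost_model()
  for (worsen in c(1, 0.5)) {
    scen <- scenario("s", worsening_multiplier = worsen)
    n <- 40000
    sim <- simulate_cohort(constant_cohort(n, frailty = "pre_frail"),
                           death_only_structure(), params, scen,
                           sim_config(n_cycles = 2, seed = 107, max_age = 1e6))
    got <- cohort_outcomes(sim, um, cm, rate = 0)
    want <- expected_qalys(2, worsen)
    mc_se <- sd(got$qalys) / sqrt(n)
    expect_lt(abs(got$mean_qalys - want), 3 * mc_se)
  }
  # enumeration itself confirms stochastic dominance of the intervention
  expect_gt(expected_qalys(2, 0.5), expected_qalys(2, 1))
})
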
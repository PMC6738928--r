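test_that("discount factor identities", {
  expect_equal(discount_factor(5, 0), 1)
  expect_equal(discount_factor(0, 0.07), 1)
  expect_equal(discount_factor(1, 0.05), 1 / 1.05)
  expect_equal(discount_factor(2, 0.05), 1.05^-2)
  expect_error(discount_factor(-1, 0.05), "non-negative")
  expect_error(discount_factor(1, -1), "exceed -1")
})

make_traj <- function(frailty, died, ...) {
  n <- length(frailty)
  traj <- data.frame(cycle = seq_len(n) - 1L, age = 70 + seq_len(n) - 1,
                     frailty = frailty, died = died)
  extra <- list(...)
  for (nm in names(extra)) traj[[nm]] <- extra[[nm]]
  traj
}

test_that("QALY accrual: one full-health year is one QALY; linear in utility", {
  um1 <- utility_model(baseline = c(non_frail = 1, pre_frail = 1, frail = 1))
  traj <- make_traj("non_frail", FALSE)
  expect_equal(accrue_qalys(traj, um1, rate = 0), 1)

  um5 <- utility_model(baseline = c(non_frail = 0.5, pre_frail = 0.5, frail = 0.5))
  traj2 <- make_traj(c("non_frail", "non_frail"), c(FALSE, FALSE))
  expect_equal(accrue_qalys(traj2, um5, rate = 0), 1)

  # QALYs never exceed undiscounted life-years
  um <- illustrative_utilities()
  traj3 <- make_traj(c("frail", "frail", "frail"), c(FALSE, FALSE, TRUE))
  expect_lte(accrue_qalys(traj3, um, rate = 0), 2)

  # monotone: raising one cycle's utility never lowers the total
  umlow <- utility_model(baseline = c(non_frail = 0.9, pre_frail = 0.6, frail = 0.3))
  mixed <- make_traj(c("frail", "pre_frail"), c(FALSE, FALSE))
  raised <- make_traj(c("pre_frail", "pre_frail"), c(FALSE, FALSE))
  expect_gte(accrue_qalys(raised, umlow, 0), accrue_qalys(mixed, umlow, 0))
})

test_that("event decrements and discounting combine multiplicatively", {
  um <- utility_model(baseline = c(non_frail = 0.8, pre_frail = 0.7, frail = 0.6),
                      event_decrements = c(fall = 0.5))
  traj <- make_traj(c("non_frail", "non_frail"), c(FALSE, FALSE),
                    fall = c(TRUE, FALSE))
  expect_equal(accrue_qalys(traj, um, rate = 0), 0.8 * 0.5 + 0.8)
  expect_equal(accrue_qalys(traj, um, rate = 0.05),
               0.8 * 0.5 + 0.8 / 1.05)
})

test_that("cost accrual: one-offs, state costs, discount arithmetic", {
  cm <- cost_model(event_costs = c(fall = 100),
                   frailty_costs = c(non_frail = 0, pre_frail = 0, frail = 0))
  t0 <- make_traj("non_frail", FALSE, fall = TRUE)
  expect_equal(accrue_costs(t0, cm, rate = 0), 100)
  expect_equal(accrue_costs(make_traj("non_frail", FALSE, fall = FALSE), cm,
                            rate = 0), 0)
  # event at start of year 2 discounted two years
  t2 <- make_traj(rep("non_frail", 3), rep(FALSE, 3), fall = c(FALSE, FALSE, TRUE))
  expect_equal(accrue_costs(t2, cm, rate = 0.05), 100 * 1.05^-2)
  # discounted totals never exceed undiscounted for non-negative flows
  cmfull <- illustrative_cm_mini()
  t3 <- make_traj(rep("frail", 4), rep(FALSE, 4), fall = c(TRUE, FALSE, TRUE, FALSE))
  expect_lte(accrue_costs(t3, cmfull, scenario(), rate = 0.05),
             accrue_costs(t3, cmfull, scenario(), rate = 0))
})

test_that("per-trajectory and cohort-level accrual agree", {
  co <- mini_cohort(60, seed = 121)
  sim <- simulate_cohort(co, mini_structure(), mini_params(), scenario(),
                         sim_config(n_cycles = 6, seed = 122, max_age = 1e6))
  um <- illustrative_um_mini(); cm <- illustrative_cm_mini()
  out <- cohort_outcomes(sim, um, cm, rate = 0.05)
  for (i in c(1, 7, 23, 60)) {
    traj <- trajectory(sim, i)
    expect_equal(out$qalys[i], accrue_qalys(traj, um, rate = 0.05))
    expect_equal(out$costs[i], accrue_costs(traj, cm, scenario(), rate = 0.05))
  }
})

test_that("utility model validates combined range", {
  expect_error(utility_model(baseline = c(non_frail = 1.2, pre_frail = 1, frail = 1)),
               "lie in")
  expect_error(cost_model(event_costs = c(fall = -5)), "non-negative")
})

test_that("incremental analysis quadrants and guards", {
  a <- list(costs = rep(1000, 4), qalys = rep(2, 4))
  b <- list(costs = rep(2000, 4), qalys = rep(2.5, 4))
  inc <- incremental_analysis(a, b)
  expect_equal(inc$icer, 2000)
  expect_equal(inc$label, "tradeoff")

  dom <- incremental_analysis(a, list(costs = rep(990, 4), qalys = rep(2.1, 4)))
  expect_equal(dom$label, "dominant")
  ded <- incremental_analysis(a, list(costs = rep(1010, 4), qalys = rep(1.9, 4)))
  expect_equal(ded$label, "dominated")

  same <- incremental_analysis(a, a)
  expect_equal(same$delta_cost, 0)
  expect_equal(same$delta_qaly, 0)
  expect_equal(same$label, "equal effectiveness")
  expect_true(is.na(same$icer))
})

test_that("PSA: degenerate distributions reproduce the deterministic result", {
  co <- mini_cohort(150, seed = 131)
  cfg <- sim_config(n_cycles = 5, seed = 132, max_age = 1e6)
  um <- illustrative_um_mini(); cm <- illustrative_cm_mini()
  intervention <- scenario("i", TRUE, worsening_multiplier = 0.6, one_off_cost = 500)
  det <- run_comparison(co, mini_structure(), mini_params(), scenario(),
                        intervention, um, cm, cfg)
  spec <- list(
    psa_param("coefficient", "fixed", value = -1.5, event = "fall",
              covariate = "(Intercept)"),
    psa_param("utility", "fixed", value = 0.70, category = "pre_frail"),
    psa_param("cost", "fixed", value = 1000, event = "fall"))
  psa <- run_psa(co, mini_structure(), mini_params(), scenario(), intervention,
                 um, cm, spec, n_draws = 5, thresholds = c(0, 50000), config = cfg)
  expect_equal(unique(psa$draws$delta_cost), det$incremental$delta_cost)
  expect_equal(unique(psa$draws$delta_qaly), det$incremental$delta_qaly)
})

test_that("CEAC matches a brute-force recount and stays in [0, 1]", {
  co <- mini_cohort(120, seed = 141)
  cfg <- sim_config(n_cycles = 4, seed = 142, max_age = 1e6)
  intervention <- scenario("i", TRUE, worsening_multiplier = 0.6, one_off_cost = 800)
  spec <- list(
    psa_param("coefficient", "normal", mean = -1.5, sd = 0.3,
              event = "fall", covariate = "(Intercept)"),
    psa_param("utility", "beta", shape1 = 70, shape2 = 30, category = "pre_frail"),
    psa_param("cost", "gamma", shape = 4, rate = 0.004, event = "fall"))
  thresholds <- seq(0, 80000, by = 20000)
  psa <- run_psa(co, mini_structure(), mini_params(), scenario(), intervention,
                 illustrative_um_mini(), illustrative_cm_mini(), spec,
                 n_draws = 20, thresholds = thresholds, config = cfg)
  for (k in seq_along(thresholds)) {
    recount <- mean(thresholds[k] * psa$draws$delta_qaly - psa$draws$delta_cost > 0)
    expect_equal(psa$ceac$prob_cost_effective[k], recount)
  }
  expect_true(all(psa$ceac$prob_cost_effective >= 0 &
                  psa$ceac$prob_cost_effective <= 1))
  expect_error(psa_param("utility", "beta", shape1 = -1, shape2 = 2,
                         category = "frail"), "invalid distribution")
})
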
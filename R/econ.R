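# Health-economic outputs: discounted QALYs and costs from trajectories,
# incremental cost-effectiveness, probabilistic sensitivity analysis.

#' Discount factor
#'
#' @param t time in years from model start.
#' @param rate annual discount rate (> -1).
#' @return `(1 + rate)^(-t)`.
#' @export
discount_factor <- function(t, rate) {
  if (any(t < 0)) stop("t must be non-negative", call. = FALSE)
  if (rate <= -1) stop("rate must exceed -1", call. = FALSE)
  (1 + rate)^(-t)
}

#' Utility model
#'
#' Cycle utility is the baseline utility of the individual's frailty category
#' multiplied by the decrement of every event experienced that cycle and the
#' multiplier of every persistent state occupied at cycle start. All inputs
#' lie in \[0, 1\], so the combined utility does too (multiplicative
#' combination, floored at 0). One full year at utility 1 accrues exactly one
#' QALY.
#'
#' @param baseline named utilities for `non_frail`, `pre_frail`, `frail`.
#' @param event_decrements named multiplicative decrements per event
#'   occurrence (in \[0, 1\]).
#' @param state_multipliers named multipliers per persistent state
#'   (names `state_<event>`, in \[0, 1\]).
#' @return object of class `utility_model`.
#' @export
utility_model <- function(baseline, event_decrements = numeric(0),
                          state_multipliers = numeric(0)) {
  stopifnot(all(frailty_levels %in% names(baseline)))
  vals <- c(baseline, event_decrements, state_multipliers)
  if (any(vals < 0) || any(vals > 1))
    stop("utilities, decrements and multipliers must lie in [0, 1]", call. = FALSE)
  structure(list(baseline = baseline[frailty_levels],
                 event_decrements = event_decrements,
                 state_multipliers = state_multipliers),
            class = "utility_model")
}

#' Cost model
#'
#' @param event_costs named one-off costs per event occurrence.
#' @param state_costs named annual costs per persistent state occupied
#'   (names `state_<event>`).
#' @param frailty_costs named annual costs per frailty category.
#' @return object of class `cost_model`. Currency-unit agnostic.
#' @export
cost_model <- function(event_costs = numeric(0), state_costs = numeric(0),
                       frailty_costs = c(non_frail = 0, pre_frail = 0, frail = 0)) {
  if (any(c(event_costs, state_costs, frailty_costs) < 0))
    stop("costs must be non-negative", call. = FALSE)
  stopifnot(all(frailty_levels %in% names(frailty_costs)))
  structure(list(event_costs = event_costs, state_costs = state_costs,
                 frailty_costs = frailty_costs[frailty_levels]),
            class = "cost_model")
}

#' Illustrative utility and cost inputs
#'
#' Placeholder (synthetic) values for demonstration and testing only; no
#' published utilities or unit costs stand behind them.
#' @return a [utility_model()] / [cost_model()].
#' @export
illustrative_utilities <- function() {
  utility_model(
    baseline = c(non_frail = 0.85, pre_frail = 0.75, frail = 0.60),
    event_decrements = c(hip_fracture = 0.80, falls = 0.95,
                         hospital_admission = 0.90, delirium = 0.85,
                         residential_care = 0.95, physical_disability = 0.90),
    state_multipliers = c(state_residential_care = 0.90,
                          state_physical_disability = 0.85))
}

#' @rdname illustrative_utilities
#' @export
illustrative_costs <- function() {
  cost_model(
    event_costs = c(hip_fracture = 25000, falls = 1200,
                    hospital_admission = 6000, delirium = 4000,
                    residential_care = 5000, physical_disability = 2000),
    state_costs = c(state_residential_care = 45000,
                    state_physical_disability = 8000),
    frailty_costs = c(non_frail = 500, pre_frail = 1500, frail = 4000))
}

traj_time <- function(cycle, cycle_length, half_cycle) {
  (cycle + if (half_cycle) 0.5 else 0) * cycle_length
}

combined_utility_row <- function(row, um) {
  u <- um$baseline[[row$frailty]]
  for (e in names(um$event_decrements))
    if (!is.null(row[[e]]) && isTRUE(row[[e]] == 1 || isTRUE(row[[e]])))
      u <- u * um$event_decrements[[e]]
  for (s in names(um$state_multipliers))
    if (!is.null(row[[s]]) && row[[s]] == 1) u <- u * um$state_multipliers[[s]]
  u
}

#' Discounted QALYs of one trajectory
#'
#' Sums `cycle_length x combined utility x discount factor` over the cycles
#' lived (the death cycle accrues nothing: death occurs at cycle start).
#'
#' @param traj trajectory data frame from [simulate_individual()].
#' @param um a [utility_model()].
#' @param rate annual discount rate.
#' @param half_cycle discount at cycle midpoints.
#' @return discounted QALYs.
#' @export
accrue_qalys <- function(traj, um, rate = 0, half_cycle = FALSE) {
  stopifnot(inherits(um, "utility_model"))
  lived <- traj[!traj$died, , drop = FALSE]
  if (nrow(lived) == 0) return(0)
  cl <- if (nrow(traj) > 1) diff(traj$age)[1] else 1
  u <- vapply(seq_len(nrow(lived)), function(r)
    combined_utility_row(lived[r, ], um), numeric(1))
  if (any(u < 0) || any(u > 1))
    stop("combined utility outside [0, 1]; check model inputs", call. = FALSE)
  sum(cl * u * discount_factor(traj_time(lived$cycle, cl, half_cycle), rate))
}

#' Discounted costs of one trajectory
#'
#' Event one-off costs, annual frailty-category and persistent-state costs,
#' and scenario intervention costs (one-off at model start, per cycle lived),
#' each discounted at its accrual time.
#'
#' @param traj trajectory data frame.
#' @param cm a [cost_model()].
#' @param scen the [scenario()] the trajectory was simulated under.
#' @param rate annual discount rate.
#' @param half_cycle discount at cycle midpoints.
#' @return discounted total cost.
#' @export
accrue_costs <- function(traj, cm, scen = scenario(), rate = 0, half_cycle = FALSE) {
  stopifnot(inherits(cm, "cost_model"))
  lived <- traj[!traj$died, , drop = FALSE]
  cl <- if (nrow(traj) > 1) diff(traj$age)[1] else 1
  total <- scen$one_off_cost
  if (nrow(lived)) {
    df <- discount_factor(traj_time(lived$cycle, cl, half_cycle), rate)
    percyc <- cm$frailty_costs[lived$frailty] * cl + scen$per_cycle_cost
    for (e in names(cm$event_costs))
      if (e %in% names(lived)) percyc <- percyc + cm$event_costs[[e]] * (lived[[e]] * 1)
    for (s in names(cm$state_costs))
      if (s %in% names(lived)) percyc <- percyc + cm$state_costs[[s]] * lived[[s]] * cl
    total <- total + sum(percyc * df)
  }
  unname(total)
}

#' Discounted cohort outcomes from a simulation run
#'
#' Vectorised accrual over the trace matrices: per-individual discounted
#' QALYs and costs, cohort means and Monte-Carlo standard errors. Agrees
#' with summing [accrue_qalys()] / [accrue_costs()] over per-individual
#' trajectories.
#'
#' @param sim a `frail_sim` from [simulate_cohort()].
#' @param um a [utility_model()].
#' @param cm a [cost_model()].
#' @param rate annual discount rate applied to both costs and effects.
#' @return list with `qalys`, `costs`, `life_years` vectors and their means
#'   and standard errors.
#' @export
cohort_outcomes <- function(sim, um, cm, rate = 0.05) {
  stopifnot(inherits(sim, "frail_sim"), inherits(um, "utility_model"),
            inherits(cm, "cost_model"))
  n <- sim$n; C <- sim$n_cycles; cl <- sim$cycle_length
  half <- isTRUE(sim$config$half_cycle_correction)
  scen <- sim$scenario
  qaly <- numeric(n)
  cost <- rep(scen$one_off_cost, n)
  for (t in seq_len(C)) {
    livedt <- sim$entered[, t] & !sim$died[, t]
    if (!any(livedt)) next
    dfac <- discount_factor(traj_time(t - 1L, cl, half), rate)
    u <- um$baseline[sim$frailty[, t]]
    ccyc <- cm$frailty_costs[sim$frailty[, t]] * cl + scen$per_cycle_cost
    for (e in names(sim$events)) {
      occ <- sim$events[[e]][, t]
      if (e %in% names(um$event_decrements))
        u <- ifelse(occ, u * um$event_decrements[[e]], u)
      if (e %in% names(cm$event_costs))
        ccyc <- ccyc + cm$event_costs[[e]] * occ
    }
    for (s in names(sim$states)) {
      on <- !is.na(sim$states[[s]][, t]) & sim$states[[s]][, t] == 1
      if (s %in% names(um$state_multipliers))
        u <- ifelse(on, u * um$state_multipliers[[s]], u)
      if (s %in% names(cm$state_costs))
        ccyc <- ccyc + cm$state_costs[[s]] * on * cl
    }
    qaly <- qaly + ifelse(livedt, cl * u * dfac, 0)
    cost <- cost + ifelse(livedt, ccyc * dfac, 0)
  }
  list(scenario = scen$name, qalys = unname(qaly), costs = unname(cost),
       life_years = sim$life_years,
       mean_qalys = mean(qaly), mean_costs = mean(cost),
       se_qalys = stats::sd(qaly) / sqrt(n), se_costs = stats::sd(cost) / sqrt(n))
}

#' Incremental cost-effectiveness analysis
#'
#' @param results_a comparator outcomes (a list with `costs` and `qalys`
#'   vectors, e.g. from [run_comparison()]'s per-scenario slots).
#' @param results_b intervention outcomes.
#' @param paired treat per-individual outcomes as paired (common random
#'   numbers) when computing Monte-Carlo errors.
#' @return list of class `ce_results`: `delta_cost`, `delta_qaly`, their MC
#'   standard errors, `icer` (NA when incremental QALYs are zero) and a
#'   `label`: `"dominant"` (cheaper, more effective), `"dominated"` (dearer,
#'   less effective), `"equal effectiveness"` (zero QALY difference, no ICER)
#'   or `"tradeoff"`.
#' @export
incremental_analysis <- function(results_a, results_b, paired = TRUE) {
  ca <- results_a$costs; cb <- results_b$costs
  qa <- results_a$qalys; qb <- results_b$qalys
  if (paired && length(ca) != length(cb))
    stop("paired analysis requires cohorts of identical size", call. = FALSE)
  dc <- mean(cb) - mean(ca)
  dq <- mean(qb) - mean(qa)
  if (paired) {
    se_dc <- stats::sd(cb - ca) / sqrt(length(ca))
    se_dq <- stats::sd(qb - qa) / sqrt(length(qa))
  } else {
    se_dc <- sqrt(stats::var(ca) / length(ca) + stats::var(cb) / length(cb))
    se_dq <- sqrt(stats::var(qa) / length(qa) + stats::var(qb) / length(qb))
  }
  if (dq == 0) {
    icer <- NA_real_; label <- "equal effectiveness"
  } else if (dc < 0 && dq > 0) {
    icer <- dc / dq; label <- "dominant"
  } else if (dc > 0 && dq < 0) {
    icer <- dc / dq; label <- "dominated"
  } else {
    icer <- dc / dq; label <- "tradeoff"
  }
  structure(list(delta_cost = dc, delta_qaly = dq,
                 se_delta_cost = se_dc, se_delta_qaly = se_dq,
                 icer = icer, label = label), class = "ce_results")
}

#' @export
print.ce_results <- function(x, ...) {
  cat(sprintf("  incremental cost: %.2f (SE %.2f)\n", x$delta_cost, x$se_delta_cost))
  cat(sprintf("  incremental QALYs: %.4f (SE %.4f)\n", x$delta_qaly, x$se_delta_qaly))
  if (x$label == "equal effectiveness") {
    cat("  equal effectiveness; ICER undefined\n")
  } else {
    cat(sprintf("  ICER: %.0f per QALY (%s)\n", x$icer, x$label))
  }
  invisible(x)
}

#' Declare a PSA parameter
#'
#' @param target `"coefficient"` (normal draw on a risk-equation
#'   coefficient), `"utility"` (beta draw on a baseline frailty utility) or
#'   `"cost"` (gamma draw on an event one-off cost); `dist = "fixed"` pins
#'   any target at a constant.
#' @param dist `"normal"`, `"beta"`, `"gamma"`, or `"fixed"`.
#' @param ... distribution arguments (`mean`/`sd`, `shape1`/`shape2`,
#'   `shape`/`rate`, or `value`), plus the address of the target:
#'   `event` + `covariate` for coefficients, `category` for utilities,
#'   `event` for costs.
#' @return list of class `psa_param`.
#' @export
psa_param <- function(target = c("coefficient", "utility", "cost"),
                      dist = c("normal", "beta", "gamma", "fixed"), ...) {
  target <- match.arg(target)
  dist <- match.arg(dist)
  args <- list(...)
  ok <- switch(dist,
               normal = all(c("mean", "sd") %in% names(args)) && args$sd >= 0,
               beta = all(c("shape1", "shape2") %in% names(args)) &&
                 args$shape1 > 0 && args$shape2 > 0,
               gamma = all(c("shape", "rate") %in% names(args)) &&
                 args$shape > 0 && args$rate > 0,
               fixed = "value" %in% names(args))
  if (!isTRUE(ok)) stop("invalid distribution parameters for ", dist, call. = FALSE)
  structure(c(list(target = target, dist = dist), args), class = "psa_param")
}

draw_psa_value <- function(p) {
  switch(p$dist,
         normal = stats::rnorm(1, p$mean, p$sd),
         beta = stats::rbeta(1, p$shape1, p$shape2),
         gamma = stats::rgamma(1, p$shape, rate = p$rate),
         fixed = p$value)
}

apply_psa_draw <- function(params, um, cm, psa_spec, values) {
  for (k in seq_along(psa_spec)) {
    p <- psa_spec[[k]]; v <- values[k]
    if (p$target == "coefficient") {
      params$equations[[p$event]]$coefficients[[p$covariate]] <- v
    } else if (p$target == "utility") {
      um$baseline[[p$category]] <- min(max(v, 0), 1)
    } else {
      cm$event_costs[[p$event]] <- max(v, 0)
    }
  }
  list(params = params, um = um, cm = cm)
}

#' Probabilistic sensitivity analysis with CEAC
#'
#' Draws parameter sets from their declared distributions, reruns the paired
#' scenario comparison per draw, and summarises decision uncertainty as a
#' cost-effectiveness acceptability curve: at each willingness-to-pay
#' threshold, the fraction of draws with positive incremental net monetary
#' benefit. One simulation seed is shared across draws (common random numbers
#' across the PSA), so zero-variance distributions reproduce the
#' deterministic result exactly.
#'
#' @inheritParams run_comparison
#' @param psa_spec list of [psa_param()] declarations.
#' @param n_draws number of PSA draws.
#' @param thresholds willingness-to-pay grid for the CEAC.
#' @return list of class `frail_psa` with `draws` (per-draw `delta_cost`,
#'   `delta_qaly`) and `ceac` (threshold, probability cost-effective).
#' @export
run_psa <- function(cohort, structure, params, scenario_a, scenario_b,
                    utility_model, cost_model, psa_spec, n_draws = 100,
                    thresholds = seq(0, 100000, by = 10000),
                    config = sim_config(), discount_rate = 0.05) {
  stopifnot(n_draws >= 1, length(psa_spec) >= 1)
  base_seed <- if (is.null(config$seed)) 0L else config$seed
  set.seed(base_seed + 7919L)
  value_mat <- vapply(seq_len(n_draws), function(d)
    vapply(psa_spec, draw_psa_value, numeric(1)), numeric(length(psa_spec)))
  value_mat <- matrix(value_mat, nrow = length(psa_spec))
  dc <- dq <- numeric(n_draws)
  for (d in seq_len(n_draws)) {
    mod <- apply_psa_draw(params, utility_model, cost_model, psa_spec, value_mat[, d])
    cmp <- run_comparison(cohort, structure, mod$params, scenario_a, scenario_b,
                          mod$um, mod$cm, config, discount_rate)
    dc[d] <- cmp$incremental$delta_cost
    dq[d] <- cmp$incremental$delta_qaly
  }
  ceac <- vapply(thresholds, function(l) mean(l * dq - dc > 0), numeric(1))
  structure(list(draws = data.frame(draw = seq_len(n_draws),
                                    delta_cost = dc, delta_qaly = dq),
                 ceac = data.frame(threshold = thresholds, prob_cost_effective = ceac)),
            class = "frail_psa")
}
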
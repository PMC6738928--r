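# Individual-level discrete-time simulation engine. Per cycle, in fixed
# order: (1) death Bernoulli; (2) each non-fatal event Bernoulli,
# independently given the linear predictors; (3) frailty category transition;
# (4) history counters / persistent states updated; (5) ageing. Outcome
# accrual (utilities, costs, discounting) lives in the health-economics
# module and works off the recorded traces.

#' Intervention / comparator scenario
#'
#' @param name scenario label.
#' @param intervention logical flag.
#' @param worsening_multiplier multiplier (> 0, typically <= 1) applied to
#'   worsening frailty transitions.
#' @param improvement_multiplier multiplier applied to improving transitions.
#' @param hazard_multipliers named positive multipliers applied to event
#'   risks on the odds scale (a log-multiplier added to the linear
#'   predictor); names are event names, `death` included.
#' @param one_off_cost intervention cost charged once at model start.
#' @param per_cycle_cost intervention cost charged every cycle lived.
#' @return object of class `frail_scenario`.
#' @export
scenario <- function(name = "usual_care", intervention = FALSE,
                     worsening_multiplier = 1, improvement_multiplier = 1,
                     hazard_multipliers = numeric(0),
                     one_off_cost = 0, per_cycle_cost = 0) {
  if (worsening_multiplier <= 0 || improvement_multiplier <= 0)
    stop("transition multipliers must be positive", call. = FALSE)
  if (length(hazard_multipliers) && (is.null(names(hazard_multipliers)) ||
                                     any(hazard_multipliers <= 0)))
    stop("hazard multipliers must be a named vector of positive values", call. = FALSE)
  if (one_off_cost < 0 || per_cycle_cost < 0)
    stop("intervention costs must be non-negative", call. = FALSE)
  structure(list(name = name, intervention = intervention,
                 worsening_multiplier = worsening_multiplier,
                 improvement_multiplier = improvement_multiplier,
                 hazard_multipliers = hazard_multipliers,
                 one_off_cost = one_off_cost, per_cycle_cost = per_cycle_cost),
            class = "frail_scenario")
}

#' Simulation configuration
#'
#' @param n_cycles number of cycles to simulate; default runs until every
#'   individual can have reached `max_age`.
#' @param cycle_length cycle length in years.
#' @param max_age individuals exit the model (stop being simulated) once
#'   their age reaches this bound.
#' @param seed integer master seed; all randomness in a run derives from it.
#' @param common_random_numbers reuse the same seed (and therefore the same
#'   fixed per-cycle draw layout) across compared scenarios, pairing sample
#'   paths.
#' @param half_cycle_correction discount accruals at cycle midpoints instead
#'   of cycle starts.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(n_cycles = NULL, cycle_length = 1, max_age = 110,
                       seed = NULL, common_random_numbers = TRUE,
                       half_cycle_correction = FALSE) {
  stopifnot(cycle_length > 0, is.finite(max_age))
  structure(list(n_cycles = n_cycles, cycle_length = cycle_length,
                 max_age = max_age, seed = seed,
                 common_random_numbers = common_random_numbers,
                 half_cycle_correction = half_cycle_correction),
            class = "sim_config")
}

# numeric state matrix: attributes + frailty indicators + persistent states
init_state_matrix <- function(cohort, structure) {
  at <- attribute_names(structure)
  missing_at <- setdiff(at, names(cohort))
  if (length(missing_at))
    stop("cohort lacks attributes: ", paste(missing_at, collapse = ", "), call. = FALSE)
  n <- nrow(cohort)
  cols <- setdiff(at, "frailty_status")
  A <- matrix(0, n, length(cols), dimnames = list(NULL, cols))
  for (cl in cols) {
    v <- cohort[[cl]]
    if (is.factor(v) || is.character(v)) v <- as.numeric(as.factor(v))
    A[, cl] <- as.numeric(v)
  }
  A
}

init_frailty <- function(cohort) {
  v <- cohort$frailty_status
  if (is.null(v)) stop("cohort lacks frailty_status", call. = FALSE)
  if (is.numeric(v)) cat0 <- as.integer(v) else cat0 <- match(as.character(v), frailty_levels)
  if (any(is.na(cat0)) || any(cat0 < 1) || any(cat0 > 3))
    stop("frailty_status must be one of ", paste(frailty_levels, collapse = ", "),
         call. = FALSE)
  cat0
}

#' Simulate a cohort through the individual-level model
#'
#' Each individual is advanced cycle by cycle until death, the age bound, or
#' the horizon. Random draws follow a fixed layout (death, each non-fatal
#' event, frailty transition — for every individual, every cycle, regardless
#' of vital status), so two runs with the same seed consume identical draws
#' position by position: the common-random-numbers contract used by
#' [run_comparison()].
#'
#' @param cohort baseline data frame, one row per individual, with a column
#'   per structure attribute (`frailty_status` as category name or index).
#' @param structure a `frail_structure`.
#' @param params a [risk_params()] covering every event in the structure.
#' @param scen a [scenario()].
#' @param config a [sim_config()].
#' @return object of class `frail_sim` holding per-cycle trace matrices
#'   (`entered`, `died`, `frailty` category codes, one logical matrix per
#'   non-fatal event, persistent-state and counter traces), the final state
#'   and per-individual summaries (`cycles_entered`, `life_years`,
#'   `death_cycle`).
#' @export
simulate_cohort <- function(cohort, structure, params, scen = scenario(),
                            config = sim_config()) {
  stopifnot(inherits(structure, "frail_structure"), inherits(params, "risk_params"),
            inherits(scen, "frail_scenario"), inherits(config, "sim_config"))
  if (!is.data.frame(cohort) || nrow(cohort) == 0)
    stop("cohort must be a non-empty data frame", call. = FALSE)
  check_params_cover(params, structure)
  death_name <- absorbing_event(structure)
  if (is.null(death_name)) stop("structure lacks an absorbing death event", call. = FALSE)
  n <- nrow(cohort)
  nf <- nonfatal_events(structure)
  nf_names <- vapply(nf, `[[`, character(1), "name")
  pers <- persistent_events(structure)
  A <- init_state_matrix(cohort, structure)
  cat_now <- init_frailty(cohort)
  S <- matrix(0, n, length(pers),
              dimnames = list(NULL, sprintf("state_%s", pers)))
  for (p in pers) {  # carried-in persistent states, if the cohort records them
    cl <- paste0("state_", p)
    if (cl %in% names(cohort)) S[, cl] <- as.numeric(cohort[[cl]])
  }
  cl <- config$cycle_length
  has_age <- "age" %in% colnames(A)
  age <- if (has_age) A[, "age"] else rep(0, n)
  C <- config$n_cycles
  if (is.null(C)) C <- max(1L, ceiling((config$max_age - min(age)) / cl))
  if (!is.null(config$seed)) set.seed(config$seed)

  hm <- function(ev) {
    m <- scen$hazard_multipliers
    if (ev %in% names(m)) log(m[[ev]]) else 0
  }
  P3 <- effective_transition_matrix(params$frailty_model,
                                    scen$worsening_multiplier,
                                    scen$improvement_multiplier)
  cum3 <- t(apply(P3, 1, cumsum))

  entered <- matrix(FALSE, n, C)
  died <- matrix(FALSE, n, C)
  frail_tr <- matrix(NA_integer_, n, C)
  ev_tr <- lapply(nf_names, function(e) matrix(FALSE, n, C))
  names(ev_tr) <- nf_names
  ctr_names <- counter_attributes(structure)
  ctr_tr <- lapply(ctr_names, function(a) matrix(NA_real_, n, C))
  names(ctr_tr) <- ctr_names
  st_tr <- lapply(colnames(S), function(s) matrix(0, n, C))
  names(st_tr) <- colnames(S)

  alive <- rep(TRUE, n)
  counters_of <- vapply(nf, `[[`, character(1), "history_counter")

  state_mat <- function() {
    cbind(A,
          frailty_pre_frail = as.numeric(cat_now == 2),
          frailty_frail = as.numeric(cat_now == 3),
          S)
  }

  used <- 0L
  for (t in seq_len(C)) {
    active <- alive & (age < config$max_age - 1e-9)
    if (!any(active)) break
    used <- t
    entered[, t] <- active
    frail_tr[, t] <- ifelse(active, cat_now, NA_integer_)
    for (a in ctr_names) ctr_tr[[a]][, t] <- ifelse(active, A[, a], NA_real_)
    for (s in colnames(S)) st_tr[[s]][, t] <- ifelse(active, S[, s], NA_real_)

    # fixed draw layout for common random numbers
    u_death <- stats::runif(n)
    U_ev <- if (length(nf_names)) matrix(stats::runif(n * length(nf_names)),
                                         n, length(nf_names)) else NULL
    u_frail <- stats::runif(n)

    M <- state_mat()
    p_death <- cycle_probability(linear_predictor(params$equations[[death_name]], M) +
                                   hm(death_name))
    dies <- active & (u_death < p_death)
    died[, t] <- dies
    alive[dies] <- FALSE
    surv <- active & !dies

    for (k in seq_along(nf_names)) {
      e <- nf_names[k]
      p_e <- cycle_probability(linear_predictor(params$equations[[e]], M) + hm(e))
      occ <- surv & (U_ev[, k] < p_e)
      ev_tr[[e]][, t] <- occ
      ctr <- counters_of[k]
      if (!is.na(ctr)) A[occ, ctr] <- A[occ, ctr] + 1
      if (e %in% pers) S[occ, paste0("state_", e)] <- 1
    }

    if (any(surv)) {
      cs <- cum3[cat_now[surv], , drop = FALSE]
      r <- u_frail[surv]
      cat_now[surv] <- 1L + (r > cs[, 1]) + (r > cs[, 2])
    }
    age[surv] <- age[surv] + cl
    if (has_age) A[surv, "age"] <- age[surv]
  }

  keep <- seq_len(max(used, 1L))
  trim <- function(m) m[, keep, drop = FALSE]
  entered <- trim(entered); died <- trim(died); frail_tr <- trim(frail_tr)
  ev_tr <- lapply(ev_tr, trim); ctr_tr <- lapply(ctr_tr, trim)
  st_tr <- lapply(st_tr, trim)

  cycles_entered <- rowSums(entered)
  death_cycle <- apply(died, 1, function(z) if (any(z)) which(z)[1] else NA_integer_)
  life_cycles <- rowSums(entered & !died)
  structure(list(
    n = n, n_cycles = ncol(entered), cycle_length = cl,
    entered = entered, died = died, frailty = frail_tr,
    events = ev_tr, counters = ctr_tr, states = st_tr,
    final_alive = alive, final_frailty = cat_now, final_age = age,
    cycles_entered = cycles_entered, death_cycle = death_cycle,
    life_years = life_cycles * cl,
    scenario = scen, config = config,
    structure_events = event_names(structure),
    death_event = death_name), class = "frail_sim")
}

#' @export
print.frail_sim <- function(x, ...) {
  cat(sprintf("<frail_sim> n = %d, cycles = %d (cycle length %g y)\n",
              x$n, x$n_cycles, x$cycle_length))
  cat(sprintf("  scenario '%s'; deaths: %d; mean life-years: %.2f\n",
              x$scenario$name, sum(!is.na(x$death_cycle)), mean(x$life_years)))
  invisible(x)
}

#' Simulate one individual and return their trajectory
#'
#' @param baseline single-row data frame of baseline attributes.
#' @inheritParams simulate_cohort
#' @return a trajectory data frame, one row per cycle entered: `cycle`
#'   (0-based), `age`, `frailty`, `died`, one indicator column per non-fatal
#'   event, persistent-state (`state_*`) and history-counter columns as at
#'   cycle start.
#' @export
simulate_individual <- function(baseline, structure, params, scen = scenario(),
                                config = sim_config()) {
  stopifnot(nrow(baseline) == 1)
  sim <- simulate_cohort(baseline, structure, params, scen, config)
  trajectory(sim, 1L)
}

#' Extract one individual's trajectory from a cohort simulation
#'
#' @param sim a `frail_sim`.
#' @param i individual index.
#' @return trajectory data frame (see [simulate_individual()]).
#' @export
trajectory <- function(sim, i) {
  stopifnot(inherits(sim, "frail_sim"), i >= 1, i <= sim$n)
  in_cycle <- which(sim$entered[i, ])
  age0 <- sim$final_age[i] - sim$cycle_length *
    sum(sim$entered[i, ] & !sim$died[i, ])
  out <- data.frame(
    cycle = in_cycle - 1L,
    age = age0 + (in_cycle - 1L) * sim$cycle_length,
    frailty = frailty_levels[sim$frailty[i, in_cycle]],
    died = sim$died[i, in_cycle])
  for (e in names(sim$events)) out[[e]] <- sim$events[[e]][i, in_cycle]
  for (s in names(sim$states)) out[[s]] <- sim$states[[s]][i, in_cycle]
  for (a in names(sim$counters)) out[[a]] <- sim$counters[[a]][i, in_cycle]
  out
}

#' Compare two scenarios on the same cohort
#'
#' Runs the comparator and intervention scenarios on an identical cohort.
#' Under common random numbers (the default) both runs use the same master
#' seed and therefore identical draw positions, so a scenario compared with
#' itself yields exactly zero incremental cost and QALYs and incremental
#' estimates have paired (variance-reduced) Monte-Carlo errors.
#'
#' @param cohort baseline cohort data frame.
#' @param structure,params model structure and parameters.
#' @param scenario_a comparator [scenario()].
#' @param scenario_b intervention [scenario()].
#' @param utility_model,cost_model see [utility_model()] / [cost_model()].
#' @param config a [sim_config()]; its seed drives both runs.
#' @param discount_rate annual discount rate for costs and effects.
#' @return list of class `frail_comparison`: per-scenario outcome summaries
#'   and the incremental analysis (see [incremental_analysis()]).
#' @export
run_comparison <- function(cohort, structure, params, scenario_a, scenario_b,
                           utility_model, cost_model, config = sim_config(),
                           discount_rate = 0.05) {
  seed_b <- config$seed
  if (!isTRUE(config$common_random_numbers) && !is.null(seed_b))
    seed_b <- seed_b + 1L
  config_b <- config
  config_b$seed <- seed_b
  sim_a <- simulate_cohort(cohort, structure, params, scenario_a, config)
  sim_b <- simulate_cohort(cohort, structure, params, scenario_b, config_b)
  out_a <- cohort_outcomes(sim_a, utility_model, cost_model, discount_rate)
  out_b <- cohort_outcomes(sim_b, utility_model, cost_model, discount_rate)
  inc <- incremental_analysis(out_a, out_b,
                              paired = isTRUE(config$common_random_numbers))
  structure(list(comparator = out_a, intervention = out_b, incremental = inc,
                 scenario_a = scenario_a$name, scenario_b = scenario_b$name),
            class = "frail_comparison")
}

#' @export
print.frail_comparison <- function(x, ...) {
  cat(sprintf("<frail_comparison> '%s' vs '%s'\n", x$scenario_b, x$scenario_a))
  print(x$incremental)
  invisible(x)
}
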
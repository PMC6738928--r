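# Validation harness: exact Markov cohort oracle, cross-model comparison of
# the microsimulation against the oracle in memoryless configurations, and
# internal validation of simulated rates against observed panel targets.

#' Exact cohort Markov trace
#'
#' Repeated vector-matrix products: the memoryless cohort model the
#' individual-level engine generalises. Used as an independent oracle for
#' cross-model validation.
#'
#' @param P square transition matrix (rows sum to 1).
#' @param init initial distribution over states.
#' @param cycles number of cycles (>= 1).
#' @return `(cycles + 1) x nstates` occupancy matrix; row `t + 1` is the
#'   distribution after `t` cycles.
#' @export
markov_oracle <- function(P, init, cycles) {
  P <- as.matrix(P)
  if (nrow(P) != ncol(P) || any(P < 0) || any(P > 1) ||
      any(abs(rowSums(P) - 1) > 1e-9))
    stop("P must be a square stochastic matrix", call. = FALSE)
  stopifnot(length(init) == nrow(P), abs(sum(init) - 1) < 1e-9, cycles >= 1)
  trace <- matrix(0, cycles + 1, nrow(P))
  colnames(trace) <- colnames(P)
  trace[1, ] <- init
  for (t in seq_len(cycles)) trace[t + 1, ] <- drop(trace[t, ] %*% P)
  trace
}

#' Markov matrix of a memoryless frailty-and-death configuration
#'
#' Builds the exact 4-state chain (non-frail, pre-frail, frail, dead) implied
#' by a per-category death probability and a frailty transition matrix:
#' death is evaluated first within a cycle, then the frailty transition among
#' survivors — matching the engine's within-cycle ordering.
#'
#' @param trans a [frailty_transition_model()].
#' @param death_probs per-cycle death probability for each frailty category.
#' @return 4x4 stochastic matrix.
#' @export
memoryless_markov_matrix <- function(trans, death_probs) {
  stopifnot(inherits(trans, "frailty_transition_model"), length(death_probs) == 3,
            all(death_probs >= 0), all(death_probs <= 1))
  P <- matrix(0, 4, 4, dimnames = list(c(frailty_levels, "dead"),
                                       c(frailty_levels, "dead")))
  for (i in 1:3) {
    P[i, 1:3] <- (1 - death_probs[i]) * trans$probs[i, ]
    P[i, 4] <- death_probs[i]
  }
  P[4, 4] <- 1
  P
}

#' Cross-model validation: microsimulation vs the Markov oracle
#'
#' In a memoryless configuration — death risk depending only on the frailty
#' category, no history counters, time-invariant attributes — the
#' individual-level engine and the cohort Markov model describe the same
#' process, so microsimulated occupancy must match the oracle trace up to
#' Monte-Carlo error. The death equation may use only the intercept and the
#' frailty indicator columns; any other covariate with a nonzero coefficient
#' violates the memoryless precondition and raises an error.
#'
#' @param params a [risk_params()] whose death equation is memoryless and
#'   whose frailty model drives the transitions.
#' @param init initial distribution over the three frailty categories.
#' @param n number of simulated individuals.
#' @param cycles number of cycles.
#' @param seed integer seed for the microsimulation.
#' @return list of class `oracle_comparison`: `oracle` and `observed`
#'   occupancy traces, per-cell `deviation`, `se` (binomial at the oracle
#'   probabilities), `max_abs_deviation`, and `flagged` — cells exceeding 3
#'   binomial standard errors.
#' @export
compare_microsim_to_oracle <- function(params, init, n, cycles, seed = NULL) {
  stopifnot(inherits(params, "risk_params"), length(init) == 3,
            abs(sum(init) - 1) < 1e-9, n >= 1, cycles >= 1)
  death_eq <- params$equations[["death"]]
  if (is.null(death_eq)) stop("params lack a death equation", call. = FALSE)
  allowed <- c("frailty_pre_frail", "frailty_frail")
  extra <- setdiff(death_eq$covariates, allowed)
  nonzero <- extra[abs(death_eq$coefficients[extra]) > 0]
  if (length(nonzero))
    stop("memoryless precondition violated: death risk depends on ",
         paste(nonzero, collapse = ", "), call. = FALSE)

  p_death <- vapply(1:3, function(i)
    cycle_probability(linear_predictor(
      death_eq, c(frailty_pre_frail = as.numeric(i == 2),
                  frailty_frail = as.numeric(i == 3),
                  age = 0))), numeric(1))
  P <- memoryless_markov_matrix(params$frailty_model, p_death)
  oracle <- markov_oracle(P, c(init, 0), cycles)

  # deterministic category split (largest-remainder) keeps t = 0 exact
  counts <- floor(init * n)
  rem <- n - sum(counts)
  if (rem > 0) {
    frac_order <- order(init * n - counts, decreasing = TRUE)
    counts[frac_order[seq_len(rem)]] <- counts[frac_order[seq_len(rem)]] + 1
  }
  cohort <- data.frame(age = 0,
                       frailty_status = rep(frailty_levels, counts))
  structure_ml <- model_structure(
    events = list(health_event("death", "absorbing")),
    attributes = list(patient_attribute("age", "continuous", TRUE),
                      patient_attribute("frailty_status", "categorical", TRUE)),
    edges = data.frame(attribute = "frailty_status", event = "death"))
  sim <- simulate_cohort(cohort, structure_ml,
                         risk_params(list(death = death_eq), params$frailty_model),
                         scenario(),
                         sim_config(n_cycles = cycles, seed = seed, max_age = Inf0()))

  observed <- matrix(0, cycles + 1, 4, dimnames = dimnames(oracle))
  observed[1, 1:3] <- counts / n
  dead_cum <- 0
  for (t in seq_len(cycles)) {
    if (t <= sim$n_cycles) dead_cum <- dead_cum + sum(sim$died[, t])
    if (t < cycles && t + 1 <= sim$n_cycles) {
      cat_t <- sim$frailty[sim$entered[, t + 1], t + 1]
    } else if (t == cycles || t >= sim$n_cycles) {
      cat_t <- sim$final_frailty[sim$final_alive]
    } else {
      cat_t <- integer(0)
    }
    observed[t + 1, 1:3] <- tabulate(cat_t, nbins = 3) / n
    observed[t + 1, 4] <- dead_cum / n
  }
  deviation <- observed - oracle
  se <- sqrt(oracle * (1 - oracle) / n)
  flagged <- abs(deviation) > 3 * se + 1e-12
  structure(list(oracle = oracle, observed = observed, deviation = deviation,
                 se = se, max_abs_deviation = max(abs(deviation)),
                 flagged = flagged, n = n),
            class = "oracle_comparison")
}

#' @export
print.oracle_comparison <- function(x, ...) {
  cat(sprintf("<oracle_comparison> n = %d, cycles = %d\n", x$n, nrow(x$oracle) - 1))
  cat(sprintf("  max |occupancy deviation| = %.5f; cells beyond 3 SE: %d\n",
              x$max_abs_deviation, sum(x$flagged)))
  invisible(x)
}

#' Calibration targets from an observed panel
#'
#' Extracts per-wave death rates (deaths / individuals entering the wave),
#' per-wave non-fatal event rates among survivors, and per-wave frailty
#' category prevalences, each with the count it is based on.
#'
#' @param panel long panel data frame (see [generate_panel()]).
#' @param structure the `frail_structure` the panel was generated under.
#' @return data frame of class `calibration_targets`: `metric`, `name`,
#'   `wave`, `observed`, `n`.
#' @export
panel_targets <- function(panel, structure) {
  death_name <- absorbing_event(structure)
  nf <- vapply(nonfatal_events(structure), `[[`, character(1), "name")
  rows <- list()
  for (w in sort(unique(panel$wave))) {
    pw <- panel[panel$wave == w, ]
    rows[[length(rows) + 1]] <- data.frame(
      metric = "death_rate", name = death_name, wave = w,
      observed = mean(pw[[death_name]]), n = nrow(pw))
    surv <- pw[pw[[death_name]] == 0, ]
    for (e in nf) {
      rows[[length(rows) + 1]] <- data.frame(
        metric = "event_rate", name = e, wave = w,
        observed = mean(surv[[e]]), n = nrow(surv))
    }
    for (f in frailty_levels) {
      rows[[length(rows) + 1]] <- data.frame(
        metric = "prevalence", name = f, wave = w,
        observed = mean(pw$frailty_status == f), n = nrow(pw))
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("calibration_targets", class(out))
  out
}

# the same quantities measured on a simulation run
sim_rates <- function(sim) {
  rows <- list()
  for (t in seq_len(sim$n_cycles)) {
    entered <- sim$entered[, t]
    if (!any(entered)) break
    n_in <- sum(entered)
    rows[[length(rows) + 1]] <- data.frame(
      metric = "death_rate", name = sim$death_event, wave = t,
      predicted = sum(sim$died[, t]) / n_in)
    surv <- entered & !sim$died[, t]
    for (e in names(sim$events)) {
      rows[[length(rows) + 1]] <- data.frame(
        metric = "event_rate", name = e, wave = t,
        predicted = sum(sim$events[[e]][surv, t]) / sum(surv))
    }
    for (i in 1:3) {
      rows[[length(rows) + 1]] <- data.frame(
        metric = "prevalence", name = frailty_levels[i], wave = t,
        predicted = sum(sim$frailty[entered, t] == i) / n_in)
    }
  }
  do.call(rbind, rows)
}

#' Internal validation of a simulation against calibration targets
#'
#' Compares simulated per-wave rates with observed targets; a target passes
#' when the absolute difference is below `tolerance` times the observed
#' rate's binomial standard error. Targets with no simulated counterpart are
#' reported as unmatched rather than raising an error.
#'
#' @param sim a `frail_sim`.
#' @param targets a [panel_targets()] data frame.
#' @param tolerance multiple of the observed SE allowed (default 3).
#' @return data frame of class `validation_report`: predicted vs observed,
#'   absolute and standardised differences, `pass`, `matched`.
#' @export
internal_validation <- function(sim, targets, tolerance = 3) {
  stopifnot(inherits(sim, "frail_sim"))
  if (nrow(targets) == 0) {
    out <- data.frame(metric = character(), name = character(), wave = integer(),
                      observed = numeric(), predicted = numeric(),
                      diff = numeric(), se = numeric(), z = numeric(),
                      pass = logical(), matched = logical())
    class(out) <- c("validation_report", class(out))
    return(out)
  }
  pred <- sim_rates(sim)
  out <- merge(as.data.frame(targets), pred,
               by = c("metric", "name", "wave"), all.x = TRUE)
  out$matched <- !is.na(out$predicted)
  out$se <- sqrt(pmax(out$observed * (1 - out$observed), 1e-12) / out$n)
  out$diff <- out$predicted - out$observed
  out$z <- out$diff / out$se
  out$pass <- out$matched & abs(out$diff) < tolerance * out$se
  out <- out[order(out$metric, out$name, out$wave), ]
  rownames(out) <- NULL
  class(out) <- c("validation_report", class(out))
  out
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("<validation_report> %d targets, %d matched, %d pass\n",
              nrow(x), sum(x$matched), sum(x$pass)))
  print.data.frame(x, digits = 4)
  invisible(x)
}
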
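# Synthetic baseline cohorts and longitudinal ageing panels with known
# ground-truth risk parameters, emulating SHARE/DYNOPTA-style repeated-wave
# data (attributes, frailty status, events, death) so that risk-equation
# fitting and validation are fully testable offline.

#' Specify a marginal distribution for one cohort attribute
#'
#' @param dist one of `"normal"`, `"uniform"`, `"binary"`, `"poisson"`,
#'   `"categorical"`, `"constant"`.
#' @param ... parameters: `mean`/`sd`, `min`/`max`, `p`, `lambda`,
#'   `levels`/`probs` (levels may be numeric codes or category names),
#'   `value`.
#' @return list of class `marginal_spec`.
#' @export
marginal <- function(dist = c("normal", "uniform", "binary", "poisson",
                              "categorical", "constant"), ...) {
  dist <- match.arg(dist)
  args <- list(...)
  ok <- switch(dist,
               normal = all(c("mean", "sd") %in% names(args)) && args$sd >= 0,
               uniform = all(c("min", "max") %in% names(args)) && args$min <= args$max,
               binary = "p" %in% names(args) && args$p >= 0 && args$p <= 1,
               poisson = "lambda" %in% names(args) && args$lambda >= 0,
               categorical = all(c("levels", "probs") %in% names(args)) &&
                 length(args$levels) == length(args$probs) &&
                 abs(sum(args$probs) - 1) < 1e-9,
               constant = "value" %in% names(args))
  if (!isTRUE(ok)) stop("invalid parameters for marginal '", dist, "'", call. = FALSE)
  structure(c(list(dist = dist), args), class = "marginal_spec")
}

marginal_quantile <- function(m, u) {
  switch(m$dist,
         normal = stats::qnorm(u, m$mean, m$sd),
         uniform = stats::qunif(u, m$min, m$max),
         binary = as.numeric(u > 1 - m$p),
         poisson = stats::qpois(u, m$lambda),
         categorical = m$levels[1L + findInterval(u, cumsum(m$probs),
                                                  rightmost.closed = TRUE)],
         constant = rep(m$value, length(u)))
}

#' Specify a synthetic baseline cohort
#'
#' Dependence between attributes is induced by a Gaussian copula on rank
#' correlations: latent multivariate-normal draws are transformed to uniforms
#' and pushed through each marginal's quantile function. Spearman rank
#' correlations are converted to the latent Pearson scale via
#' `2 sin(pi rho / 6)`. This is an emulation device for plausible joint
#' structure, not a claim about any real survey's dependence.
#'
#' @param n cohort size.
#' @param marginals named list of [marginal()] specs, one per attribute.
#' @param correlations optional data frame `a`, `b`, `rho` of pairwise
#'   Spearman correlations between named attributes.
#' @param seed integer seed.
#' @return list of class `cohort_spec`.
#' @export
cohort_spec <- function(n, marginals, correlations = NULL, seed = NULL) {
  stopifnot(n > 0, is.list(marginals), length(names(marginals)) == length(marginals))
  if (!is.null(correlations))
    stopifnot(all(c("a", "b", "rho") %in% names(correlations)),
              all(abs(correlations$rho) <= 1),
              all(correlations$a %in% names(marginals)),
              all(correlations$b %in% names(marginals)))
  structure(list(n = n, marginals = marginals, correlations = correlations,
                 seed = seed), class = "cohort_spec")
}

#' Generate a baseline cohort from a spec
#'
#' Deterministic under a fixed seed: the same spec and seed always produce an
#' identical table.
#'
#' @param spec a [cohort_spec()].
#' @return data frame with `id` plus one column per attribute.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (!is.null(spec$seed)) set.seed(spec$seed)
  nm <- names(spec$marginals)
  k <- length(nm)
  R <- diag(k); dimnames(R) <- list(nm, nm)
  if (!is.null(spec$correlations)) {
    for (r in seq_len(nrow(spec$correlations))) {
      rho <- 2 * sin(pi * spec$correlations$rho[r] / 6)
      a <- spec$correlations$a[r]; b <- spec$correlations$b[r]
      R[a, b] <- R[b, a] <- rho
    }
  }
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8)
    stop("correlation specification is not positive semi-definite", call. = FALSE)
  L <- chol(R + diag(1e-10, k))
  Z <- matrix(stats::rnorm(spec$n * k), spec$n, k) %*% L
  U <- stats::pnorm(Z)
  out <- data.frame(id = seq_len(spec$n))
  for (j in seq_len(k)) out[[nm[j]]] <- marginal_quantile(spec$marginals[[j]], U[, j])
  out
}

#' Default cohort spec for the consensus model structure
#'
#' A community-dwelling older cohort: baseline age uniform 65-90, frailty
#' status distributed 50/35/15 over non-frail/pre-frail/frail (within the
#' span of published frailty prevalence estimates for 65+), sparse event
#' histories and binary comorbidities at plausible prevalences. Mild positive
#' rank correlations couple age with frailty, disability history and
#' admission history. Illustrative, not calibrated to any survey.
#'
#' @param n cohort size.
#' @param seed integer seed.
#' @return a [cohort_spec()] covering every attribute of
#'   [default_structure()].
#' @export
default_cohort_spec <- function(n, seed = NULL) {
  cohort_spec(
    n = n,
    marginals = list(
      age = marginal("uniform", min = 65, max = 90),
      gender = marginal("binary", p = 0.55),
      education = marginal("categorical", levels = 1:3, probs = c(0.4, 0.4, 0.2)),
      frailty_status = marginal("categorical", levels = frailty_levels,
                                probs = c(0.50, 0.35, 0.15)),
      previous_hospital_admissions = marginal("poisson", lambda = 0.4),
      previous_fractures = marginal("poisson", lambda = 0.2),
      polypharmacy = marginal("binary", p = 0.30),
      stroke = marginal("binary", p = 0.06),
      diabetes = marginal("binary", p = 0.15),
      physical_activity = marginal("binary", p = 0.35),
      depression = marginal("binary", p = 0.15)),
    correlations = data.frame(
      a = c("age", "age", "age"),
      b = c("previous_hospital_admissions", "previous_fractures", "polypharmacy"),
      rho = c(0.2, 0.15, 0.2)),
    seed = seed)
}

#' Generate a longitudinal panel from known true parameters
#'
#' Advances the cohort through `waves` cycles using the *same* risk-equation
#' machinery as the simulation engine at the supplied true parameters, and
#' emits one row per individual-wave: attribute values at wave start
#' (including updated history counters, persistent states and frailty
#' category indicators), the per-wave event indicators, and the death
#' indicator. Death truncates follow-up; non-fatal event indicators are `NA`
#' in the wave an individual dies (events are sampled conditional on
#' surviving the wave).
#'
#' @param cohort baseline cohort data frame.
#' @param structure a `frail_structure`.
#' @param true_params a [risk_params()] — the ground truth.
#' @param waves number of panel waves (>= 2).
#' @param cycle_length years between waves.
#' @param seed integer seed.
#' @return long data frame, one row per individual-wave.
#' @export
generate_panel <- function(cohort, structure, true_params, waves,
                           cycle_length = 1, seed = NULL) {
  stopifnot(waves >= 2)
  check_params_cover(true_params, structure)
  cfg <- sim_config(n_cycles = waves, cycle_length = cycle_length,
                    max_age = Inf0(), seed = seed)
  sim <- simulate_cohort(cohort, structure, true_params, scenario(), cfg)
  panel_from_sim(sim, cohort, structure)
}

# large finite age bound: panels follow everyone for all waves
Inf0 <- function() 1e6

panel_from_sim <- function(sim, cohort, structure) {
  n <- sim$n; C <- sim$n_cycles; cl <- sim$cycle_length
  at <- attribute_names(structure)
  static <- setdiff(at, c("age", "frailty_status", names(sim$counters)))
  death_name <- sim$death_event
  age0 <- sim$final_age - cl * rowSums(sim$entered & !sim$died)
  rows <- vector("list", C)
  for (t in seq_len(C)) {
    inw <- sim$entered[, t]
    if (!any(inw)) break
    idx <- which(inw)
    df <- data.frame(id = cohort$id[idx] %||% idx, wave = t,
                     age = age0[idx] + (t - 1) * cl,
                     frailty_status = frailty_levels[sim$frailty[idx, t]])
    df$frailty_pre_frail <- as.numeric(sim$frailty[idx, t] == 2)
    df$frailty_frail <- as.numeric(sim$frailty[idx, t] == 3)
    for (a in names(sim$counters)) df[[a]] <- sim$counters[[a]][idx, t]
    for (s in names(sim$states)) df[[s]] <- sim$states[[s]][idx, t]
    for (a in static) {
      v <- cohort[[a]][idx]
      if (is.factor(v) || is.character(v)) v <- as.numeric(as.factor(v))
      df[[a]] <- v
    }
    dies <- sim$died[idx, t]
    df[[death_name]] <- as.numeric(dies)
    for (e in names(sim$events))
      df[[e]] <- ifelse(dies, NA_real_, as.numeric(sim$events[[e]][idx, t]))
    rows[[t]] <- df
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$id, out$wave), ]
  rownames(out) <- NULL
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
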
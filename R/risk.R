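# Per-event risk equations: logistic per-cycle event probabilities as
# functions of attributes, event history and frailty state, plus the frailty
# category transition model and intervention modifiers.

#' Define a risk equation
#'
#' A risk equation maps an individual's state to a per-cycle event
#' probability through a linear predictor and a logit link. Covariates are
#' named state columns; frailty status enters as the indicator columns
#' `frailty_pre_frail` and `frailty_frail` (or as a continuous `fi_score`),
#' and persistent event states as `state_<event>` columns.
#'
#' @param event event name the equation drives.
#' @param coefficients named numeric vector; the intercept is named
#'   `"(Intercept)"`, all other names are covariates.
#' @return object of class `risk_equation`.
#' @export
risk_equation <- function(event, coefficients) {
  stopifnot(is.character(event), is.numeric(coefficients),
            !is.null(names(coefficients)))
  if (any(!is.finite(coefficients))) stop("coefficients must be finite", call. = FALSE)
  covs <- setdiff(names(coefficients), "(Intercept)")
  structure(list(event = event, covariates = covs, coefficients = coefficients),
            class = "risk_equation")
}

#' Linear predictor of a risk equation
#'
#' @param eq a [risk_equation()].
#' @param state a named numeric vector, a single-row list, or a data frame /
#'   numeric matrix with one row per individual and covariates as columns.
#' @return numeric vector of linear predictor values (one per row).
#' @export
linear_predictor <- function(eq, state) {
  stopifnot(inherits(eq, "risk_equation"))
  if (is.data.frame(state)) state <- as.matrix(state)
  if (!is.matrix(state)) state <- matrix(unlist(state), nrow = 1,
                                         dimnames = list(NULL, names(state)))
  missing_cov <- setdiff(eq$covariates, colnames(state))
  if (length(missing_cov))
    stop("state lacks covariates: ", paste(missing_cov, collapse = ", "), call. = FALSE)
  intercept <- if ("(Intercept)" %in% names(eq$coefficients))
    eq$coefficients[["(Intercept)"]] else 0
  if (length(eq$covariates) == 0) return(rep(intercept, nrow(state)))
  drop(state[, eq$covariates, drop = FALSE] %*% eq$coefficients[eq$covariates]) + intercept
}

#' Per-cycle probability from a linear predictor (logit link)
#'
#' @param lp finite numeric linear predictor(s).
#' @return probabilities `1 / (1 + exp(-lp))`.
#' @export
cycle_probability <- function(lp) {
  if (any(!is.finite(lp))) stop("linear predictor must be finite", call. = FALSE)
  stats::plogis(lp)
}

#' Frailty category transition model
#'
#' Per-cycle transition probabilities over the three frailty categories
#' (non-frail, pre-frail, frail). Rows index the current category and must
#' sum to 1.
#'
#' @param probs 3x3 numeric matrix of transition probabilities.
#' @return object of class `frailty_transition_model`.
#' @export
frailty_transition_model <- function(probs) {
  probs <- as.matrix(probs)
  stopifnot(all(dim(probs) == c(3, 3)))
  if (any(probs < 0) || any(probs > 1))
    stop("transition probabilities must lie in [0, 1]", call. = FALSE)
  if (any(abs(rowSums(probs) - 1) > 1e-9))
    stop("transition matrix rows must sum to 1", call. = FALSE)
  dimnames(probs) <- list(frailty_levels, frailty_levels)
  structure(list(probs = probs), class = "frailty_transition_model")
}

#' Scenario-adjusted frailty transition probabilities
#'
#' Intervention effects act on the off-diagonal mass: worsening transitions
#' (towards more severe categories) are scaled by `worsening_multiplier`,
#' improving transitions by `improvement_multiplier`, and the freed (or
#' consumed) probability is reassigned to staying in the current category.
#' With a worsening multiplier below 1 this shifts mass away from
#' deterioration, the mechanism by which a frailty intervention "reverses or
#' delays" progression.
#'
#' @param current current category (name from [frailty_levels] or index 1-3).
#' @param model a [frailty_transition_model()].
#' @param worsening_multiplier,improvement_multiplier positive multipliers;
#'   1 leaves the row unchanged.
#' @return named probability vector over the three categories (sums to 1).
#' @export
frailty_transition_probs <- function(current, model, worsening_multiplier = 1,
                                     improvement_multiplier = 1) {
  stopifnot(inherits(model, "frailty_transition_model"))
  i <- if (is.character(current)) match(current, frailty_levels) else as.integer(current)
  if (is.na(i) || i < 1 || i > 3) stop("invalid frailty category", call. = FALSE)
  if (worsening_multiplier < 0 || improvement_multiplier < 0)
    stop("multipliers must be non-negative", call. = FALSE)
  row <- model$probs[i, ]
  j <- seq_len(3)
  row[j > i] <- row[j > i] * worsening_multiplier
  row[j < i] <- row[j < i] * improvement_multiplier
  row[i] <- 1 - sum(row[j != i])
  if (any(row < -1e-12) || any(row > 1 + 1e-12))
    stop("scenario modifiers push transition probabilities outside [0, 1]",
         call. = FALSE)
  pmin(pmax(row, 0), 1)
}

# full 3x3 matrix after scenario modification
effective_transition_matrix <- function(model, worsening_multiplier = 1,
                                        improvement_multiplier = 1) {
  out <- t(vapply(1:3, frailty_transition_probs, numeric(3), model = model,
                  worsening_multiplier = worsening_multiplier,
                  improvement_multiplier = improvement_multiplier))
  dimnames(out) <- list(frailty_levels, frailty_levels)
  out
}

#' Bundle risk equations and the frailty transition model
#'
#' @param equations named list of [risk_equation()] objects, one per event in
#'   the target structure (names must match the events).
#' @param frailty_model a [frailty_transition_model()].
#' @return object of class `risk_params`.
#' @export
risk_params <- function(equations, frailty_model) {
  stopifnot(is.list(equations), inherits(frailty_model, "frailty_transition_model"))
  nm <- vapply(equations, `[[`, character(1), "event")
  names(equations) <- nm
  structure(list(equations = equations, frailty_model = frailty_model),
            class = "risk_params")
}

check_params_cover <- function(params, structure) {
  missing_ev <- setdiff(event_names(structure), names(params$equations))
  if (length(missing_ev))
    stop("risk params lack equations for events: ",
         paste(missing_ev, collapse = ", "), call. = FALSE)
  invisible(TRUE)
}

#' Fit a per-cycle risk equation to panel data
#'
#' Maximum-likelihood logistic regression of the per-wave event indicator on
#' the requested covariates (IRLS via `stats::glm`, converged when the
#' relative deviance change drops below 1e-8 or after 100 iterations). Rows
#' where the outcome is missing — e.g. non-fatal events in the wave an
#' individual died — are dropped.
#'
#' @param panel a long panel data frame (one row per individual-wave), as
#'   produced by [generate_panel()].
#' @param event name of the event indicator column to model.
#' @param covariates character vector of covariate column names.
#' @return object of class `risk_fit`: `equation` (a [risk_equation()] at the
#'   estimates), `coefficients`, `se`, `loglik`, `converged`, `n`.
#' @export
fit_risk_equation <- function(panel, event, covariates) {
  stopifnot(is.data.frame(panel), event %in% names(panel))
  missing_cov <- setdiff(covariates, names(panel))
  if (length(missing_cov))
    stop("panel lacks covariates: ", paste(missing_cov, collapse = ", "), call. = FALSE)
  dat <- panel[!is.na(panel[[event]]), c(event, covariates), drop = FALSE]
  y <- dat[[event]]
  if (nrow(dat) == 0 || length(unique(y)) < 2)
    stop("degenerate outcome: event '", event,
         "' has no variation in the panel (all ", if (any(y == 1)) "one" else "zero",
         ")", call. = FALSE)
  fml <- if (length(covariates)) {
    stats::reformulate(covariates, response = event)
  } else {
    stats::reformulate("1", response = event)
  }
  separation <- FALSE
  fit <- withCallingHandlers(
    stats::glm(fml, family = stats::binomial(), data = dat,
               control = stats::glm.control(epsilon = 1e-8, maxit = 100)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        separation <<- TRUE
      invokeRestart("muffleWarning")
    })
  if (fit$deviance < 1e-6 || (separation && fit$deviance < 1e-4))
    stop("complete separation: the event is perfectly predicted", call. = FALSE)
  sm <- summary(fit)
  est <- stats::coef(fit)
  structure(list(
    event = event,
    equation = risk_equation(event, est),
    coefficients = est,
    se = sm$coefficients[, "Std. Error"],
    loglik = as.numeric(stats::logLik(fit)),
    converged = fit$converged,
    n = nrow(dat)), class = "risk_fit")
}

#' @export
print.risk_fit <- function(x, ...) {
  cat(sprintf("<risk_fit> event '%s' (n = %d, logLik = %.2f, converged = %s)\n",
              x$event, x$n, x$loglik, x$converged))
  print(cbind(estimate = x$coefficients, se = x$se))
  invisible(x)
}

#' Estimate the frailty transition matrix from panel data
#'
#' Empirical (multinomial-ML) per-cycle transition fractions between
#' consecutive waves among survivors.
#'
#' @param panel a long panel with `id`, `wave`, `frailty_status` and the
#'   death indicator column.
#' @param death_col name of the death indicator column (default `"death"`).
#' @return a [frailty_transition_model()].
#' @export
fit_frailty_transitions <- function(panel, death_col = "death") {
  stopifnot(all(c("id", "wave", "frailty_status") %in% names(panel)))
  panel <- panel[order(panel$id, panel$wave), ]
  same <- c(panel$id[-1] == panel$id[-nrow(panel)], FALSE)
  surv <- same & panel[[death_col]] == 0
  from <- match(panel$frailty_status[surv], frailty_levels)
  to <- match(panel$frailty_status[which(surv) + 1L], frailty_levels)
  counts <- table(factor(from, levels = 1:3), factor(to, levels = 1:3))
  if (any(rowSums(counts) == 0))
    stop("no observed transitions out of some frailty category", call. = FALSE)
  frailty_transition_model(sweep(counts, 1, rowSums(counts), "/"))
}

#' Write / read risk parameters as JSON
#'
#' @param params a [risk_params()] object.
#' @param path file path (or, for reading, a JSON string).
#' @return `read_risk_params` returns a [risk_params()].
#' @export
write_risk_params <- function(params, path = NULL) {
  stopifnot(inherits(params, "risk_params"))
  payload <- list(
    equations = lapply(params$equations, function(eq)
      list(event = eq$event, coefficients = as.list(eq$coefficients))),
    frailty_transitions = unname(apply(params$frailty_model$probs, 1, as.list)))
  json <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (is.null(path)) return(json)
  writeLines(json, path)
  invisible(json)
}

#' @rdname write_risk_params
#' @export
read_risk_params <- function(path) {
  payload <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  equations <- lapply(payload$equations, function(e)
    risk_equation(e$event, unlist(e$coefficients)))
  probs <- do.call(rbind, lapply(payload$frailty_transitions, unlist))
  risk_params(equations, frailty_transition_model(probs))
}
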
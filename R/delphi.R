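# Delphi consensus classification of candidate model structural choices
# (health states/events and patient attributes) from panellist Likert scores.

#' Agreement-band thresholds for the Delphi classifier
#'
#' The default bands reproduce the published consensus rules: an aspect shows
#' an *acceptable* level of agreement when the panel mean is at least 4 (on
#' the 1-5 Likert scale) and at least 80% of panellists scored 4 or 5; it
#' shows a *moderate* level when the mean is at least 3 and at least 60%
#' scored 4 or higher. The acceptable band is evaluated first, so the two
#' bands are exhaustive and mutually exclusive even though the mean intervals
#' overlap at 4.
#'
#' @param acceptable_mean,acceptable_frac lower bounds on the panel mean and
#'   the fraction of panellists scoring >= 4 for the acceptable band.
#' @param moderate_mean,moderate_frac the same bounds for the moderate band.
#' @return An object of class `delphi_thresholds`.
#' @export
delphi_thresholds <- function(acceptable_mean = 4, acceptable_frac = 0.8,
                              moderate_mean = 3, moderate_frac = 0.6) {
  stopifnot(is.numeric(acceptable_mean), is.numeric(moderate_mean),
            acceptable_frac >= 0, acceptable_frac <= 1,
            moderate_frac >= 0, moderate_frac <= 1)
  structure(list(acceptable_mean = acceptable_mean,
                 acceptable_frac = acceptable_frac,
                 moderate_mean = moderate_mean,
                 moderate_frac = moderate_frac),
            class = "delphi_thresholds")
}

agreement_levels <- c("acceptable", "moderate", "unacceptable")

check_scores <- function(scores) {
  if (length(scores) == 0) stop("score vector is empty", call. = FALSE)
  if (any(is.na(scores))) stop("scores contain NA", call. = FALSE)
  if (any(scores != round(scores)) || any(scores < 1) || any(scores > 5))
    stop("scores must be integers on the 1-5 Likert scale", call. = FALSE)
  invisible(scores)
}

#' Summarise a panel's Likert scores for one aspect
#'
#' @param scores integer vector of Likert scores in 1..5, one per panellist.
#' @return list with `mean_score`, `frac_high` (fraction scoring 4 or 5) and
#'   `n` (panel size).
#' @export
#' @examples
#' summarize_scores(c(5, 5, 5, 5, 4, 4, 4, 3, 3))
summarize_scores <- function(scores) {
  check_scores(scores)
  list(mean_score = mean(scores),
       frac_high = mean(scores >= 4),
       n = length(scores))
}

#' Classify one aspect of a structural choice into an agreement band
#'
#' @param summary a score summary from [summarize_scores()], or a raw score
#'   vector (summarised internally).
#' @param thresholds a [delphi_thresholds()] object.
#' @return one of `"acceptable"`, `"moderate"`, `"unacceptable"`.
#' @export
classify_aspect <- function(summary, thresholds = delphi_thresholds()) {
  if (is.numeric(summary)) summary <- summarize_scores(summary)
  stopifnot(inherits(thresholds, "delphi_thresholds"))
  m <- summary$mean_score
  f <- summary$frac_high
  stopifnot(m >= 1, m <= 5, f >= 0, f <= 1)
  if (m >= thresholds$acceptable_mean && f >= thresholds$acceptable_frac) {
    "acceptable"
  } else if (m >= thresholds$moderate_mean && f >= thresholds$moderate_frac) {
    "moderate"
  } else {
    "unacceptable"
  }
}

check_level <- function(level, what = "agreement level") {
  if (length(level) != 1 || is.na(level) || !level %in% agreement_levels)
    stop(sprintf("%s must be one of %s", what,
                 paste(agreement_levels, collapse = ", ")), call. = FALSE)
  level
}

#' Decision rule for a candidate health state/event
#'
#' A health event is scored on two aspects: the strength of its relationship
#' with frailty (round 1) and its impact on mortality, quality of life and
#' resource use (round 2). Both acceptable: included outright. Any
#' unacceptable aspect: rejected. The remaining combinations (moderate with
#' moderate or acceptable, either order) are fed back to the panel in round 3.
#'
#' @param strength,impact agreement levels for the two aspects.
#' @return one of `"included"`, `"round3"`, `"rejected"`.
#' @export
classify_health_event <- function(strength, impact) {
  check_level(strength, "strength level")
  check_level(impact, "impact level")
  if (strength == "unacceptable" || impact == "unacceptable") return("rejected")
  if (strength == "acceptable" && impact == "acceptable") return("included")
  "round3"
}

#' Decision rule for a candidate patient attribute
#'
#' Attributes are scored on a single aspect (influence on frailty
#' progression): acceptable agreement includes, moderate agreement is fed
#' back in round 3, anything else is rejected.
#'
#' @param level agreement level for the attribute.
#' @return one of `"included"`, `"round3"`, `"rejected"`.
#' @export
classify_attribute <- function(level) {
  check_level(level)
  switch(level, acceptable = "included", moderate = "round3", "rejected")
}

#' Classify one structural choice from its panel scores
#'
#' @param choice_name name of the candidate health event or attribute.
#' @param choice_kind `"health_event"` or `"patient_attribute"`.
#' @param strength_scores Likert scores for the strength-of-relationship
#'   aspect (round 1).
#' @param impact_scores Likert scores for the impact aspect (round 2); must
#'   be supplied for health events and omitted for attributes.
#' @param thresholds a [delphi_thresholds()] object.
#' @return A `delphi_classification` object: the per-aspect levels, the
#'   round-1/2 `decision`, and `round3_final` (filled by [apply_round3()]).
#' @export
classify_choice <- function(choice_name, choice_kind = c("health_event", "patient_attribute"),
                            strength_scores, impact_scores = NULL,
                            thresholds = delphi_thresholds()) {
  choice_kind <- match.arg(choice_kind)
  if (choice_kind == "health_event" && is.null(impact_scores))
    stop("health events require impact scores", call. = FALSE)
  if (choice_kind == "patient_attribute" && !is.null(impact_scores))
    stop("patient attributes are scored on a single aspect", call. = FALSE)
  strength_level <- classify_aspect(summarize_scores(strength_scores), thresholds)
  if (choice_kind == "health_event") {
    impact_level <- classify_aspect(summarize_scores(impact_scores), thresholds)
    decision <- classify_health_event(strength_level, impact_level)
  } else {
    impact_level <- NULL
    decision <- classify_attribute(strength_level)
  }
  structure(list(choice_name = choice_name, choice_kind = choice_kind,
                 strength_level = strength_level, impact_level = impact_level,
                 decision = decision, round3_final = NULL),
            class = "delphi_classification")
}

#' Re-classify a fed-back choice with its round-3 scores
#'
#' Only choices whose round-1/2 decision was `"round3"` may be updated. The
#' updated scores are re-summarised and re-classified with the same bands; a
#' choice is included only if it now reaches acceptable agreement (for health
#' events, on both aspects), otherwise it is rejected.
#'
#' @param prior a `delphi_classification` with `decision == "round3"`.
#' @param strength_scores,impact_scores updated Likert scores; an aspect left
#'   `NULL` keeps no memory of earlier scores and must be re-supplied.
#' @param thresholds a [delphi_thresholds()] object.
#' @return the updated `delphi_classification` with `round3_final` set.
#' @export
apply_round3 <- function(prior, strength_scores, impact_scores = NULL,
                         thresholds = delphi_thresholds()) {
  stopifnot(inherits(prior, "delphi_classification"))
  if (!identical(prior$decision, "round3"))
    stop("apply_round3() called on a choice that was not fed back", call. = FALSE)
  redone <- classify_choice(prior$choice_name, prior$choice_kind,
                            strength_scores, impact_scores, thresholds)
  prior$strength_level <- redone$strength_level
  prior$impact_level <- redone$impact_level
  prior$round3_final <- if (identical(redone$decision, "included")) "included" else "rejected"
  prior
}

#' Final decision of a classification
#'
#' @param x a `delphi_classification`.
#' @return `"included"`, `"rejected"`, or `"round3"` when a fed-back choice
#'   has not yet received round-3 scores.
#' @export
final_decision <- function(x) {
  stopifnot(inherits(x, "delphi_classification"))
  if (!is.null(x$round3_final)) return(x$round3_final)
  x$decision
}

#' @export
print.delphi_classification <- function(x, ...) {
  cat(sprintf("<delphi_classification> %s (%s)\n", x$choice_name, x$choice_kind))
  cat("  strength:", x$strength_level)
  if (!is.null(x$impact_level)) cat("  impact:", x$impact_level)
  cat("\n  decision:", x$decision)
  if (!is.null(x$round3_final)) cat("  round3:", x$round3_final)
  cat("\n")
  invisible(x)
}

#' Run the full three-round classification over a response table
#'
#' The response table has one row per panellist score:
#' `choice_name, choice_kind, aspect, panellist_id, round, score`, where
#' `aspect` is `"strength"` (the single attribute aspect is also recorded as
#' strength) or `"impact"`, and `round` 3 rows hold the revised scores of
#' fed-back choices. Aspects not re-scored in round 3 reuse the earlier
#' scores.
#'
#' @param responses a data frame in the layout above.
#' @param thresholds a [delphi_thresholds()] object.
#' @return A data frame with one row per choice: the per-aspect levels, the
#'   rounds-1/2 decision, `round3_final` and the `final` decision.
#' @export
classify_delphi_responses <- function(responses, thresholds = delphi_thresholds()) {
  need <- c("choice_name", "choice_kind", "aspect", "round", "score")
  missing_cols <- setdiff(need, names(responses))
  if (length(missing_cols))
    stop("responses lack columns: ", paste(missing_cols, collapse = ", "), call. = FALSE)
  split_rows <- split(responses, responses$choice_name)
  rows <- lapply(split_rows, function(df) {
    kind <- unique(df$choice_kind)
    if (length(kind) != 1) stop("inconsistent choice_kind for ", df$choice_name[1], call. = FALSE)
    pick <- function(aspect, rnd3) {
      sel <- df$aspect == aspect & (if (rnd3) df$round == 3 else df$round < 3)
      df$score[sel]
    }
    s1 <- pick("strength", FALSE)
    i1 <- if (kind == "health_event") pick("impact", FALSE) else NULL
    cl <- classify_choice(df$choice_name[1], kind, s1, i1, thresholds)
    if (identical(cl$decision, "round3")) {
      s3 <- pick("strength", TRUE)
      i3 <- if (kind == "health_event") pick("impact", TRUE) else NULL
      has_r3 <- length(s3) > 0 || length(i3) > 0
      if (has_r3) {
        if (length(s3) == 0) s3 <- s1
        if (kind == "health_event" && length(i3) == 0) i3 <- i1
        cl <- apply_round3(cl, s3, i3, thresholds)
      }
    }
    data.frame(choice_name = cl$choice_name, choice_kind = cl$choice_kind,
               strength_level = cl$strength_level,
               impact_level = if (is.null(cl$impact_level)) NA_character_ else cl$impact_level,
               decision = cl$decision,
               round3_final = if (is.null(cl$round3_final)) NA_character_ else cl$round3_final,
               final = final_decision(cl),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Exhaustively classify every possible score vector of a panel
#'
#' Enumerates all `5^panel_size` Likert score vectors (every panellist scores
#' 1..5) by an arithmetic base-5 digit sweep, accumulating each vector's sum
#' and count of scores >= 4, and classifies every distinct
#' (mean, fraction-high) summary with [classify_aspect()]. Used to verify by
#' brute force that the agreement bands guarantee their stated minimum
#' consensus: with the default thresholds and a 9-member panel, every
#' acceptable vector has at least 8/9 panellists scoring 4 or 5 and every
#' moderate vector at least 6/9 scoring >= 4.
#'
#' @param panel_size number of panellists (default 9; capped at 9 so the
#'   enumeration stays around 2 million vectors).
#' @param thresholds a [delphi_thresholds()] object.
#' @return A data frame with one row per distinct (sum, n_high) summary:
#'   `mean_score`, `frac_high`, `level` and `n_vectors`, the number of score
#'   vectors sharing that summary (counts total `5^panel_size`).
#' @export
enumerate_score_vectors <- function(panel_size = 9, thresholds = delphi_thresholds()) {
  stopifnot(panel_size >= 1, panel_size <= 9)
  n_vec <- 5^panel_size
  idx <- 0:(n_vec - 1)
  total <- integer(n_vec)
  n_high <- integer(n_vec)
  for (d in seq_len(panel_size)) {
    digit <- (idx %/% 5^(d - 1)) %% 5 + 1L
    total <- total + digit
    n_high <- n_high + (digit >= 4L)
  }
  tab <- table(total, n_high)
  cells <- which(tab > 0, arr.ind = TRUE)
  sums <- as.integer(rownames(tab))[cells[, 1]]
  highs <- as.integer(colnames(tab))[cells[, 2]]
  level <- vapply(seq_along(sums), function(i) {
    classify_aspect(list(mean_score = sums[i] / panel_size,
                         frac_high = highs[i] / panel_size,
                         n = panel_size),
                    thresholds)
  }, character(1))
  out <- data.frame(sum = sums, n_high = highs,
                    mean_score = sums / panel_size,
                    frac_high = highs / panel_size,
                    level = level,
                    n_vectors = as.integer(tab[cells]))
  out[order(out$sum, out$n_high), , drop = FALSE]
}
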
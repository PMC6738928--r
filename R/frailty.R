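# Frailty measurement: deficit-accumulation index and physical phenotype.

#' Frailty category labels used throughout the package
#' @export
frailty_levels <- c("non_frail", "pre_frail", "frail")

#' Frailty Index (deficit accumulation)
#'
#' The FI is the proportion of health deficits present out of a fixed list of
#' measured deficits, e.g. 20 deficits out of 50 measured gives 0.4. Scale
#' invariant: `frailty_index(k, n) == frailty_index(m*k, m*n)`.
#'
#' @param deficits_present,deficits_total integer counts (vectorised).
#' @return FI score(s) in \[0, 1\].
#' @export
#' @examples
#' frailty_index(20, 50)  # 0.4
frailty_index <- function(deficits_present, deficits_total) {
  if (any(deficits_total <= 0)) stop("deficits_total must be positive", call. = FALSE)
  if (any(deficits_present < 0) || any(deficits_present > deficits_total))
    stop("deficits_present must lie in [0, deficits_total]", call. = FALSE)
  deficits_present / deficits_total
}

#' Frailty Phenotype category
#'
#' The physical phenotype counts five criteria (unintentional weight loss,
#' exhaustion, weak grip strength, slow walking speed, sedentary behaviour):
#' three or more present is frail, one or two pre-frail, none non-frail.
#'
#' @param criteria logical vector of length 5 (one individual) or a logical
#'   matrix with 5 columns (one row per individual); alternatively an integer
#'   criteria count in 0..5.
#' @return character vector of categories from [frailty_levels].
#' @export
phenotype_category <- function(criteria) {
  if (is.matrix(criteria)) {
    stopifnot(ncol(criteria) == 5)
    k <- rowSums(criteria != 0)
  } else if (is.logical(criteria)) {
    stopifnot(length(criteria) == 5)
    k <- sum(criteria)
  } else {
    k <- criteria
    if (any(is.na(k)) || any(k != round(k)) || any(k < 0) || any(k > 5))
      stop("criteria count must be an integer in 0..5", call. = FALSE)
  }
  ifelse(k >= 3, "frail", ifelse(k >= 1, "pre_frail", "non_frail"))
}

#' Map a Frailty Index score to a frailty category
#'
#' No canonical FI cutpoints exist for categorical use, so the two cutpoints
#' must be supplied explicitly. Intervals are half-open on the left:
#' `fi < c1` is non-frail, `c1 <= fi < c2` pre-frail, `fi >= c2` frail.
#'
#' @param fi numeric FI score(s) in \[0, 1\].
#' @param cutpoints numeric vector `c(c1, c2)` with `0 < c1 < c2 < 1`.
#' @return character vector of categories.
#' @export
fi_to_category <- function(fi, cutpoints) {
  if (missing(cutpoints) || is.null(cutpoints))
    stop("FI cutpoints must be configured; there is no baked-in default", call. = FALSE)
  stopifnot(length(cutpoints) == 2)
  c1 <- cutpoints[1]; c2 <- cutpoints[2]
  if (!(c1 > 0 && c1 < c2 && c2 < 1))
    stop("cutpoints must satisfy 0 < c1 < c2 < 1", call. = FALSE)
  if (any(fi < 0) || any(fi > 1)) stop("fi must lie in [0, 1]", call. = FALSE)
  ifelse(fi >= c2, "frail", ifelse(fi >= c1, "pre_frail", "non_frail"))
}
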
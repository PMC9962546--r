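# Income-rank concentration index.
#
# CI = 2 * cov_pop(LU, R) / mu, where LU_i is the indicator for unit i,
# R_i is the unit's fractional rank when units are ordered by per-capita
# disposable income, mu is the indicator mean, and cov_pop is the
# divide-by-n covariance (equivalently, the sum of cross-products divided
# by n). Positive values mean the indicator is concentrated among richer
# units, negative among poorer; the range is [-1, 1] for non-negative
# indicators.

#' Fractional ranks of units by an ordering variable
#'
#' Units sorted ascending receive ranks `(position - 0.5) / n`; tied
#' values receive the mean of their positions' ranks, so the ranks of
#' `(10, 10, 30)` are `(1/3, 1/3, 5/6)`. With no weights the mean rank is
#' exactly 1/2. A population-weighted variant (rank at the midpoint of
#' each unit's cumulative weight share) is available but is not the
#' default: the concentration index here treats each province as one
#' unit.
#'
#' @param ordering_values numeric vector (e.g. per-capita disposable
#'   income), length >= 2, all finite.
#' @param unit_ids optional unit labels carried through to the result.
#' @param weights optional positive weights for the weighted variant.
#' @return a `rank_vector`: list with `unit_ids`, `ranks` (in (0,1), in
#'   the input's unit order), `n` and `ordering_variable`.
#' @examples
#' fractional_ranks(c(10, 20))$ranks      # 0.25 0.75
#' fractional_ranks(c(10, 10, 30))$ranks  # 1/3 1/3 5/6
#' @export
fractional_ranks <- function(ordering_values, unit_ids = NULL,
                             weights = NULL) {
  n <- length(ordering_values)
  if (n < 2L) {
    abort_ltc("fractional ranks need at least 2 units",
              "ltcineq_insufficient_units_error")
  }
  if (any(!is.finite(ordering_values))) {
    abort_ltc("ordering values must all be finite",
              "ltcineq_validation_error")
  }
  if (is.null(unit_ids)) unit_ids <- as.character(seq_len(n))
  if (is.null(weights)) {
    ranks <- (rank(ordering_values, ties.method = "average") - 0.5) / n
  } else {
    stopifnot(length(weights) == n, all(weights > 0))
    ord <- order(ordering_values, unit_ids)
    w <- weights[ord] / sum(weights)
    # midpoint of each unit's weight interval on the cumulative scale
    r_sorted <- cumsum(w) - w / 2
    ranks <- numeric(n)
    ranks[ord] <- r_sorted
  }
  structure(list(unit_ids = unit_ids, ranks = ranks, n = n,
                 ordering_variable = deparse(substitute(ordering_values))),
            class = "rank_vector")
}

#' Concentration index of an indicator against socioeconomic rank
#'
#' Computes `CI = 2 * sum_i (LU_i - mu)(R_i - Rbar) / (n * mu)` — twice
#' the divide-by-n covariance between the indicator and the fractional
#' income rank, scaled by the indicator mean. The indicator and rank
#' vectors must describe the same units in the same order.
#'
#' @param indicator an [indicator_vector()], or a bare numeric vector of
#'   indicator values.
#' @param ranks a [fractional_ranks()] result aligned with `indicator`.
#' @return an `inequality_result` with `statistic =
#'   "concentration_index"` and `value` in `[-1, 1]`.
#' @examples
#' r <- fractional_ranks(c(100, 200))
#' concentration_index(c(1, 3), r)$value  # 0.25
#' @export
concentration_index <- function(indicator, ranks) {
  stopifnot(inherits(ranks, "rank_vector"))
  if (inherits(indicator, "indicator_vector")) {
    lu <- indicator$values
    ids <- indicator$unit_ids
    if (!identical(as.character(ids), as.character(ranks$unit_ids))) {
      abort_ltc("indicator and rank vectors describe different units",
                "ltcineq_alignment_error")
    }
  } else {
    lu <- as.numeric(indicator)
  }
  # the 1/n form: mu is the unweighted mean over units
  mu <- mean(lu)
  n <- length(lu)
  if (n != ranks$n) {
    abort_ltc("indicator and rank vectors have different lengths",
              "ltcineq_alignment_error")
  }
  if (!is.finite(mu) || mu <= 0) {
    abort_ltc("indicator mean must be positive: CI undefined",
              "ltcineq_undefined_ci_error")
  }
  r <- ranks$ranks
  ci <- 2 * sum((lu - mean(lu)) * (r - mean(r))) / (n * mu)
  ci <- min(max(ci, -1), 1)  # clamp roundoff at the theoretical bounds
  inequality_result("concentration_index", ci, n_units = n)
}
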
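#' Round half away from zero for display
#'
#' Rounds to a fixed number of decimal places with halves carried away from
#' zero (0.005 -> 0.01, -0.005 -> -0.01), the convention used by the
#' statistical-yearbook style tables this package reproduces. R's own
#' `round()` rounds half to even, which disagrees on exact halves.
#'
#' Intended for display and for comparing reconstructed rates against
#' printed tables only; internal computations are never rounded.
#'
#' @param x numeric vector.
#' @param places non-negative integer number of decimal places.
#' @return `x` rounded at `places` decimals, half away from zero.
#' @examples
#' round_display(0.005, 2)   # 0.01
#' round_display(-0.005, 2)  # -0.01
#' round_display(0.4377, 2)  # 0.44
#' @export
round_display <- function(x, places = 2L) {
  stopifnot(is.numeric(x), length(places) == 1L, places >= 0)
  f <- 10^places
  # nudge by an epsilon scaled to the value so that values that are exact
  # halves in decimal but land just below .5 in binary still round up
  sign(x) * floor(abs(x) * f + 0.5 + 1e-9 * pmax(1, abs(x))) / f
}

# internal: stop with a classed condition so callers/tests can match on class
abort_ltc <- function(msg, class) {
  stop(structure(
    class = c(class, "ltcineq_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

# internal: TRUE where x is a non-negative, finite number (NA allowed -> FALSE)
is_nonneg_number <- function(x) is.finite(x) & x >= 0
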
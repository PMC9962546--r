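#' Bootstrap-percentile interval for an inequality statistic
#'
#' Resamples units (provinces) with replacement `reps` times, recomputes
#' the statistic on each resample, and returns the percentile interval at
#' the requested coverage. A resample on which the statistic is undefined
#' (for instance, zero total resource) is redrawn and counted; if more
#' than half of the draws are degenerate the bootstrap fails. Fully
#' reproducible given `seed`; the global RNG state is restored on exit.
#'
#' The intervals are labelled bootstrap-percentile in all outputs because
#' that is exactly what they are; no analytic or jackknife variant is
#' offered.
#'
#' @param data a data frame (or list) of unit-level inputs, one row per
#'   unit.
#' @param statistic a function `data -> numeric(1)` computing the
#'   statistic on a (re)sampled data set; typically a closure around
#'   [gini()] or [concentration_index()].
#' @param reps number of bootstrap replicates B (>= 100).
#' @param level interval coverage in (0, 1); 0.95 by default.
#' @param seed integer seed; mandatory.
#' @return a list with `interval` (length-2 numeric), `level`, `reps`,
#'   `seed`, `n_degenerate` (redraw count) and `replicates` (the B
#'   bootstrap values).
#' @examples
#' d <- data.frame(pop = c(1, 1, 1, 1), res = c(1, 2, 3, 4))
#' f <- function(x) gini(lorenz_points(x$pop, x$res))$value
#' bootstrap_interval(d, f, reps = 200, seed = 7)$interval
#' @export
bootstrap_interval <- function(data, statistic, reps = 1000L,
                               level = 0.95, seed) {
  stopifnot(is.function(statistic), reps >= 100L, level > 0, level < 1)
  if (missing(seed)) {
    abort_ltc("a seed is mandatory for bootstrap intervals",
              "ltcineq_validation_error")
  }
  n <- if (is.data.frame(data)) nrow(data) else length(data)
  if (n < 2L) {
    abort_ltc("bootstrap needs at least 2 units",
              "ltcineq_insufficient_units_error")
  }
  take <- function(idx) {
    if (is.data.frame(data)) data[idx, , drop = FALSE] else data[idx]
  }

  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  })
  set.seed(seed)

  values <- numeric(reps)
  n_degenerate <- 0L
  max_degenerate <- ceiling(reps / 2)
  for (b in seq_len(reps)) {
    repeat {
      idx <- sample.int(n, n, replace = TRUE)
      v <- tryCatch(statistic(take(idx)), ltcineq_error = function(e) NA_real_)
      if (!is.na(v)) break
      n_degenerate <- n_degenerate + 1L
      if (n_degenerate > max_degenerate) {
        abort_ltc(sprintf(
          "bootstrap failed: %d degenerate resamples (> half of B = %d)",
          n_degenerate, reps), "ltcineq_bootstrap_error")
      }
    }
    values[b] <- v
  }
  alpha <- (1 - level) / 2
  interval <- unname(quantile(values, c(alpha, 1 - alpha), type = 7))
  list(interval = interval, level = level, reps = as.integer(reps),
       seed = as.integer(seed), n_degenerate = n_degenerate,
       replicates = values)
}
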
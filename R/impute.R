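#' Impute a missing urban/rural split for one year
#'
#' Some yearbook editions omit the urban/rural breakdown for a single
#' year. In `"five_year_average"` mode, every count column that is `NA`
#' in the target year is replaced, per (province, stratum), by the
#' arithmetic mean of that province/stratum's observed values over all
#' other years in the panel, and the record is flagged in the `imputed`
#' column. Whether such a proxy should average counts, rates or shares is
#' a genuinely open choice; this implements mean-of-counts and flags every
#' touched row so the proxy is always visible downstream.
#'
#' @param panel an [ltc_panel()].
#' @param year the calendar year whose stratum-level counts are missing.
#' @param mode `"none"` (default; return the panel unchanged) or
#'   `"five_year_average"`.
#' @return the panel with imputed counts and updated `imputed` flags.
#' @export
impute_stratum_split <- function(panel, year,
                                 mode = c("none", "five_year_average")) {
  mode <- match.arg(mode)
  stopifnot(inherits(panel, "ltc_panel"))
  if (mode == "none") return(panel)

  # optional counts that were never collected anywhere in the panel are
  # not a missing stratum split and are left alone; mandatory counts are
  # always imputable (and error without donor years)
  count_cols <- intersect(.count_cols, names(panel))
  optional <- intersect(count_cols, .optional_cols)
  never_observed <- optional[vapply(optional,
                                    function(col) all(is.na(panel[[col]])),
                                    logical(1))]
  count_cols <- setdiff(count_cols, never_observed)
  target <- which(panel$year == year)
  for (i in target) {
    donor <- which(panel$province == panel$province[i] &
                   panel$stratum == panel$stratum[i] &
                   panel$year != year)
    for (col in count_cols) {
      if (is.na(panel[[col]][i])) {
        obs <- panel[[col]][donor]
        obs <- obs[!is.na(obs)]
        if (length(obs) == 0L) {
          abort_ltc(sprintf(
            "cannot impute %s for %s/%s in %d: no observed years",
            col, panel$province[i], panel$stratum[i], year),
            "ltcineq_imputation_error")
        }
        panel[[col]][i] <- mean(obs)
        panel$imputed[i] <- TRUE
      }
    }
  }
  panel
}
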
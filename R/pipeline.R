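# Pipeline: panel -> indicators -> inequality tables.

#' Gini coefficient of one panel slice
#'
#' Computes the population-weighted grouped Gini of a raw resource count
#' against elderly-population size for a single (year, stratum) slice:
#' provinces are the groups, elderly population the weights, and the raw
#' count the resource amount, so the statistic measures how resource
#' shares deviate from elderly-population shares.
#'
#' @param panel an [ltc_panel()].
#' @param year,stratum the slice to analyse.
#' @param resource one of `"institutions"`, `"beds"`, `"workers"`,
#'   `"disabled_residents"`, `"rehab_nursing_services"`.
#' @param reps,level,seed bootstrap settings; `reps = 0` skips the
#'   interval (and `seed` may be omitted).
#' @return an `inequality_result`.
#' @export
panel_gini <- function(panel, year, stratum, resource = "beds",
                       reps = 0L, level = 0.95, seed = NULL) {
  resource <- match.arg(resource, c("institutions", "beds", "workers",
                                    "disabled_residents",
                                    "rehab_nursing_services"))
  slice <- panel[panel$year == year & panel$stratum == stratum, , drop = FALSE]
  if (nrow(slice) == 0L) {
    abort_ltc(sprintf("no records for %s/%s", year, stratum),
              "ltcineq_validation_error")
  }
  res <- gini(lorenz_points(slice$elderly_pop, slice[[resource]],
                            unit_ids = slice$province))
  res$n_units <- nrow(slice)
  if (reps > 0L) {
    stat <- function(d) {
      gini(lorenz_points(d$elderly_pop, d[[resource]]), classify = FALSE)$value
    }
    bs <- bootstrap_interval(slice, stat, reps = reps, level = level,
                             seed = seed)
    res$interval <- bs$interval; res$level <- bs$level
    res$reps <- bs$reps; res$seed <- bs$seed
  }
  res
}

#' Concentration index of one panel slice
#'
#' Computes the income-rank concentration index of a derived utilization
#' indicator for a single (year, stratum) slice: provinces are ranked by
#' per-capita disposable income (fractional ranks, one province = one
#' unit) and the index is twice the divide-by-n covariance between the
#' indicator and the rank, over the indicator mean.
#'
#' @inheritParams panel_gini
#' @param indicator an indicator name accepted by [indicator_vector()].
#' @return an `inequality_result`.
#' @export
panel_ci <- function(panel, year, stratum,
                     indicator = "disabled_residents_per_1000",
                     reps = 0L, level = 0.95, seed = NULL) {
  slice <- panel[panel$year == year & panel$stratum == stratum, , drop = FALSE]
  if (nrow(slice) < 2L) {
    abort_ltc(sprintf("need >= 2 provinces for %s/%s", year, stratum),
              "ltcineq_insufficient_units_error")
  }
  if (anyNA(slice$income_pc)) {
    abort_ltc("income_pc missing: concentration index not computable",
              "ltcineq_missing_indicator_error")
  }
  compute <- function(d) {
    iv <- indicator_vector(ltc_slice(d), indicator)
    rk <- fractional_ranks(d$income_pc, unit_ids = d$province)
    concentration_index(iv, rk)
  }
  res <- compute(slice)
  if (reps > 0L) {
    stat <- function(d) compute(d)$value
    bs <- bootstrap_interval(slice, stat, reps = reps, level = level,
                             seed = seed)
    res$interval <- bs$interval; res$level <- bs$level
    res$reps <- bs$reps; res$seed <- bs$seed
  }
  res
}

# internal: re-tag a slice data frame as ltc_panel without re-validation
# (bootstrap resamples duplicate provinces, which would trip the
# uniqueness invariant; inequality statistics are well defined anyway)
ltc_slice <- function(d) {
  structure(d, class = c("ltc_panel", class(tibble::tibble())))
}

#' Run the full inequality analysis
#'
#' Orchestrates ingestion (or synthesis), indicator aggregation and the
#' inequality statistics for every (year, stratum) cell of the panel:
#' population-weighted Gini coefficients for the three resource counts on
#' the full panel, and income-rank concentration indices for the two
#' utilization indicators on the exclusion-filtered panel. Utilization
#' statistics are skipped with a warning when the needed columns are
#' missing.
#'
#' @param panel an [ltc_panel()]; exactly one of `panel` / `synth` must
#'   be supplied.
#' @param synth a [synth_config()]; the panel is generated.
#' @param reps bootstrap replicates B per statistic (0 = no intervals).
#' @param level interval coverage.
#' @param seed integer seed, mandatory when `reps > 0` or synthesizing;
#'   per-statistic bootstrap seeds are derived from it deterministically.
#' @param exclude provinces excluded from utilization analyses.
#' @param outdir if non-`NULL`, write `aggregate_<stratum>.csv`,
#'   `gini.csv`, `concentration_index.csv` and `run_log.json` there.
#' @param round_places decimal places for displayed rates in aggregate
#'   files (inequality values are written at full precision plus a 3-dp
#'   display column).
#' @return a `report_bundle`: list with `aggregates` (one tibble per
#'   stratum), `gini` and `concentration` tibbles, and `log` (the
#'   resolved configuration).
#' @export
run_analysis <- function(panel = NULL, synth = NULL, reps = 1000L,
                         level = 0.95, seed = NULL,
                         exclude = utilization_exclusions(),
                         outdir = NULL, round_places = 2L) {
  if (is.null(panel) == is.null(synth)) {
    abort_ltc("supply exactly one of panel / synth", "ltcineq_validation_error")
  }
  if ((reps > 0L || !is.null(synth)) && is.null(seed)) {
    abort_ltc("seed is mandatory when bootstrapping or synthesizing",
              "ltcineq_validation_error")
  }
  truth <- NULL
  if (!is.null(synth)) {
    bundle <- synthesize_panel(synth)
    panel <- bundle$panel
    truth <- bundle$truth
  }
  stopifnot(inherits(panel, "ltc_panel"))

  cells <- unique(as.data.frame(panel[, c("year", "stratum")]))
  cells <- cells[order(cells$year, cells$stratum), ]
  util_panel <- apply_exclusions(panel, "utilization", exclude = exclude)

  gini_rows <- list(); ci_rows <- list(); warn_util <- FALSE
  k <- 0L
  for (i in seq_len(nrow(cells))) {
    yr <- cells$year[i]; st <- cells$stratum[i]
    for (resource in c("institutions", "beds", "workers")) {
      k <- k + 1L
      sub_seed <- if (is.null(seed)) NULL else (seed + k) %% .Machine$integer.max
      r <- panel_gini(panel, yr, st, resource, reps = reps, level = level,
                      seed = sub_seed)
      gini_rows[[k]] <- result_row(yr, st, paste0(resource, "_per_1000"), r)
    }
    for (ind in c("disabled_residents_per_1000", "services_per_resident")) {
      k <- k + 1L
      sub_seed <- if (is.null(seed)) NULL else (seed + k) %% .Machine$integer.max
      r <- tryCatch(
        panel_ci(util_panel, yr, st, ind, reps = reps, level = level,
                 seed = sub_seed),
        ltcineq_missing_indicator_error = function(e) NULL)
      if (is.null(r)) { warn_util <- TRUE; next }
      ci_rows[[length(ci_rows) + 1L]] <- result_row(yr, st, ind, r)
    }
  }
  if (warn_util) {
    warning("utilization columns missing for some cells; ",
            "concentration indices skipped there", call. = FALSE)
  }

  aggregates <- lapply(setNames(nm = sort(unique(panel$stratum))),
                       function(st) {
    agg <- aggregate_rates(ltc_slice(panel[panel$stratum == st, ]))
    rate_cols <- setdiff(names(agg), c("year", "stratum", "group",
                                       "elderly_pop"))
    for (col in rate_cols) agg[[col]] <- round_display(agg[[col]],
                                                       round_places)
    agg
  })

  bundle <- structure(list(
    aggregates = aggregates,
    gini = do.call(rbind, gini_rows),
    concentration = if (length(ci_rows)) do.call(rbind, ci_rows) else NULL,
    truth = truth,
    log = list(package_version = as.character(utils::packageVersion("ltcineq")),
               r_version = R.version.string,
               reps = reps, level = level, seed = seed,
               exclude = exclude, round_places = round_places,
               synthetic = !is.null(synth),
               provenance = attr(panel, "provenance"))),
    class = "report_bundle")

  if (!is.null(outdir)) {
    if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
    for (st in names(bundle$aggregates)) {
      write_table(bundle$aggregates[[st]],
                  file.path(outdir, sprintf("aggregate_%s.csv", st)))
    }
    write_table(bundle$gini, file.path(outdir, "gini.csv"))
    if (!is.null(bundle$concentration)) {
      write_table(bundle$concentration,
                  file.path(outdir, "concentration_index.csv"))
    }
    writeLines(jsonlite::toJSON(bundle$log, auto_unbox = TRUE, pretty = TRUE,
                                null = "null"),
               file.path(outdir, "run_log.json"))
  }
  bundle
}

# internal: one output row per inequality statistic
result_row <- function(year, stratum, indicator, r) {
  tibble::tibble(
    year = year, stratum = stratum, indicator = indicator,
    statistic = r$statistic, value = r$value,
    value_3dp = round_display(r$value, 3L),
    ci_low = if (is.null(r$interval)) NA_real_ else r$interval[1],
    ci_high = if (is.null(r$interval)) NA_real_ else r$interval[2],
    label = if (is.null(r$label)) NA_character_ else r$label,
    n = r$n_units,
    reps = if (is.null(r$reps)) NA_integer_ else r$reps,
    seed = if (is.null(r$seed)) NA_integer_ else r$seed)
}

#' Range of inequality values over a table subset
#'
#' Filters an inequality table (as produced by [run_analysis()], or any
#' data frame with `stratum`, `indicator` and a value column) and returns
#' the minimum and maximum of the values — e.g. the spread of all urban
#' Gini coefficients across years and indicators.
#'
#' @param table a data frame of inequality results.
#' @param stratum,indicator optional filters; `NULL` keeps everything.
#' @param value_col name of the value column (default `"value"`).
#' @return named numeric `c(min = , max = )`.
#' @export
summarize_range <- function(table, stratum = NULL, indicator = NULL,
                            value_col = "value") {
  stopifnot(is.data.frame(table), value_col %in% names(table))
  keep <- rep(TRUE, nrow(table))
  if (!is.null(stratum)) keep <- keep & table$stratum %in% stratum
  if (!is.null(indicator)) keep <- keep & table$indicator %in% indicator
  vals <- table[[value_col]][keep]
  if (length(vals) == 0L) {
    abort_ltc("no rows left after filtering", "ltcineq_empty_selection_error")
  }
  c(min = min(vals), max = max(vals))
}

#' @export
print.report_bundle <- function(x, ...) {
  cat(sprintf("<report_bundle> %d aggregate table(s), %d Gini row(s), %d CI row(s)\n",
              length(x$aggregates), NROW(x$gini), NROW(x$concentration)))
  invisible(x)
}
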
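# Indicator derivation: per-1000-elderly resource rates, per-resident
# service rates, and regional/national aggregation.

.resource_indicators <- c(institutions = "institutions_per_1000",
                          beds = "beds_per_1000",
                          workers = "workers_per_1000")
.utilization_indicators <- c(disabled_residents = "disabled_residents_per_1000",
                             rehab_nursing_services = "services_per_resident")

#' Resources per 1000 elderly persons
#'
#' The elderly population is recorded in thousands, so the per-1000 rate
#' is simply `count / elderly_pop`.
#'
#' @param count resource count (institutions, beds, workers, residents).
#' @param elderly_pop population aged 65+ in thousands; must be positive.
#' @return rate per 1000 persons aged 65+.
#' @examples
#' per_thousand_rate(15, 3)          # 5 per 1000
#' per_thousand_rate(970778, 62247)  # about 15.60 beds per 1000
#' @export
per_thousand_rate <- function(count, elderly_pop) {
  stopifnot(length(count) == length(elderly_pop))
  if (any(!is_nonneg_number(count))) {
    abort_ltc("count must be non-negative and finite",
              "ltcineq_validation_error")
  }
  if (any(!is.finite(elderly_pop) | elderly_pop <= 0)) {
    abort_ltc("elderly_pop must be positive: rate undefined",
              "ltcineq_undefined_rate_error")
  }
  count / elderly_pop
}

#' Services delivered per institutional resident
#'
#' @param services episode count of rehabilitation and nursing services.
#' @param residents number of institutional residents; must be positive —
#'   a zero denominator is an error, deliberately distinct from a rate of 0.
#' @return services per resident.
#' @export
services_per_resident <- function(services, residents) {
  stopifnot(length(services) == length(residents))
  if (any(!is_nonneg_number(services))) {
    abort_ltc("services must be non-negative and finite",
              "ltcineq_validation_error")
  }
  if (any(!is.finite(residents) | residents <= 0)) {
    abort_ltc("residents must be positive: rate undefined",
              "ltcineq_undefined_rate_error")
  }
  services / residents
}

#' Aggregate a panel to regional and national rates
#'
#' For every (year, stratum) cell, computes each group's rate as
#' (sum of counts in the group) / (sum of elderly population in the
#' group) — algebraically the elderly-population-weighted mean of the
#' province rates — for the three resource indicators and, where the
#' columns are present, the two utilization indicators. A `Total` row per
#' (year, stratum) aggregates over all groups. Rates are never computed
#' from previously rounded rates.
#'
#' @param panel an [ltc_panel()].
#' @param by grouping column, `"region"` (default) or `"province"`.
#' @return a tibble with columns `year`, `stratum`, `group`,
#'   `elderly_pop` (thousands) and one column per derivable indicator;
#'   `Total` rows carry the grouping label `"Total"`.
#' @examples
#' # two equal-population provinces with bed rates 1 and 3 average to 2
#' p <- ltc_panel(data.frame(
#'   province = c("Beijing", "Shanghai"), year = 2013, stratum = "urban",
#'   elderly_pop = c(100, 100), institutions = c(10, 10),
#'   beds = c(100, 300), workers = c(200, 200)))
#' aggregate_rates(p)
#' @export
aggregate_rates <- function(panel, by = c("region", "province")) {
  by <- match.arg(by)
  stopifnot(inherits(panel, "ltc_panel"))
  if (nrow(panel) == 0L) {
    abort_ltc("cannot aggregate an empty panel", "ltcineq_validation_error")
  }

  one_group <- function(rows, year, stratum, label) {
    pop <- sum(rows$elderly_pop)
    if (pop <= 0) {
      abort_ltc(sprintf("zero elderly population in group %s/%s/%s",
                        year, stratum, label),
                "ltcineq_undefined_rate_error")
    }
    out <- tibble::tibble(year = year, stratum = stratum, group = label,
                          elderly_pop = pop)
    for (cnt in names(.resource_indicators)) {
      out[[.resource_indicators[[cnt]]]] <-
        per_thousand_rate(sum(rows[[cnt]]), pop)
    }
    dis <- rows$disabled_residents
    out$disabled_residents_per_1000 <-
      if (anyNA(dis)) NA_real_ else per_thousand_rate(sum(dis), pop)
    svc <- rows$rehab_nursing_services
    out$services_per_resident <-
      if (anyNA(svc) || anyNA(dis) || sum(dis) == 0) NA_real_
      else services_per_resident(sum(svc), sum(dis))
    out
  }

  cells <- unique(panel[, c("year", "stratum")])
  res <- lapply(seq_len(nrow(cells)), function(k) {
    yr <- cells$year[k]; st <- cells$stratum[k]
    sub <- panel[panel$year == yr & panel$stratum == st, , drop = FALSE]
    groups <- sort(unique(sub[[by]]))
    rows <- lapply(groups, function(g) {
      one_group(sub[sub[[by]] == g, , drop = FALSE], yr, st, g)
    })
    rows <- c(rows, list(one_group(sub, yr, st, "Total")))
    do.call(rbind, rows)
  })
  out <- do.call(rbind, res)
  out[order(out$year, out$stratum, out$group != "Total", out$group), ]
}

#' Build an indicator vector for inequality analysis
#'
#' Extracts one indicator as province-level values `LU_i` with their
#' elderly-population weights, for a single (year, stratum) slice of a
#' panel. The mean is the unweighted mean over provinces by default, the
#' `1/n` form used by the concentration index; a population-weighted mean
#' is available for descriptive use.
#'
#' @param panel an [ltc_panel()] restricted to one year and stratum.
#' @param indicator one of `"institutions_per_1000"`, `"beds_per_1000"`,
#'   `"workers_per_1000"`, `"disabled_residents_per_1000"`,
#'   `"services_per_resident"`.
#' @param weighted_mean if `TRUE`, the stored mean is weighted by
#'   elderly population.
#' @return an `indicator_vector`: list with `indicator`, `unit_ids`,
#'   `values`, `weights` (elderly_pop, thousands), `mean`, `n`.
#' @export
indicator_vector <- function(panel, indicator, weighted_mean = FALSE) {
  stopifnot(inherits(panel, "ltc_panel"))
  choices <- unname(c(.resource_indicators, .utilization_indicators))
  indicator <- match.arg(indicator, choices)
  if (length(unique(panel$year)) > 1L || length(unique(panel$stratum)) > 1L) {
    abort_ltc("indicator_vector expects a single (year, stratum) slice",
              "ltcineq_validation_error")
  }
  if (nrow(panel) < 1L) {
    abort_ltc("indicator_vector needs at least one province",
              "ltcineq_validation_error")
  }
  needed <- switch(indicator,
    institutions_per_1000 = "institutions",
    beds_per_1000         = "beds",
    workers_per_1000      = "workers",
    disabled_residents_per_1000 = "disabled_residents",
    services_per_resident = c("rehab_nursing_services",
                              "disabled_residents"))
  if (anyNA(panel[, needed])) {
    abort_ltc(sprintf("indicator %s not derivable: missing counts", indicator),
              "ltcineq_missing_indicator_error")
  }
  pop <- panel$elderly_pop
  values <- switch(indicator,
    institutions_per_1000 = per_thousand_rate(panel$institutions, pop),
    beds_per_1000         = per_thousand_rate(panel$beds, pop),
    workers_per_1000      = per_thousand_rate(panel$workers, pop),
    disabled_residents_per_1000 =
      per_thousand_rate(panel$disabled_residents, pop),
    services_per_resident =
      services_per_resident(panel$rehab_nursing_services,
                            panel$disabled_residents))
  if (anyNA(values)) {
    abort_ltc(sprintf("indicator %s not derivable: missing counts", indicator),
              "ltcineq_missing_indicator_error")
  }
  mu <- if (weighted_mean) sum(values * pop) / sum(pop) else mean(values)
  structure(list(indicator = indicator, unit_ids = panel$province,
                 values = values, weights = pop, mean = mu,
                 n = length(values), weighted_mean = weighted_mean),
            class = "indicator_vector")
}

#' @export
print.indicator_vector <- function(x, ...) {
  cat(sprintf("<indicator_vector> %s: n = %d, mean = %.4f\n",
              x$indicator, x$n, x$mean))
  invisible(x)
}
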
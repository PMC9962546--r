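# Region schemes and province exclusion rules.

#' Region scheme: province -> economic region
#'
#' Loads a mapping from province names to region labels. The default,
#' shipped with the package, is the standard three-way economic partition
#' of the 31 mainland-China provinces: 11 Eastern (developed), 8 Central
#' (developing) and 12 Western (undeveloped) provinces, grouped by
#' geography and GDP per capita. Any two-column `province,region` CSV can
#' be supplied instead, so panels from other settings can be analyzed.
#'
#' @param path path to a `province,region` CSV; `NULL` (default) loads the
#'   scheme shipped with the package.
#' @return a named character vector mapping lower-cased, trimmed province
#'   names to region labels, with the original spellings kept in
#'   `attr(, "display")`.
#' @examples
#' scheme <- region_scheme()
#' table(scheme)
#' @export
region_scheme <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "region_scheme.csv", package = "ltcineq",
                        mustWork = TRUE)
  }
  tab <- utils::read.csv(path, colClasses = "character", strip.white = TRUE,
                         fileEncoding = "UTF-8")
  if (!all(c("province", "region") %in% tolower(names(tab)))) {
    abort_ltc("region scheme file needs columns 'province' and 'region'",
              "ltcineq_schema_error")
  }
  names(tab) <- tolower(names(tab))
  key <- tolower(trimws(tab$province))
  if (anyDuplicated(key)) {
    abort_ltc("region scheme maps some province more than once",
              "ltcineq_validation_error")
  }
  structure(setNames(trimws(tab$region), key),
            display = setNames(trimws(tab$province), key))
}

#' Look up the region of a province
#'
#' Matching is case-insensitive after trimming whitespace; there is no
#' fuzzy matching, so a misspelled province is an error, not a guess.
#'
#' @param province province name.
#' @param scheme a scheme from [region_scheme()].
#' @return the region label, e.g. `"Eastern"`.
#' @examples
#' assign_region("Beijing")   # "Eastern"
#' assign_region("Sichuan")   # "Western"
#' @export
assign_region <- function(province, scheme = region_scheme()) {
  stopifnot(length(province) == 1L, length(scheme) >= 1L)
  key <- tolower(trimws(province))
  if (!key %in% names(scheme)) {
    abort_ltc(sprintf("unknown province: '%s'", province),
              "ltcineq_lookup_error")
  }
  unname(scheme[[key]])
}

#' Default utilization exclusion list
#'
#' Provinces with seriously incomplete utilization records (Hainan, Tibet,
#' Inner Mongolia, Jilin in the default Chinese panel) are dropped from
#' utilization-inequality analyses but kept for resource analyses.
#'
#' @param path path to a one-column `province` CSV; `NULL` loads the
#'   default list shipped with the package.
#' @return character vector of province names.
#' @export
utilization_exclusions <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "exclusions_utilization.csv",
                        package = "ltcineq", mustWork = TRUE)
  }
  tab <- utils::read.csv(path, colClasses = "character", strip.white = TRUE,
                         fileEncoding = "UTF-8")
  trimws(tab[[1]])
}

#' Apply purpose-specific province exclusions
#'
#' For `purpose = "utilization"` removes the provinces on the exclusion
#' list (case-insensitive match); for `purpose = "resources"` removes
#' nothing. Idempotent, and never adds rows.
#'
#' @param panel an [ltc_panel()].
#' @param purpose `"resources"` or `"utilization"`.
#' @param exclude character vector of provinces to drop for utilization
#'   analyses; defaults to [utilization_exclusions()].
#' @return the filtered `ltc_panel` (attributes preserved).
#' @export
apply_exclusions <- function(panel, purpose = c("resources", "utilization"),
                             exclude = utilization_exclusions()) {
  purpose <- match.arg(purpose)
  stopifnot(inherits(panel, "ltc_panel"))
  if (purpose == "resources" || nrow(panel) == 0L) return(panel)
  keep <- !tolower(panel$province) %in% tolower(trimws(exclude))
  out <- panel[keep, , drop = FALSE]
  attributes_to_keep <- attributes(panel)[c("scheme", "provenance", "class")]
  attributes(out)[names(attributes_to_keep)] <- attributes_to_keep
  out
}
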
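# Panel data model and delimited-text I/O.
#
# A panel is a tibble with one row per (province, year, stratum) carrying
# raw resource counts, utilization counts and per-capita income, plus a
# region scheme attached as an attribute. elderly_pop is stored in
# THOUSANDS of persons aged 65+, exactly as the yearbook-style tables
# print it; all per-1000 rate arithmetic relies on that unit.

.mandatory_cols <- c("province", "year", "stratum", "elderly_pop",
                     "institutions", "beds", "workers")
.optional_cols  <- c("disabled_residents", "rehab_nursing_services",
                     "income_pc")
.count_cols     <- c("elderly_pop", "institutions", "beds", "workers",
                     "disabled_residents", "rehab_nursing_services")
.panel_cols     <- c(.mandatory_cols, .optional_cols)

#' Construct a validated LTC panel
#'
#' Builds an `ltc_panel` from a data frame of province/year/stratum rows,
#' validating non-negativity, positivity of income, and uniqueness of the
#' (province, year, stratum) key. Optional columns that are absent are
#' added as `NA` so downstream code sees a fixed schema.
#'
#' @param records data frame with columns `province`, `year`, `stratum`
#'   (`"urban"` or `"rural"`), `elderly_pop` (thousands of persons aged
#'   65+), `institutions`, `beds`, `workers`, and optionally
#'   `disabled_residents`, `rehab_nursing_services`, `income_pc`.
#' @param scheme region scheme from [region_scheme()]; defaults to the
#'   31-province Eastern/Central/Western scheme shipped with the package.
#' @param provenance free-text note on where the records come from.
#' @return an `ltc_panel` tibble with the scheme and provenance attached
#'   as attributes and a `region` column resolved from the scheme
#'   (`NA` with a warning for provinces the scheme does not cover).
#' @seealso [read_panel()] to build one from a delimited file.
#' @export
ltc_panel <- function(records, scheme = region_scheme(),
                      provenance = "unspecified") {
  stopifnot(is.data.frame(records))
  missing_cols <- setdiff(.mandatory_cols, names(records))
  if (length(missing_cols) > 0L) {
    abort_ltc(sprintf("panel is missing mandatory column(s): %s",
                      paste(missing_cols, collapse = ", ")),
              "ltcineq_schema_error")
  }
  records <- tibble::as_tibble(records)
  for (col in setdiff(.optional_cols, names(records))) {
    records[[col]] <- NA_real_
  }
  records <- records[, c(.panel_cols,
                         setdiff(names(records), .panel_cols))]
  records$province <- trimws(as.character(records$province))
  records$stratum  <- tolower(trimws(as.character(records$stratum)))

  bad_stratum <- !records$stratum %in% c("urban", "rural")
  if (any(bad_stratum)) {
    abort_ltc(sprintf("stratum must be 'urban' or 'rural' (rows: %s)",
                      paste(which(bad_stratum), collapse = ", ")),
              "ltcineq_validation_error")
  }
  for (col in .count_cols) {
    bad <- !is.na(records[[col]]) & records[[col]] < 0
    if (any(bad)) {
      abort_ltc(sprintf("negative %s (rows: %s)", col,
                        paste(which(bad), collapse = ", ")),
                "ltcineq_validation_error")
    }
  }
  bad_income <- !is.na(records$income_pc) & records$income_pc <= 0
  if (any(bad_income)) {
    abort_ltc(sprintf("income_pc must be positive when present (rows: %s)",
                      paste(which(bad_income), collapse = ", ")),
              "ltcineq_validation_error")
  }
  key <- paste(tolower(records$province), records$year, records$stratum)
  if (anyDuplicated(key)) {
    dups <- unique(key[duplicated(key)])
    abort_ltc(sprintf("duplicate (province, year, stratum) key(s): %s",
                      paste(dups, collapse = "; ")),
              "ltcineq_uniqueness_error")
  }

  records$region <- vapply(records$province, function(p) {
    tryCatch(assign_region(p, scheme), error = function(e) NA_character_)
  }, character(1), USE.NAMES = FALSE)
  if (anyNA(records$region)) {
    warning(sprintf("province(s) not covered by the region scheme: %s",
                    paste(unique(records$province[is.na(records$region)]),
                          collapse = ", ")), call. = FALSE)
  }
  if (!"imputed" %in% names(records)) records$imputed <- FALSE

  structure(records,
            class = c("ltc_panel", class(tibble::tibble())),
            scheme = scheme, provenance = provenance)
}

#' Read a delimited panel table
#'
#' Reads a UTF-8 delimited text file (comma by default, tab accepted) with
#' a header row into a validated [ltc_panel()]. Numeric cells that fail to
#' parse are reported with their row numbers.
#'
#' @param path path to the file.
#' @param delim field delimiter, `","` (default) or `"\t"`.
#' @inheritParams ltc_panel
#' @return an `ltc_panel`.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeLines(c(
#'   "province,year,stratum,elderly_pop,institutions,beds,workers",
#'   "Beijing,2013,urban,2000,300,40000,5000",
#'   "Sichuan,2013,urban,5000,400,50000,6000"), f)
#' read_panel(f)
#' @export
read_panel <- function(path, delim = ",", scheme = region_scheme(),
                       provenance = path) {
  if (!file.exists(path)) {
    abort_ltc(sprintf("panel file not found: %s", path), "ltcineq_io_error")
  }
  raw <- utils::read.csv(path, sep = delim, colClasses = "character",
                         check.names = TRUE, fileEncoding = "UTF-8",
                         strip.white = TRUE)
  names(raw) <- tolower(names(raw))
  missing_cols <- setdiff(.mandatory_cols, names(raw))
  if (length(missing_cols) > 0L) {
    abort_ltc(sprintf("file %s is missing mandatory column(s): %s",
                      path, paste(missing_cols, collapse = ", ")),
              "ltcineq_schema_error")
  }
  num_cols <- intersect(c("year", .count_cols, "income_pc"), names(raw))
  for (col in num_cols) {
    blank <- is.na(raw[[col]]) | raw[[col]] == ""
    parsed <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- !blank & is.na(parsed)
    if (any(bad)) {
      abort_ltc(sprintf(
        "malformed numeric value(s) in column '%s' at data row(s) %s of %s",
        col, paste(which(bad), collapse = ", "), path),
        "ltcineq_parse_error")
    }
    raw[[col]] <- parsed
  }
  ltc_panel(raw, scheme = scheme, provenance = provenance)
}

#' Write a tabular result as delimited text
#'
#' Writes any data frame (panels, aggregate tables, inequality tables) as
#' a delimited text file with a header row and stable column order, so
#' that writing and re-reading a panel round-trips field for field.
#'
#' @param table a data frame; may have zero rows (header-only file).
#' @param path output path; the directory must exist.
#' @param delim field delimiter, `","` by default.
#' @return `path`, invisibly.
#' @export
write_table <- function(table, path, delim = ",") {
  stopifnot(is.data.frame(table))
  dir <- dirname(path)
  if (!dir.exists(dir)) {
    abort_ltc(sprintf("output directory does not exist: %s", dir),
              "ltcineq_io_error")
  }
  out <- as.data.frame(table)
  # drop derived columns so a written panel re-reads through read_panel
  out <- out[, setdiff(names(out), c("region")), drop = FALSE]
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' @export
print.ltc_panel <- function(x, ...) {
  cat(sprintf("<ltc_panel> %d record(s), %d province(s), years %s, strata: %s\n",
              nrow(x), length(unique(x$province)),
              if (nrow(x)) paste(range(x$year), collapse = "-") else "-",
              paste(sort(unique(x$stratum)), collapse = ", ")))
  cat(sprintf("  provenance: %s\n", attr(x, "provenance")))
  NextMethod()
}
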
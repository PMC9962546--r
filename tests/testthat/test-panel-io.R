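test_that("a well-formed file parses into one record per row and round-trips", {
  f <- tempfile(fileext = ".csv")
  writeLines(c(
    "province,year,stratum,elderly_pop,institutions,beds,workers,income_pc",
    "Beijing,2013,urban,2000,300,40000,5000,40000",
    "Anhui,2013,urban,3000,240,24000,3000,20000",
    "Sichuan,2013,urban,5000,400,50000,6000,18000"), f)
  p <- read_panel(f)
  expect_s3_class(p, "ltc_panel")
  expect_equal(nrow(p), 3L)
  expect_equal(p$region, c("Eastern", "Central", "Western"))
  expect_true(all(is.na(p$disabled_residents)))  # absent optional column

  # write_table . read_panel is the identity, field for field
  g <- tempfile(fileext = ".csv")
  write_table(p, g)
  p2 <- read_panel(g)
  for (col in c("province", "year", "stratum", "elderly_pop",
                "institutions", "beds", "workers", "income_pc")) {
    expect_equal(p2[[col]], p[[col]], info = col)
  }
})

test_that("schema, parse and validation errors name the offender", {
  f <- tempfile(fileext = ".csv")
  writeLines(c("province,year,stratum,institutions,beds,workers",
               "Beijing,2013,urban,300,40000,5000"), f)
  expect_error(read_panel(f), "elderly_pop", class = "ltcineq_schema_error")

  g <- tempfile(fileext = ".csv")
  writeLines(c("province,year,stratum,elderly_pop,institutions,beds,workers",
               "Beijing,2013,urban,2000,300,oops,5000"), g)
  expect_error(read_panel(g), "row.* 1", class = "ltcineq_parse_error")

  expect_error(
    make_panel(beds = c(-1, 24000, 50000)),
    "beds", class = "ltcineq_validation_error")
  expect_error(
    make_panel(provinces = c("Beijing", "Beijing", "Sichuan")),
    class = "ltcineq_uniqueness_error")
  expect_error(read_panel(tempfile()), class = "ltcineq_io_error")
})

test_that("tab-delimited input and case-insensitive provinces are accepted", {
  f <- tempfile(fileext = ".tsv")
  writeLines(c("province\tyear\tstratum\telderly_pop\tinstitutions\tbeds\tworkers",
               "  beijing \t2013\turban\t2000\t300\t40000\t5000"), f)
  p <- read_panel(f, delim = "\t")
  expect_equal(p$region, "Eastern")
})

test_that("the default scheme partitions 31 provinces into 11/8/12 regions", {
  scheme <- region_scheme()
  expect_length(scheme, 31L)
  counts <- table(scheme)
  expect_equal(unname(counts[c("Eastern", "Central", "Western")]),
               c(11L, 8L, 12L), ignore_attr = TRUE)
  expect_equal(assign_region("Beijing"), "Eastern")
  expect_equal(assign_region("Sichuan"), "Western")
  expect_equal(assign_region("  SHANGHAI "), "Eastern")
  expect_error(assign_region("Atlantis"), class = "ltcineq_lookup_error")
})

test_that("utilization exclusions drop exactly the four flagged provinces", {
  p <- make_full_panel()
  expect_equal(nrow(p), 31L)
  u <- apply_exclusions(p, "utilization")
  expect_equal(nrow(u), 27L)
  expect_false(any(c("Hainan", "Tibet", "Inner Mongolia", "Jilin")
                   %in% u$province))
  # resources purpose removes nothing; exclusion is idempotent
  expect_equal(nrow(apply_exclusions(p, "resources")), 31L)
  expect_equal(apply_exclusions(u, "utilization")$province, u$province)
  # empty panel passes through both purposes
  e <- p[0, ]
  expect_equal(nrow(apply_exclusions(ltcineq:::ltc_slice(e), "utilization")), 0L)
})

test_that("five-year-average imputation fills missing counts with the mean", {
  df <- data.frame(province = "Beijing", year = 2013:2017, stratum = "urban",
                   elderly_pop = 2000, institutions = 300,
                   beds = c(10, 20, NA, 30, 40), workers = 5000)
  p <- ltc_panel(df)
  out <- impute_stratum_split(p, 2015, mode = "five_year_average")
  expect_equal(out$beds[out$year == 2015], 25)  # mean of 10,20,30,40
  expect_true(out$imputed[out$year == 2015])
  expect_false(any(out$imputed[out$year != 2015]))

  # mode = none is the identity
  expect_equal(impute_stratum_split(p, 2015, mode = "none")$beds, p$beds)

  # no observed donor years -> imputation error
  df$beds <- NA_real_
  expect_error(
    impute_stratum_split(ltc_panel(df), 2015, mode = "five_year_average"),
    class = "ltcineq_imputation_error")
})

test_that("write_table handles empty tables and missing directories", {
  f <- tempfile(fileext = ".csv")
  write_table(make_panel()[0, ], f)
  expect_equal(length(readLines(f)), 1L)  # header only
  expect_error(
    write_table(make_panel(), file.path(tempfile(), "no", "such", "dir.csv")),
    class = "ltcineq_io_error")
})
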
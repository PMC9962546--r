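test_that("per-1000 and per-resident rates follow their definitions", {
  expect_equal(per_thousand_rate(0, 500), 0)
  expect_equal(per_thousand_rate(15, 3), 5)
  # a national-scale division, checked at display precision
  expect_equal(round_display(per_thousand_rate(970778, 62247), 2), 15.60)
  expect_error(per_thousand_rate(10, 0), class = "ltcineq_undefined_rate_error")

  expect_equal(services_per_resident(0, 10), 0)
  expect_equal(services_per_resident(30, 10), 3)
  expect_error(services_per_resident(30, 0),
               class = "ltcineq_undefined_rate_error")
})

test_that("display rounding is half-away-from-zero", {
  expect_equal(round_display(0.4377, 2), 0.44)
  expect_equal(round_display(0.005, 2), 0.01)
  expect_equal(round_display(-0.005, 2), -0.01)
  expect_equal(round_display(0.125, 2), 0.13)   # R's round() would give 0.12
  expect_equal(round_display(2.5, 0), 3)
  expect_equal(round_display(15.595, 2), 15.60)
})

test_that("group rates equal the population-weighted mean of member rates", {
  # two equal-population provinces with bed rates 1 and 3 average to 2
  p <- make_panel(elderly_pop = c(100, 100, 200),
                  beds = c(100, 300, 400))
  agg <- aggregate_rates(p)
  total <- agg[agg$group == "Total", ]
  expect_equal(total$beds_per_1000, sum(c(100, 300, 400)) / 400)

  # single-province group: group rate equals the province rate
  east <- agg[agg$group == "Eastern", ]
  expect_equal(east$beds_per_1000, 100 / 100)
})

test_that("aggregation is consistent, scale invariant and monotone", {
  p <- make_full_panel(seed = 21)
  agg <- aggregate_rates(p)
  total <- agg[agg$group == "Total", ]
  regions <- agg[agg$group != "Total", ]
  # Total population is the sum of region populations
  expect_equal(total$elderly_pop, sum(regions$elderly_pop))
  # Total rate is the population-weighted mean of region rates, exactly
  for (col in c("institutions_per_1000", "beds_per_1000",
                "workers_per_1000")) {
    expect_equal(total[[col]],
                 sum(regions[[col]] * regions$elderly_pop) /
                   sum(regions$elderly_pop),
                 tolerance = 1e-12, info = col)
  }
  # scaling every count and population by c > 0 leaves rates unchanged
  p2 <- p
  for (col in c("elderly_pop", "institutions", "beds", "workers",
                "disabled_residents", "rehab_nursing_services")) {
    p2[[col]] <- p2[[col]] * 7
  }
  agg2 <- aggregate_rates(ltcineq:::ltc_slice(p2))
  expect_equal(agg2$beds_per_1000, agg$beds_per_1000, tolerance = 1e-12)
  # adding beds strictly increases the group bed rate
  p3 <- p
  p3$beds[1] <- p3$beds[1] + 1000
  agg3 <- aggregate_rates(ltcineq:::ltc_slice(p3))
  expect_gt(agg3$beds_per_1000[agg3$group == "Total"],
            agg$beds_per_1000[agg$group == "Total"])
})

test_that("indicator vectors carry aligned values, weights and the 1/n mean", {
  p <- make_full_panel(seed = 31)
  iv <- indicator_vector(p, "beds_per_1000")
  expect_equal(iv$n, 31L)
  expect_equal(iv$values, p$beds / p$elderly_pop)
  expect_equal(iv$mean, mean(iv$values))
  ivw <- indicator_vector(p, "beds_per_1000", weighted_mean = TRUE)
  expect_equal(ivw$mean,
               sum(iv$values * p$elderly_pop) / sum(p$elderly_pop))
  # utilization indicator with missing counts is an explicit error
  p$disabled_residents <- NA_real_
  expect_error(indicator_vector(p, "disabled_residents_per_1000"),
               class = "ltcineq_missing_indicator_error")
})
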
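test_that("fractional ranks follow the (position - 0.5)/n rule with tie averaging", {
  expect_equal(fractional_ranks(c(10, 20))$ranks, c(0.25, 0.75))
  expect_equal(fractional_ranks(c(10, 10, 30))$ranks, c(1/3, 1/3, 5/6))
  # ranks reattach to the same units whatever the input order
  fwd <- fractional_ranks(c(5, 1, 9), unit_ids = c("a", "b", "c"))
  rev <- fractional_ranks(c(9, 1, 5), unit_ids = c("c", "b", "a"))
  expect_equal(setNames(fwd$ranks, fwd$unit_ids)[c("a", "b", "c")],
               setNames(rev$ranks, rev$unit_ids)[c("a", "b", "c")])
  # unweighted mean rank is exactly 1/2
  set.seed(8)
  expect_equal(mean(fractional_ranks(rnorm(17))$ranks), 0.5)
  expect_error(fractional_ranks(3), class = "ltcineq_insufficient_units_error")
  expect_error(fractional_ranks(c(1, Inf)), class = "ltcineq_validation_error")
})

test_that("population-weighted ranks sit at cumulative weight midpoints", {
  r <- fractional_ranks(c(10, 20, 30), weights = c(1, 2, 1))
  expect_equal(r$ranks, c(0.125, 0.5, 0.875))
})

test_that("the concentration index matches its brute-force definition", {
  # LU = (1, 3) on ranks (0.25, 0.75): 2 * 0.5 / (2 * 2) = 0.25
  expect_equal(concentration_index(c(1, 3), fractional_ranks(c(10, 20)))$value,
               0.25)
  # brute-force cross-product oracle on random cases
  for (s in 1:100) {
    set.seed(s)
    n <- sample(3:30, 1)
    lu <- exp(rnorm(n)); inc <- rnorm(n)
    rk <- fractional_ranks(inc)
    brute <- 2 * sum((lu - mean(lu)) * (rk$ranks - mean(rk$ranks))) /
      (n * mean(lu))
    expect_equal(concentration_index(lu, rk)$value, brute,
                 tolerance = 1e-12, info = paste("seed", s))
    expect_lte(abs(concentration_index(lu, rk)$value), 1)
  }
})

test_that("a constant indicator has zero concentration", {
  expect_equal(concentration_index(rep(2, 5),
                                   fractional_ranks(c(1, 5, 2, 9, 4)))$value, 0)
})

test_that("reversing the income ordering negates the index exactly", {
  set.seed(7)
  lu <- exp(rnorm(12)); inc <- rnorm(12)
  ci_fwd <- concentration_index(lu, fractional_ranks(inc))$value
  ci_rev <- concentration_index(lu, fractional_ranks(-inc))$value
  expect_equal(ci_rev, -ci_fwd, tolerance = 1e-12)
})

test_that("equal-weight CI ranked by the indicator itself equals its Gini", {
  expect_equal(concentration_index(c(1, 3), fractional_ranks(c(1, 3)))$value,
               gini(lorenz_points(c(1, 1), c(1, 3)))$value)  # both 0.25
  for (s in 1:50) {
    set.seed(1000 + s)
    n <- sample(3:40, 1)
    lu <- exp(rnorm(n, 0, 0.7))  # distinct values a.s., equal weights
    ci <- concentration_index(lu, fractional_ranks(lu))$value
    g <- gini(lorenz_points(rep(1, n), lu))$value
    expect_equal(ci, g, tolerance = 1e-9, info = paste("seed", s))
  }
})

test_that("CI is scale invariant and needs a positive mean", {
  set.seed(5)
  lu <- exp(rnorm(10)); rk <- fractional_ranks(rnorm(10))
  expect_equal(concentration_index(lu * 500, rk)$value,
               concentration_index(lu, rk)$value, tolerance = 1e-12)
  expect_error(concentration_index(rep(0, 10), rk),
               class = "ltcineq_undefined_ci_error")
  # misaligned unit ids are an alignment error
  p <- make_full_panel(seed = 41)
  iv <- indicator_vector(p, "beds_per_1000")
  rk2 <- fractional_ranks(p$income_pc, unit_ids = rev(p$province))
  expect_error(concentration_index(iv, rk2),
               class = "ltcineq_alignment_error")
})
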
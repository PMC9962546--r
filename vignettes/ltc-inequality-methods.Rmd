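---
title: "Measuring inequality in long-term-care resource panels: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring inequality in long-term-care resource panels: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ltcineq)
```

# The data model

The unit of analysis is a province (or any administrative unit) observed
in a calendar year within a stratum (urban or rural). Each record carries
raw counts — long-term-care institutions, beds, workers, disabled
residents, rehabilitation-and-nursing service episodes — together with
the population aged 65+ **in thousands** and per-capita disposable income.
Storing the elderly population in thousands is deliberate: it is the unit
in which yearbook-style tables print it, and it makes every per-1000
indicator a plain ratio `count / elderly_pop` with no hidden factor.

Three structural rules are enforced at construction time: counts are
non-negative, income is strictly positive when present, and
(province, year, stratum) is a unique key. Province names are matched
case-insensitively after trimming; there is deliberately no fuzzy
matching, because a silent wrong match in an inequality analysis is far
worse than a loud lookup error.

The default region scheme partitions the 31 mainland-China provinces
into 11 Eastern, 8 Central and 12 Western provinces by geography and
GDP per capita, and the default utilization analysis excludes Hainan,
Tibet, Inner Mongolia and Jilin, whose utilization records are
seriously incomplete in the source yearbooks. Both lists are plain CSV
files under `inst/extdata/` and can be replaced wholesale, so panels
from other countries are first-class inputs.

## The missing-stratum proxy

Some yearbook editions omit the urban/rural split for one year.
`impute_stratum_split()` offers a mean-of-counts proxy: each missing
count is replaced by the arithmetic mean of that province/stratum's
observed values over the other years, and the record is flagged. Whether
such a proxy should average counts, rates or shares is genuinely
ambiguous, which is why the mode defaults to `"none"` and every touched
row carries `imputed = TRUE`. Optional count columns that were never
collected anywhere in a panel are left alone — an absent measurement
programme is not a missing split — while a mandatory count with no
observed donor years raises an error rather than inventing data.

# Indicators and aggregation

Group rates (regional or national) are always computed as summed counts
over summed population, never as means of previously rounded rates. The
two forms are algebraically identical at full precision — the summed-count
rate *is* the population-weighted mean of member rates — but the
summed-count route means that when a printed table is reconstructed from
its own rounded regional rows, the only error carried is the rounding of
those inputs. Reconstructing national totals from published 2-dp regional
rates reproduces the published national rates to within one unit in the
last printed digit, which is exactly the attainable agreement: a value
whose unrounded form sits within half an ulp of a rounding boundary can
legitimately land on either side.

Displayed values use `round_display()`, which rounds half away from zero
(0.005 → 0.01), matching the convention of the source tables; R's
bankers' rounding would disagree on exact halves. Rounding is confined
to display and table comparison — no internal computation ever rounds.

# The Gini coefficient on grouped data

Provinces are groups with population weights. The implementation sorts
groups ascending by per-capita resource level, accumulates population
shares `P_i` and resource shares `LR_i` (with `LR_0 = 0`), and computes
the area under the Lorenz curve by the trapezoid rule,

$$S = \tfrac12 \sum_i (LR_{i-1} + LR_i)\,P_i, \qquad G = 2\left(\tfrac12 - S\right).$$

Sorting ascending is what makes the curve convex; a descending sort
would produce a crossing curve, so the implementation always re-sorts
and never trusts input order. Ties in per-capita level are broken by
unit id, which fixes the curve's intermediate points deterministically;
the area, and hence `G`, is tie-order invariant.

Against elderly-population size, the Gini is computed with
`pop_weight = elderly_pop` and `resource = raw count`, so it measures
how resource shares deviate from elderly-population shares — the
resource-distribution reading, not an income Gini.

**Numerical checks.** The package exports an independent pairwise oracle,
$\sum_i \sum_j p_i p_j |y_i - y_j| / (2\bar y)$, an O(n²) brute-force
form kept free of any code shared with the trapezoid route. The test
suite verifies agreement to 1e-12 on 1000 random grouped instances
(2–12 groups, lognormal weights and levels, with per-capita ties and
zero-resource groups mixed in). Degenerate inputs are explicit errors:
zero total resource (no Lorenz curve exists), negative entries, and
zero-population groups are dropped before sorting since they carry no
population share and have no defined per-capita level.

**Classification.** Following the thresholds conventional for Chinese
national statistics, `G < 0.3` is labelled "preferred equality",
`0.3 ≤ G ≤ 0.4` "moderate", `0.4 < G ≤ 0.6` "inequality alert" and
`G > 0.6` "highly inequitable".

# The concentration index

Fractional ranks are `(position − 0.5)/n` after sorting by per-capita
disposable income, with tied incomes receiving the mean of their
positions' ranks; the unweighted mean rank is then exactly 1/2. The
index is

$$CI = \frac{2}{n\,\mu} \sum_i (LU_i - \mu)(R_i - \bar R),$$

twice the divide-by-*n* covariance between indicator and rank, over the
indicator mean. One reading of the conventional shorthand
$CI = \tfrac{2}{n\mu}\mathrm{cov}(LU, R)$ — taking "cov" as a sample
covariance that itself divides by *n* — would divide by *n* twice and
shrink the index towards zero as panels grow; the implementation uses
the sum-of-cross-products reading above, which reproduces the standard
rank-covariance concentration index and its [−1, 1] range for
non-negative indicators.

Each province counts as one unit (the 1/*n* form), and `μ` is the
unweighted mean across provinces. A population-weighted rank variant
(ranks at the midpoints of cumulative population-share intervals) is
available through `fractional_ranks(weights = )` for sensitivity
analysis, but it is not the default and is never used by the pipeline.
No Wagstaff or Erreygers normalization is applied: the index is the
plain rank-covariance form, so it is scale invariant but *not*
translation invariant, and that property is left intact.

Two exact identities anchor the implementation and are enforced in the
test suite: with equal weights, the CI of an indicator ranked by itself
equals the Gini of that indicator (to 1e-9 over random cases), and
reversing the income ordering negates the CI exactly.

# Bootstrap intervals

The source tables report 95% intervals without stating a method, so the
package makes its own choice and labels it: **bootstrap-percentile**,
resampling provinces with replacement, B = 1000 by default, seed
mandatory. Outputs record B and the seed so every interval is
reproducible. A resample on which the statistic is undefined — e.g. a
Gini resample that drew only zero-resource provinces — is redrawn and
counted; if more than half of all draws are degenerate the bootstrap
aborts, since the data are then too sparse for resampling to mean
anything. The percentile interval uses R's default quantile type 7. The
global RNG stream is saved and restored, so bootstrap calls do not
perturb surrounding code.

# The synthetic panel generator

The generator exists so that every pipeline stage can be tested against
known truth without the original yearbooks. Per (province, stratum) it
draws an elderly population, lognormal with `pop_log_mean = log(2000)`
thousand and `pop_log_sd = 0.7` — heterogeneous province sizes of the
right order for the Chinese panel — and a per-capita disposable income,
lognormal with median 25,000 currency units (`income_log_sd = 0.35`).
Per (province, year, stratum) it draws per-capita resource intensities,
lognormal with shape `resource_sigma` (default 0.5), **independently of
population**, and utilization per capita that is log-linear, with slope
`util_slope` (default 0.3) and residual log-noise `noise_sd = 0.3`, in a
latent propensity correlated `copula_rho = 0.8` with the income draw.
Base rates — 0.2 institutions, 20 beds, 2 workers and 1.5 disabled
residents per 1000 elderly, 2.5 services per resident — were set once to
match the magnitudes of the published national rates, so rounding counts
to integers (populations are in the thousands) perturbs rates only in
the fourth decimal.

Two design choices make recovery *testable*:

* population and intensity are independent, so the population-weighted
  grouped Gini of a generated resource converges to the closed-form
  lognormal Gini `2Φ(σ/√2) − 1` (≈ 0.276 at σ = 0.5, a value confirmed
  against a two-million-draw simulation, frozen as 0.2762 in the tests);
* regions are assigned round-robin, not by income or size, so the null
  generator carries no region effect. A `regional_gradient` switch adds
  a multiplicative East-heavy effect (Eastern ×1.4, Central and Western
  ×0.8) for demonstration panels that mimic the real East–Central–West
  pattern; it is off by default and off in every test.

What the generator does **not** emulate: serial correlation of resources
within a province across years (intensities are redrawn each year),
measurement error in the yearbook counts, urban–rural dependence within
a province, and any calibration to actual province values. Passing
recovery tests therefore shows the estimators are correct on data
satisfying the model's assumptions — independence of weights and levels,
lognormal intensities — not that the real panel satisfies them.

## Validation problem sizes

The suite recovers the analytic Gini with a 200-province, one-year,
one-stratum panel (tolerance ±0.03, which absorbs both sampling noise —
the single-slice estimator has a spread of roughly 0.016 at this size —
and integer-rounding bias); checks concentration-index sign recovery at
`util_slope = ±0.3` over 50 seeded 31-province runs per sign (≥48
required); and checks that B = 1000 bootstrap-percentile intervals cover
the analytic Gini in at least 90 of 100 replications at 200 provinces.
The acceptance script reports the recovery Gini as the mean over the 15
independent (year × indicator) slices of one generated panel, whose
spread across seeds is about three times smaller than a single slice's.

# The pipeline

`run_analysis()` chains ingestion (or synthesis) → aggregation →
inequality: population-weighted Ginis of the three resource counts on
the full panel, concentration indices of the two utilization indicators
on the exclusion-filtered panel, each (year, stratum) cell independently
— no smoothing or trend model across years. Bootstrap seeds for
individual statistics are derived deterministically from the run seed,
so identical configurations produce byte-identical output files (the
end-to-end determinism property in the test suite). Panels lacking
utilization columns yield resource results plus a warning, not an error.
Results tables carry full-precision values alongside a 3-dp display
column, the classification label, n, B and the seed, so every number in
a report is traceable.

# Known limitations

* The Gini here is the grouped (province-level) statistic; it is not an
  individual-level Gini and will understate inequality that exists
  within provinces.
* The concentration index uses province-level means; ecological
  inference caveats apply.
* The bootstrap treats provinces as exchangeable units; with only ~30
  provinces, percentile intervals can be noticeably narrow, and no
  small-sample correction (BCa, studentized) is offered.
* The missing-stratum proxy is a mean of counts; if populations trend
  strongly over the window, a rate-based proxy would differ, which is
  one reason imputation is opt-in and flagged.
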
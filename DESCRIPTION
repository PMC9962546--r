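Package: ltcineq
Title: Inequality Measurement for Long-Term-Care Resource Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for measuring inequality in the distribution and
    utilization of long-term-care (LTC) resources from province-level
    administrative panels. Derives per-1000-elderly resource indicators
    (institutions, beds, workers) and per-resident service indicators,
    aggregates them to regional and national rates, and quantifies
    inequality with population-weighted grouped Gini coefficients
    computed from Lorenz-curve trapezoid areas and with income-rank
    concentration indices, each with bootstrap-percentile confidence
    intervals and threshold-based classification. Includes a synthetic
    panel generator with analytically known inequality targets so the
    full pipeline can be validated without access to the underlying
    statistical yearbooks.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
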
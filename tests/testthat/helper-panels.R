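# Shared builders for small in-code fixtures.

# a minimal valid panel of real provinces (units: elderly_pop in thousands)
make_panel <- function(provinces = c("Beijing", "Anhui", "Sichuan"),
                       year = 2013, stratum = "urban",
                       elderly_pop = c(2000, 3000, 5000),
                       institutions = c(300, 240, 400),
                       beds = c(40000, 24000, 50000),
                       workers = c(5000, 3000, 6000),
                       ...) {
  ltc_panel(data.frame(province = provinces, year = year, stratum = stratum,
                       elderly_pop = elderly_pop, institutions = institutions,
                       beds = beds, workers = workers, ...))
}

# a panel covering all 31 default provinces in one (year, stratum) cell
make_full_panel <- function(year = 2013, stratum = "urban", seed = 11) {
  scheme <- region_scheme()
  provinces <- unname(attr(scheme, "display"))
  set.seed(seed)
  n <- length(provinces)
  ltc_panel(data.frame(
    province = provinces, year = year, stratum = stratum,
    elderly_pop = round(exp(rnorm(n, log(2000), 0.5))),
    institutions = rpois(n, 300), beds = rpois(n, 40000),
    workers = rpois(n, 4000), disabled_residents = rpois(n, 3000),
    rehab_nursing_services = rpois(n, 8000),
    income_pc = round(exp(rnorm(n, log(25000), 0.3)))))
}

# random grouped instances for property tests: positive weights, mixed
# per-capita levels, occasional ties and zero resources
random_grouped <- function(seed) {
  set.seed(seed)
  k <- sample(2:12, 1)
  pop <- exp(rnorm(k, 0, 1))
  y <- exp(rnorm(k, 0, 0.8))
  if (k > 3 && runif(1) < 0.3) y[2] <- y[1]       # per-capita tie
  if (k > 3 && runif(1) < 0.2) y[k] <- 0          # a zero-resource group
  list(pop = pop, resource = y * pop)
}
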
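# Shared fixtures, all generated in code.

# Surface with the same hazard in every cell.
const_surface <- function(mu, ages = 0:110, years = 1900:2015) {
  build_surface(scenario_spec(
    makeham_a = 0, makeham_b = 0, makeham_c = mu,
    improvement_rho = 0, ages = ages, years = years
  ), population = sprintf("const-%g", mu))
}

# Time-invariant Gompertz-Makeham surface (no improvement).
stationary_surface <- function(ages = 0:110, years = 1900:2015) {
  build_surface(scenario_spec(improvement_rho = 0, ages = ages,
                              years = years),
                population = "stationary")
}

# Compact improving scenario for fast tests.
small_improving_spec <- function(...) {
  scenario_spec(ages = 0:100, years = 1900:2010, ...)
}

# Gompertz closed forms, the analytic oracles: survival and (via quadrature)
# e0 and e-dagger for hazard a * exp(b x).
gompertz_lx <- function(x, a, b) exp((a / b) * (1 - exp(b * x)))

gompertz_e0_oracle <- function(a, b) {
  stats::integrate(function(x) gompertz_lx(x, a, b), 0, 250,
                   rel.tol = 1e-10)$value
}

gompertz_edagger_oracle <- function(a, b) {
  # -l ln l = l * (a/b)(e^{bx} - 1); guard the 0 * Inf tail
  stats::integrate(function(x) {
    v <- gompertz_lx(x, a, b) * (a / b) * (exp(b * x) - 1)
    ifelse(is.finite(v), v, 0)
  }, 0, 250, rel.tol = 1e-10)$value
}

# Hand-built cal_series-shaped tibble for decomposition unit tests.
fake_cal_series <- function(years, cal, cal_dagger, population = "P",
                            h_cal = cal_dagger / cal) {
  tibble::new_tibble(
    tibble::tibble(
      population = population, year = as.integer(years), cal = cal,
      cal_dagger = cal_dagger, h_cal = h_cal,
      n_cohorts = 111L
    ),
    class = "cal_series"
  )
}
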
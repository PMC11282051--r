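test_that("survival_from_hazard matches closed forms", {
  # constant hazard: lx(x) = exp(-mu x) exactly under the piecewise-
  # exponential construction
  curve <- survival_from_hazard(rep(0.2, 300), step = 1)
  expect_equal(curve$lx[curve$age == 5], exp(-1), tolerance = 1e-12)

  fine <- survival_from_hazard(rep(0.2, 300), step = 0.1)
  expect_equal(fine$lx[abs(fine$age - 5) < 1e-9], exp(-1), tolerance = 1e-12)

  # zero hazard, no closure: survival stays 1 on the supplied range
  flat <- survival_from_hazard(rep(0, 11), closeout = FALSE)
  expect_equal(flat$lx, rep(1, nrow(flat)))
  expect_equal(max(flat$age), 11)

  # smooth Gompertz law vs the analytic survival function
  a <- 1e-4; b <- 0.1
  gomp <- survival_from_hazard(function(x) a * exp(b * x), step = 0.1,
                               max_age = 120)
  lx80 <- gomp$lx[abs(gomp$age - 80) < 1e-9]
  expect_equal(lx80, gompertz_lx(80, a, b), tolerance = 1e-4)

  # single-year rates keep the life-table convention: cumulative hazard is
  # the sum of the annual rates, whatever the refinement
  coarse <- survival_from_hazard(a * exp(b * (0:120)), step = 0.1)
  expect_equal(coarse$lx[abs(coarse$age - 80) < 1e-9],
               exp(-sum(a * exp(b * (0:79)))), tolerance = 1e-12)

  expect_error(survival_from_hazard(c(0.1, -0.2)), "non-negative")
  expect_error(survival_from_hazard(numeric()), "empty")
  expect_error(survival_from_hazard(rep(0.1, 5), step = 0.3), "divide")
})

test_that("life expectancy and e-dagger agree with analytic oracles", {
  exp_curve <- survival_from_hazard(rep(0.2, 300), step = 0.1)
  expect_equal(life_expectancy(exp_curve), 5, tolerance = 1e-3)
  # for constant hazard e-dagger also equals 1/mu
  expect_equal(e_dagger(exp_curve), 5, tolerance = 1e-3)

  knife <- survival_curve(0:110, as.numeric(0:110 < 50))
  expect_equal(life_expectancy(knife), 50, tolerance = 1)
  expect_identical(e_dagger(knife), 0)

  a <- 1e-4; b <- 0.1
  gomp <- survival_from_hazard(function(x) a * exp(b * x), step = 0.05,
                               max_age = 150)
  expect_equal(life_expectancy(gomp), gompertz_e0_oracle(a, b),
               tolerance = 1e-3)
  expect_equal(e_dagger(gomp), gompertz_edagger_oracle(a, b),
               tolerance = 1e-3)
})

test_that("entropy hits its limits and flags excursions above 1", {
  for (mu in c(0.05, 0.2, 1)) {
    # trapezoid error in the entropy ratio scales with (step * mu)^2
    s <- 1 / ceiling(mu / 0.05)
    curve <- survival_from_hazard(rep(mu, ceiling(60 / mu)), step = s)
    expect_equal(lifetable_entropy(curve)$entropy, 1, tolerance = 1e-3)
  }
  knife <- survival_curve(0:110, as.numeric(0:110 < 50))
  expect_identical(lifetable_entropy(knife)$entropy, 0)

  a <- 1e-4; b <- 0.1
  gomp <- survival_from_hazard(function(x) a * exp(b * x), step = 0.05,
                               max_age = 150)
  expect_equal(lifetable_entropy(gomp)$entropy,
               gompertz_edagger_oracle(a, b) / gompertz_e0_oracle(a, b),
               tolerance = 1e-3)

  # catastrophic infant mortality pushes entropy above 1: flagged, intact
  extreme <- survival_from_hazard(c(2.3, rep(0.01, 400)))
  expect_warning(res <- lifetable_entropy(extreme), "exceeds 1")
  expect_gt(res$entropy, 1)

  expect_error(lifetable_entropy(survival_curve(0, 1)), "degenerate")
})

test_that("entropy is invariant under age-axis stretching", {
  a <- 1e-4; b <- 0.1
  gomp <- survival_from_hazard(a * exp(b * (0:150)), step = 0.25)
  base <- lifetable_entropy(gomp)
  for (k in c(0.5, 2, 7.3)) {
    stretched <- survival_curve(gomp$age * k, gomp$lx)
    res <- lifetable_entropy(stretched)
    expect_equal(res$e0, base$e0 * k, tolerance = 1e-6)
    expect_equal(res$edagger, base$edagger * k, tolerance = 1e-6)
    expect_equal(res$entropy, base$entropy, tolerance = 1e-6)
  }
})

test_that("grid refinement converges monotonically on smooth hazards", {
  a <- 1e-4; b <- 0.1
  haz <- a * exp(b * (0:150))
  vals <- sapply(c(1, 0.5, 0.25), function(s) {
    cv <- survival_from_hazard(haz, step = s)
    c(life_expectancy(cv), e_dagger(cv))
  })
  expect_lt(abs(vals[1, 3] - vals[1, 2]), abs(vals[1, 2] - vals[1, 1]))
  expect_lt(abs(vals[2, 3] - vals[2, 2]), abs(vals[2, 2] - vals[2, 1]))
})

test_that("period and cohort summaries behave on structured surfaces", {
  stat <- stationary_surface(ages = 0:100, years = 1900:2010)
  p <- period_entropy(stat, 1990)
  expect_equal(p$entropy, period_entropy(stat, 1950)$entropy,
               tolerance = 1e-12)
  co <- cohort_entropy(stat, 1905)
  expect_equal(co$e0, p$e0, tolerance = 1e-9)
  expect_equal(co$entropy, p$entropy, tolerance = 1e-9)

  # constant-hazard stationary surface: entropy 1
  cs <- const_surface(0.1, ages = 0:100, years = 2000:2001)
  expect_equal(period_entropy(cs, 2000, step = 0.1)$entropy, 1,
               tolerance = 1e-3)

  # a one-year shock depresses that year's life expectancy
  shocked <- build_surface(scenario_spec(
    ages = 0:100, years = 1950:2010,
    shocks = data.frame(year = 1990, multiplier = 3)
  ))
  expect_lt(period_entropy(shocked, 1990)$e0,
            period_entropy(shocked, 1989)$e0)

  # improving mortality: a cohort outlives the period table of its birth year
  improving <- build_surface(small_improving_spec())
  expect_gt(cohort_entropy(improving, 1905)$e0,
            period_entropy(improving, 1905)$e0)

  expect_error(cohort_entropy(improving, 1990), "not observable")
})
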
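test_that("benchmark_average takes unweighted means of entropy levels", {
  members <- list(
    fake_cal_series(2000:2002, cal = c(70, 70, 70), cal_dagger = c(7, 7, 7),
                    population = "a"),
    fake_cal_series(2000:2002, cal = c(75, 75, 75),
                    cal_dagger = c(15, 15, 15), population = "b"),
    fake_cal_series(2000:2002, cal = c(60, 60, 60),
                    cal_dagger = c(18, 18, 18), population = "c")
  )
  bench <- benchmark_average(members)
  # h values are 0.1, 0.2, 0.3 -> mean 0.2
  expect_equal(bench$h_cal, rep(0.2, 3), tolerance = 1e-12)
  expect_equal(bench$cal, rep(mean(c(70, 75, 60)), 3))
  expect_equal(bench$population, rep("benchmark", 3))

  # stacked-tibble input is equivalent
  bench2 <- benchmark_average(dplyr::bind_rows(members))
  expect_equal(bench2$h_cal, bench$h_cal)

  # identical members: benchmark equals any member
  bench3 <- benchmark_average(list(members[[1]], members[[1]]))
  expect_equal(bench3$cal, members[[1]]$cal)
  expect_equal(bench3$h_cal, members[[1]]$h_cal)

  expect_error(benchmark_average(members[1]), "at least two")
  shifted <- members
  shifted[[2]]$year <- shifted[[2]]$year + 1L
  expect_error(benchmark_average(shifted), "identical years")
})

test_that("entropy-of-mean-rates benchmark equals the member for identical surfaces", {
  surf <- const_surface(0.1, ages = 0:40, years = 1950:2000)
  bench <- benchmark_average(mode = "entropy-of-mean-rates",
                             surfaces = list(surf, surf), omega = 40)
  direct <- cal_series(surf, bench$year, omega = 40)
  expect_equal(bench$cal, direct$cal, tolerance = 1e-12)
  expect_equal(bench$h_cal, direct$h_cal, tolerance = 1e-12)
  expect_error(benchmark_average(mode = "entropy-of-mean-rates",
                                 surfaces = list(surf)), "at least two")
})

test_that("gap decomposition reproduces the equal-entropy worked pair", {
  # two populations with the same entropy 0.2: one from (10, 50), the
  # other from (15, 75); the gap is 0 but the components are not
  pop <- fake_cal_series(2000, cal = 50, cal_dagger = 10, population = "low-mean")
  bench <- fake_cal_series(2000, cal = 75, cal_dagger = 15)
  expect_equal(pop$h_cal, 0.2)
  expect_equal(bench$h_cal, 0.2)
  gd <- decompose_gap(pop, bench)
  expect_equal(gd$gap, 0)
  # H~ falls back to the arithmetic mean 0.2
  expect_equal(gd$contrib_variation, 0.2 * log(10 / 15), tolerance = 1e-12)
  expect_equal(gd$contrib_longevity, -0.2 * log(50 / 75), tolerance = 1e-12)
  expect_equal(gd$contrib_variation + gd$contrib_longevity, gd$gap,
               tolerance = 1e-14)

  # identical populations: everything 0
  gd0 <- decompose_gap(pop, pop)
  expect_equal(gd0$gap, 0)
  expect_equal(gd0$contrib_variation, 0)
  expect_equal(gd0$contrib_longevity, 0)

  # equal CAL: the whole gap is lifespan variation
  pop2 <- fake_cal_series(2000, cal = 70, cal_dagger = 9)
  bench2 <- fake_cal_series(2000, cal = 70, cal_dagger = 10.5)
  gd2 <- decompose_gap(pop2, bench2)
  expect_identical(gd2$contrib_longevity, 0)
  expect_equal(gd2$contrib_variation, gd2$gap, tolerance = 1e-14)

  bad <- fake_cal_series(2000, cal = -1, cal_dagger = 10)
  expect_error(decompose_gap(bad, bench), "positive")
})

test_that("gap contributions are exactly additive and antisymmetric", {
  surf_a <- build_surface(small_improving_spec(), population = "A")
  surf_b <- build_surface(small_improving_spec(makeham_b = 0.10),
                          population = "B")
  yrs <- 2003:2010
  sa <- cal_series(surf_a, yrs, omega = 100)
  sb <- cal_series(surf_b, yrs, omega = 100)
  gd <- decompose_gap(sb, sa)
  expect_equal(gd$contrib_variation + gd$contrib_longevity, gd$gap,
               tolerance = 1e-10)
  swapped <- decompose_gap(sa, sb)
  expect_equal(swapped$gap, -gd$gap, tolerance = 1e-12)
  expect_equal(swapped$contrib_variation, -gd$contrib_variation,
               tolerance = 1e-12)
  expect_equal(swapped$contrib_longevity, -gd$contrib_longevity,
               tolerance = 1e-12)
})

test_that("gap-change terms plus residual reproduce the observed change", {
  # stationary pair: nothing moves
  pop <- fake_cal_series(2000:2004, cal = rep(70, 5), cal_dagger = rep(9, 5))
  bench <- fake_cal_series(2000:2004, cal = rep(72, 5),
                           cal_dagger = rep(10, 5))
  gc0 <- decompose_gap_change(pop, bench)
  expect_equal(gc0$total_change, rep(0, 4))
  expect_equal(gc0$term_benchmark, rep(0, 4))
  expect_equal(gc0$term_variation, rep(0, 4))
  expect_equal(gc0$term_longevity, rep(0, 4))
  expect_equal(gc0$residual, rep(0, 4))

  # only the population's lifespan variation moves: the variation term
  # carries essentially all of the change
  pop2 <- fake_cal_series(2000:2004, cal = rep(70, 5),
                          cal_dagger = 9 + 0.15 * (0:4))
  gc2 <- decompose_gap_change(pop2, bench)
  tot <- abs(gc2$term_benchmark) + abs(gc2$term_variation) +
    abs(gc2$term_longevity)
  expect_true(all(abs(gc2$term_variation) / tot >= 0.95))
  expect_equal(gc2$term_benchmark + gc2$term_variation +
                 gc2$term_longevity + gc2$residual,
               gc2$total_change, tolerance = 1e-12)

  # benchmark entropy declining while the population keeps a fixed
  # relative structure: the change is carried by the benchmark term alone,
  # whose sign is the benchmark drift times the (constant) gap bracket
  scale <- exp(0.01 * (0:4))
  bench3 <- fake_cal_series(2000:2004, cal = 70 * scale,
                            cal_dagger = 10.5 * scale^0.8)
  pop3 <- fake_cal_series(2000:2004, cal = bench3$cal * 1.1,
                          cal_dagger = bench3$cal_dagger * 1.2)
  gc3 <- decompose_gap_change(pop3, bench3)
  # log-ratios are constant, so variation and longevity terms vanish
  expect_equal(gc3$term_variation, rep(0, 4), tolerance = 1e-12)
  expect_equal(gc3$term_longevity, rep(0, 4), tolerance = 1e-12)
  expect_equal(gc3$term_benchmark, gc3$total_change, tolerance = 1e-12)
  h_tilde <- calentropy:::log_mean(pop3$h_cal, bench3$h_cal)
  bracket <- log(pop3$h_cal / bench3$h_cal)
  # benchmark entropy falls, population sits above it: term is negative
  expect_true(all(diff(h_tilde) < 0))
  expect_true(all(bracket > 0))
  expect_true(all(gc3$term_benchmark < 0))

  expect_error(decompose_gap_change(pop, bench[c(1, 3, 5), ]),
               "consecutive")
})

test_that("the residual stays negligible as annual changes shrink", {
  # the midpoint product rule makes the scheme exactly additive, so the
  # residual is at rounding level for full, halved and quartered changes
  for (scale in c(1, 0.5, 0.25)) {
    pop <- fake_cal_series(2000:2009, cal = 70 * exp(-0.004 * scale * (0:9)),
                           cal_dagger = 9 * exp(-0.012 * scale * (0:9)))
    bench <- fake_cal_series(2000:2009, cal = rep(72, 10),
                             cal_dagger = rep(10, 10))
    gc_ <- decompose_gap_change(pop, bench)
    expect_equal(gc_$term_benchmark + gc_$term_variation +
                   gc_$term_longevity + gc_$residual,
                 gc_$total_change, tolerance = 1e-14)
    expect_lt(max(abs(gc_$residual)), 1e-12)
  }
})

test_that("divergence pairs are attributed to the constructed component", {
  dp <- divergence_pair(scenario_spec(years = 1880:2000, ages = 0:90),
                        omega = 90)
  yrs <- dp$check$year
  sa <- cal_series(dp$A, yrs, omega = 90)
  sb <- cal_series(dp$B, yrs, omega = 90)
  gd <- decompose_gap(sb, sa)
  # built to differ only in the CAL-dagger trajectory: the longevity
  # contribution is numerically absent at every year
  expect_true(all(abs(gd$contrib_longevity) < 0.01 * abs(gd$gap)))
})

test_that("component shares normalise, roll, and handle zero years", {
  gd <- tibble::tibble(
    year = 2000:2009, population = "p",
    gap = rep(-0.02, 10),
    contrib_variation = rep(-0.03, 10),
    contrib_longevity = rep(0.01, 10)
  )
  sh <- component_shares(gd, window = 1)
  expect_equal(sh$share[sh$component == "variation"], rep(0.75, 10))
  expect_equal(sh$share[sh$component == "longevity"], rep(0.25, 10))
  expect_equal(sh$share, sh$share_raw)

  # constant shares are unchanged by rolling
  sh5 <- component_shares(gd, window = 5)
  expect_equal(sh5$share, sh$share)

  # raw shares sum to 1 at each year
  tot <- tapply(sh$share_raw, sh$year, sum)
  expect_equal(as.numeric(tot), rep(1, 10))

  # an all-zero year is missing, and excluded from the rolling mean
  gd$contrib_variation[3] <- 0
  gd$contrib_longevity[3] <- 0
  shz <- component_shares(gd, window = 3)
  v <- shz[shz$component == "variation", ]
  expect_true(is.na(v$share_raw[3]))
  expect_equal(v$share[3], 0.75) # neighbours only

  expect_error(component_shares(gd, window = 4), "odd")
})

test_that("crossover years follow the sign-attachment rule", {
  g1 <- tibble::tibble(year = 2000:2002, gap = c(-0.01, -0.005, 0.002))
  expect_equal(detect_crossovers(g1), 2002L)

  g2 <- tibble::tibble(year = 2000:2004, gap = -c(1, 2, 3, 4, 5) / 100)
  expect_equal(detect_crossovers(g2), integer())

  # zero attaches to the following sign: flip reported at the zero year
  g3 <- tibble::tibble(year = 2000:2002, gap = c(-0.01, 0, 0.01))
  expect_equal(detect_crossovers(g3), 2001L)

  expect_error(detect_crossovers(g1[1, ]), "at least two")
})
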
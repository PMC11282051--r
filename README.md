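# calentropy

Lifespan inequality for the population actually alive at a point in time.

Most inequality-in-mortality work summarises either one calendar year (a
period life table) or one birth cohort. `calentropy` implements the
third, cross-sectional perspective: the **cross-sectional average length
of life**

    CAL(t) = ∫₀^ω ℓ_c(x, t − x) dx,

which integrates, over age x, the survival to age x of the *actual*
cohort born in year t − x — every cohort alive at time t, each carrying
its full mortality history. Applying the e† ("e-dagger", life expectancy
lost per death) construction to the same cross-sectional schedule gives
CAL†(t), and their ratio

    H_CAL(t) = CAL†(t) / CAL(t)

is the **CAL-entropy**: a relative lifespan-inequality measure for the
whole living population, analogous to the Keyfitz–Leser life table
entropy H = e†/e₀ (0 = all deaths at one age, 1 = equal death rates at
all ages and cohorts). Because CAL(t) is taken at the start of year t it
never reads year t's rates, which makes it markedly more robust to
one-year mortality shocks than period entropy.

Two exactly additive decompositions compare populations:

* **Gap decomposition** — the CAL-entropy gap between a population and a
  benchmark (by default the unweighted mean of several populations'
  entropy levels) splits into a lifespan-variation contribution
  `H̃·ln(CAL†_pop/CAL†_bench)` and a longevity contribution
  `−H̃·ln(CAL_pop/CAL_bench)`, with H̃ the logarithmic mean of the two
  entropies.
* **Differences-of-differences** — the year-on-year change of that gap
  splits into benchmark-level, variation and longevity terms (plus a
  reported residual that is zero to machine precision by the midpoint
  product rule).

The package is aimed at demographers and population-health researchers:
it reads HMD-style `Mx_1x1` rate files and a plain long CSV dialect,
and ships a Gompertz–Makeham Lexis-surface simulator (period
improvement, cohort effects, shocks, seeded noise) so every measure and
decomposition is testable with no external data. Trend utilities (OLS,
continuous two-segment piecewise fits with breakpoint search, intrinsic
log-rates of change), ggplot2 `autoplot()` methods, broom-style
`tidy()`/`glance()`, and a small CLI round it out.

## Worked example

A synthetic population with Gompertz–Makeham baseline (a = 1e-4,
b = 0.1, c = 5e-4) improving 1.2% a year over 1870–2018:

```r
library(calentropy)

spec <- scenario_spec(makeham_a = 1e-4, makeham_b = 0.1, makeham_c = 5e-4,
                      years = 1870:2018)
surf <- build_surface(spec, population = "synthetic")

cal_series(surf, 2014:2018)
#> # A tibble: 5 × 6
#>   population  year   cal cal_dagger h_cal n_cohorts
#>   <chr>      <int> <dbl>      <dbl> <dbl>     <int>
#> 1 synthetic   2014  79.4       10.3 0.129       111
#> 2 synthetic   2015  79.5       10.3 0.129       111
#> 3 synthetic   2016  79.7       10.3 0.129       111
#> 4 synthetic   2017  79.8       10.3 0.129       111
#> 5 synthetic   2018  79.9       10.3 0.128       111
```

Read: the cohorts alive in 2018 average 79.9 years of survival under
their lived-through rates (CAL), lose 10.3 years per death (CAL†), and
their relative inequality H_CAL = 0.128 — slightly above the period
entropy of 2018 alone (0.126), because the cross-section still carries
the worse mortality older cohorts lived through:

```r
period_entropy(surf, 2018)
#> # A tibble: 1 × 5
#>    year    e0 edagger entropy omega
#> 1  2018  81.3    10.2   0.126   128

fit_linear(cal_series(surf, 1990:2018), h_cal)
#> <trend_fit> linear over 1990-2018 (n = 29), R^2 = 0.9998
#>   slope: -0.000237258 per year

100 * intrinsic_rate(cal_entropy(surf, 1990)$h_cal,
                     cal_entropy(surf, 2018)$h_cal, 1990, 2018)
#> [1] -0.1801666   # percent per year
```

Inequality declines smoothly at about 0.18% a year. Comparing two
populations built to differ only in lifespan variation
(`divergence_pair()`), the gap decomposition attributes the whole gap to
the variation component:

```r
dp <- divergence_pair(scenario_spec(improvement_rho = 0,
                                    years = 1880:2000, ages = 0:90),
                      omega = 90)
sa <- cal_series(dp$A, 1996:2000, omega = 90)
sb <- cal_series(dp$B, 1996:2000, omega = 90)
decompose_gap(sb, sa)
#> # A tibble: 5 × 5
#>    year population      gap contrib_variation contrib_longevity
#> 1  1996 B          -0.00771          -0.00771          3.18e-16
#> 2  1997 B          -0.00807          -0.00807          3.17e-16
#> 3  1998 B          -0.00844          -0.00844          3.00e-16
#> 4  1999 B          -0.00880          -0.00880          2.67e-16
#> 5  2000 B          -0.00917          -0.00917          2.66e-16
```

`decompose_gap_change()`, `component_shares()` and
`detect_crossovers()` continue the analysis over time;
`autoplot()` draws each result type.

## Command line

A thin wrapper over the same functions lives at `inst/cli/calentropy.R`
(installed under `system.file("cli", "calentropy.R", package =
"calentropy")`):

```sh
Rscript calentropy.R simulate  --config scenario.dcf
Rscript calentropy.R compute   --config run.dcf
Rscript calentropy.R decompose --config run.dcf --window 5
Rscript calentropy.R trend     --config run.dcf
```

Configs are flat key–value (DCF) files; every flag can override a config
key. Exit codes: 0 success, 2 validation/coverage failure, 1 internal
error.

## Acceptance script

`scripts/acceptance.R` recomputes the analytic limiting values of the
measures from scratch with the installed package — the entropy of a
constant-hazard life table and of a knife-edge (single death age)
survival curve, and the CAL-entropy of constant-hazard and knife-edge
mortality surfaces — and writes them as JSON:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

## Scope

Kannisto-style old-age smoothing, truncated CAL for short series,
cause-deleted entropy and age/cohort decompositions of CAL† are out of
scope; rates are taken as prepared. The methods vignette
(`vignettes/cal-entropy-methods.Rmd`) documents every discretisation
choice, the synthetic world's assumptions, and known limitations.
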
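---
title: "Measuring lifespan inequality across the cohorts alive today: methods behind calentropy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring lifespan inequality across the cohorts alive today: methods behind calentropy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(calentropy)
```

## The measures

Demographers summarise a survival function $\ell(x)$ (radix 1) by its mean,
the life expectancy $e_0 = \int_0^\omega \ell(x)\,dx$, and by the average
life expectancy lost per death,
$e^\dagger = -\int_0^\omega \ell(x)\ln \ell(x)\,dx$, an absolute measure of
lifespan variation. Their ratio, the Keyfitz–Leser life table entropy
$\mathcal{H} = e^\dagger / e_0$, is a *relative* measure of lifespan
inequality: it is 0 when every death occurs at one age (a perfectly
rectangular survival curve) and 1 when death rates are equal at all ages
(exponential survival). Under extreme infant mortality it can exceed 1;
`lifetable_entropy()` flags such values with a warning and never clamps
them. Both integrals are evaluated with the trapezoidal rule on the curve's
age grid, with the analytic-limit convention $0\ln 0 = 1\ln 1 = 0$.

A period entropy describes the synthetic cohort of one calendar year; a
cohort entropy follows one birth cohort to extinction. The cross-sectional
average length of life (CAL) takes a third perspective: at time $t$ it
integrates, over age $x$, the survival to age $x$ of the *actual* cohort
born in $t-x$,

$$\mathrm{CAL}(t) = \int_0^{\omega} \ell_c(x, t-x)\,dx,$$

so it carries the full mortality history of every cohort alive at $t$.
Applying the $e^\dagger$ construction to the same cross-sectional survival
schedule gives $\mathrm{CAL}^\dagger(t)$, and their ratio
$\mathcal{H}_{\mathrm{CAL}}(t) = \mathrm{CAL}^\dagger(t)/\mathrm{CAL}(t)$
— the CAL-entropy — is the package's headline measure: a relative lifespan
inequality index for the whole living population rather than for one
synthetic year or one birth cohort. Like $\mathcal H$ it is 1 when rates
are equal across all ages *and cohorts*, and 0 when all deaths are
concentrated at a single age.

## Discretisation choices

**Survival construction.** Hazards arrive as single-year age-specific
rates $m(x, t)$ on a Lexis grid (age $x$ labels $[x, x+1)$, year $t$
labels $[t, t+1)$; a cohort born in $c$ experiences $m(a, c+a)$ at age
$a$). Within each one-year interval the hazard is held constant, so
$\ell(x+s) = \ell(x)e^{-m(x)s}$ — one convention applied uniformly instead
of the $a_x = 1/2$ separation-factor convention; on smooth schedules the
difference is far below every tolerance used here. Grids may be refined
below one year (`step`); smooth hazard *laws* supplied as functions are
sampled at sub-interval midpoints, which converges quadratically.

**Terminal closure.** The open age interval is closed by extending the
last observed hazard until survival falls below $10^{-12}$, capped 150
years past the last age; any mass dropped at the cap is recorded in a
`truncated_mass` attribute. The top age $\omega$ of real single-year data
(110 for HMD-style files) is therefore treated as the start of a terminal
exponential tail, never extrapolated by a mortality model — old-age
smoothing is the data preparer's job, not this package's.

**The cross-section is taken at the start of year $t$.** CAL$(t)$ uses the
cohort aged exactly $x$ at the start of year $t$, whose survival to age
$x$ involves calendar years $t-x$ through $t-1$ only. The year-$t$ rates
never enter CAL$(t)$ — they first touch CAL$(t+1)$, weighted by a single
year of exposure per cohort. This is precisely why the measure barely
moves across a one-year mortality shock that sends the period entropy
jumping, a robustness property the tests assert quantitatively (a ×3
one-year shock moves period entropy by an order of magnitude more than
CAL-entropy).

**Within-interval continuation.** On $[k, k+1)$ the cross-sectional
integrand follows the cohort aged $k$, continued piecewise-exponentially
at its most recent observed hazard $m(k, t-1)$. Where adjacent cohorts
meet at integer ages the two one-sided values are both recorded (repeated
ages on the grid), so the trapezoidal rule integrates each cohort's
segment exactly rather than averaging across the jump between cohorts.
Two consequences matter:

* on a time-invariant surface the construction collapses *identically* to
  the period life table on the same grid — the central consistency oracle
  (`cal_entropy` equals `period_entropy` to machine precision there);
* the analytic limit $\mathcal H_{\mathrm{CAL}} = 1$ for an age- and
  cohort-constant hazard is met to $10^{-3}$ on a 0.1-year grid, which a
  unit-age trapezoid cannot do (its ratio bias is
  $\approx (h\mu)^2/6 \approx 7\times 10^{-3}$ at $\mu = 0.2$, $h = 1$).

The cross-sectional schedule is *not* the survival curve of any single
cohort and is not guaranteed monotone across ages; monotonicity is
enforced per cohort only, and the assembled curve is validated just for
$v(0) = 1$, $0 \le v \le 1$.

## The two decompositions

Populations are compared to a benchmark — by default the unweighted
arithmetic mean of the member populations' CAL-entropy, CAL and
CAL$^\dagger$ levels (each population weighted equally); a sensitivity
mode averages the mortality surfaces cell-wise first and measures the
averaged surface instead.

**Gap decomposition.** The cross-population derivative of
$\mathcal H_{\mathrm{CAL}}$ splits into a lifespan-variation part (the
relative difference in CAL$^\dagger$) minus a longevity part (the relative
difference in CAL). Discretely, relative derivatives become log-ratios.
Using the logarithmic-mean entropy level
$\tilde{\mathcal H} = (\mathcal H_{pop} - \mathcal H_{bench}) /
\ln(\mathcal H_{pop}/\mathcal H_{bench})$ (arithmetic mean in the
zero-gap limit) makes the split *exactly* additive:

$$\mathcal H_{pop} - \mathcal H_{bench}
  = \underbrace{\tilde{\mathcal H}\,
      \ln\frac{\mathrm{CAL}^\dagger_{pop}}{\mathrm{CAL}^\dagger_{bench}}}_{\text{variation}}
  \;\underbrace{-\;\tilde{\mathcal H}\,
      \ln\frac{\mathrm{CAL}_{pop}}{\mathrm{CAL}_{bench}}}_{\text{longevity}},$$

because $\ln \mathcal H = \ln \mathrm{CAL}^\dagger - \ln \mathrm{CAL}$.
A mean-of-entropy benchmark violates that identity by a small Jensen gap
($\bar{\mathcal H} \ne \overline{\mathrm{CAL}^\dagger}/\overline{\mathrm{CAL}}$);
the decomposition restores it by using the *effective* benchmark variation
level $\mathcal H_{bench}\cdot \mathrm{CAL}_{bench}$ inside the
log-ratio, which allocates the (entropy-level) inconsistency to the
variation term. The equal-entropy textbook pair — one population at
$10/50$, another at $15/75$, both with entropy $0.2$ — exercises the
zero-gap limit: the gap is zero while variation contributes
$0.2\ln(10/15) \approx -0.081$ and longevity exactly cancels it.

**Differences-of-differences.** Writing the gap as
$\tilde{\mathcal H}(t)\,[R^\dagger(t) - R(t)]$ with the log-ratio brackets
$R^\dagger$, $R$, its year-on-year change splits into a benchmark term
$\Delta\tilde{\mathcal H}\cdot[\bar R^\dagger - \bar R]$ (changes in the
average entropy level), a variation term
$\bar{\tilde{\mathcal H}}\,\Delta R^\dagger$ and a longevity term
$-\bar{\tilde{\mathcal H}}\,\Delta R$, using first differences for the
differenced factors and two-year midpoint averages for the rest. The
midpoint product rule $\Delta(AB) = \Delta A\,\bar B + \bar A\,\Delta B$
is an algebraic identity, so the three terms sum to the observed change to
machine precision; the residual is still computed and reported (never
folded into a term) so that any future change of scheme stays honest.
Component *shares* divide each term's absolute value by the total absolute
contribution, then apply a centred rolling mean (default width 5 years,
shrinking at the series edges — the width is a package choice; any odd
width can be set). Years where every component is zero have undefined
shares and are excluded from the rolling mean rather than invented.

## The synthetic world

`build_surface()` evaluates
$m(x,t) = (a e^{bx} + c)\, e^{-\rho(t - t_0)}\,
\mathrm{cohort}(t-x)\,\mathrm{shock}(t)\,\mathrm{noise}(x,t)$:
a Gompertz–Makeham baseline (level $a$, slope $b$, background $c$),
proportional period improvement $\rho$, an optional multiplicative
birth-cohort factor, one-year period shocks (the 1918-flu/wartime spike
pattern), and optional mean-one lognormal rate noise (chosen lognormal for
positivity; observed-rate noise has no canonical model, so any choice here
is the package's own). The reference parameterisation —
$a = 3\times10^{-5}$, $b = 0.095$, $c = 2\times10^{-4}$, $\rho = 0.012$,
ages 0–110, years 1870–2020, seed 20240725, no noise — describes a
low-mortality population improving at 1.2% a year for 151 years, long
enough that full 110-age cross-sections exist for the final four decades.
Builds are bit-reproducible from the spec (the seed is applied locally;
the global RNG stream is untouched).

What the generator emulates: realistic age profiles, steady improvement,
cohort bands, period shocks. What it does not: Lexis-triangle death
counts, population weights, migration, data errors, or old-age rate
smoothing — so a green test establishes the *mathematics* of the measures
on known structure, not their behaviour under real-data artefacts. One
stylised-world caveat found while testing: with the light default baseline
and strong improvement, life expectancy approaches the 110 top age and the
closure tail starts to dominate the entropy trend; trend-recovery checks
therefore use a heavier baseline that keeps $e_0$ well below the cap.

**Attribution fixtures.** `divergence_pair()` builds two populations that
differ, by construction, in only one component: B's hazards are tilted
around a pivot age with a linearly growing tilt
$\exp(\varepsilon(t)(x - \mathrm{pivot})/100)$ while a per-year level
factor is solved by one-dimensional root finding so that the *other*
component (CAL for a variation-only pair, CAL$^\dagger$ for a
longevity-only pair) matches population A along the whole series. Because
a year's column first affects cross-sections one year later, the factors
can be solved sequentially, driving the preserved component's discrepancy
to root-finder precision (~$10^{-10}$ years, far inside the 0.05-year
construction tolerance that is verified internally and raises an error if
missed). The attribution-recovery test runs this experiment on a
*stationary* base ($\rho = 0$): with background improvement switched off,
the benchmark-entropy drift term is silenced and the constructed component
carries $\ge 95\%$ of every year's gap change. On an improving base the
drift term genuinely carries a share of the change (about 9% in aggregate
with the defaults) — that is a property of the measure, not an artefact,
and the per-year *gap* decomposition still assigns essentially 100% to the
constructed component there.

## Trend summaries

`fit_linear()` is ordinary least squares of a measure on calendar year.
`fit_piecewise()` fits a *continuous* two-segment line (hinge
parameterisation — continuity is a package choice, motivated by reporting
a single turning point), selecting the breakpoint by exhaustive search
over observed interior years with at least three points per segment,
minimising total SSE with ties broken toward the earliest year; it nests
the linear model, so never fits worse. `intrinsic_rate()` is the
annualised log-ratio $\ln(v_2/v_1)/(t_2-t_1)$ — exact for exponential
trajectories, invariant to positive rescaling, and equal to percent per
year when multiplied by 100.

## Numerical and degenerate-input policy

* Missing data fail loudly everywhere (readers, validators, coverage
  checks): a silently imputed cell would contaminate every later
  cross-section.
* "Numerically infinite" knife-edge hazards use $10^4$ per year, under
  which one-year survival underflows to exactly 0, so the entropy and
  CAL$^\dagger$ minima are *exact* zeros under the $0\ln 0$ convention.
* Zero-gap decompositions use the arithmetic-mean fallback for
  $\tilde{\mathcal H}$ (trigger: $|\Delta\ln \mathcal H| < 10^{-12}$).
* Crossover detection attaches zero gaps to the following sign, so a
  $-,0,+$ sequence reports one crossover at the zero year.
* All acceptance-level analytic checks use a 0.1-year grid; the
  trapezoid's entropy-ratio bias scales as $(h\mu)^2$ and is $\sim 7
  \times 10^{-5}$ there.

## Limitations

Exact numeric agreement with published country results is not claimed:
those rest on external data and on an unpublished discretisation, while
the schemes here are chosen for exact additivity and documented
convergence. Truncated variants of CAL for short series, cause-deleted
entropy, and age/cohort decompositions of CAL$^\dagger$ are out of scope.

## A worked example

```{r example, eval = FALSE}
spec_a <- scenario_spec()                       # reference population
spec_b <- scenario_spec(makeham_b = 0.099)      # steeper old-age slope
a <- build_surface(spec_a, population = "A")
b <- build_surface(spec_b, population = "B")

years <- 1990:2018
sa <- cal_series(a, years)
sb <- cal_series(b, years)
bench <- benchmark_average(list(sa, sb))

gap <- decompose_gap(sb, bench)
change <- decompose_gap_change(sb, bench)
component_shares(gap, window = 5)
autoplot(gap)
```
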
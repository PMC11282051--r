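#' Cross-sectional survival over the cohorts alive at one time
#'
#' Assembles the integrand of the cross-sectional average length of life
#' (CAL) at year \eqn{t}: for each age \eqn{x = 0..\omega}, the survival to
#' age \eqn{x} of the cohort born in year \eqn{t - x}, computed independently
#' from that cohort's own diagonal hazards \eqn{m(a, t - x + a)}. The result
#' is not the survival function of any single cohort and need not be
#' monotone across ages; monotonicity holds only within each cohort.
#'
#' The cross-section is taken at the start of year \eqn{t}: survival to
#' exact age \eqn{x} uses the cohort's lived-through years \eqn{t-x ..
#' t-1}, so the year-\eqn{t} rates themselves never enter — which is what
#' makes the measure robust to a shock in the cross-section year. On the
#' age interval \eqn{[k, k+1)} the curve follows the cohort aged exactly
#' \eqn{k} at the start of year \eqn{t}, continued piecewise exponentially
#' at its most recent observed hazard \eqn{m(k, t-1)} (sub-year resolution
#' via `step`). Where adjacent cohorts meet at integer ages the
#' two one-sided values are both recorded (repeated age), so trapezoidal
#' integration of the returned curve integrates each cohort segment exactly;
#' for a time-invariant surface the construction collapses to the period
#' survival curve of year \eqn{t} on the identical grid. Beyond age
#' \eqn{\omega + 1} the oldest cohort is closed out by the terminal-hazard
#' rule shared with [survival_from_hazard()].
#'
#' @inheritParams period_column
#' @param omega Top age of the cross-section (default 110, the conventional
#'   top single age of HMD-style data). Every cohort born `year - omega`
#'   through `year` must lie fully on the surface ([cal_coverage()]).
#' @param step Sub-year grid refinement (must divide one year evenly).
#' @param closeout Close out the oldest cohort beyond `omega + 1`?
#' @return A [survival_curve()] of kind `"cal-diagonal"` with attributes
#'   `n_cohorts` and `step`.
#' @export
cal_survival <- function(surface, year, omega = 110, step = 1,
                         closeout = TRUE) {
  check_surface(surface)
  cov <- cal_coverage(surface, year, omega)
  if (!isTRUE(attr(cov, "complete"))) {
    abort(paste0(
      sprintf("CAL(%s, omega=%d) not computable: %d cohort(s) not covered: ",
              format(year), omega, nrow(cov)),
      paste(head(cov$cohort, 8L), collapse = ", "),
      if (nrow(cov) > 8L) sprintf(" and %d more", nrow(cov) - 8L) else ""
    ))
  }
  n_sub <- 1 / step
  if (!isTRUE(all.equal(n_sub, round(n_sub))) || step <= 0 || step > 1) {
    abort("`step` must evenly divide one year (e.g. 1, 0.5, 0.25, 0.1).")
  }
  n_sub <- round(n_sub)
  m <- surface_matrix(surface)
  years <- surface_years(surface)
  ycol <- as.integer(year) - years[1L] + 1L
  part <- cal_curve_from_matrix(m, ycol, omega, step, closeout)
  out <- survival_curve(part$age, part$lx, kind = "cal-diagonal",
                        label = as.character(year))
  attr(out, "step") <- step
  attr(out, "n_cohorts") <- as.integer(omega) + 1L
  attr(out, "truncated_mass") <- part$truncated_mass
  out
}

# Core of the cross-sectional construction on the bare ages x years matrix;
# `ycol` is the column index of the cross-section year. Returns the age/lx
# arrays (with repeated integer ages at cohort joins) without validation.
# The cross-section is taken at the START of year `ycol`: survival to exact
# age k uses calendar years ycol-k .. ycol-1 only, and the within-interval
# continuation uses each cohort's most recent lived-through year (ycol - 1),
# so the cross-section never reads the year-ycol column itself.
cal_curve_from_matrix <- function(m, ycol, omega, step, closeout = TRUE) {
  n_sub <- round(1 / step)
  # survival to exact age k of the cohort born in year - k
  base <- numeric(omega + 1L)
  base[1L] <- 1
  for (k in seq_len(omega)) {
    a <- 0:(k - 1L)
    base[k + 1L] <- exp(-sum(m[cbind(a + 1L, ycol - k + a)]))
  }
  haz_t <- m[1:(omega + 1L), max(ycol - 1L, 1L)]
  s <- step * (0:n_sub)
  within <- exp(-outer(s, haz_t)) # (n_sub+1) x (omega+1)
  age <- rep(0:omega, each = n_sub + 1L) + rep(s, omega + 1L)
  lx <- as.vector(within) * rep(base, each = n_sub + 1L)
  truncated <- 0
  if (closeout) {
    tail_part <- close_out_tail(omega + 1, lx[length(lx)], haz_t[omega + 1L],
                                step)
    age <- c(age, tail_part$age)
    lx <- c(lx, tail_part$lx)
    truncated <- tail_part$truncated_mass
  }
  list(age = age, lx = pmin(lx, 1), truncated_mass = truncated)
}

# Fast (CAL, CAL-dagger) pair on a bare matrix; used by the synthetic
# divergence construction where thousands of evaluations are needed.
cal_values_from_matrix <- function(m, ycol, omega, step = 1) {
  part <- cal_curve_from_matrix(m, ycol, omega, step)
  c(cal = trapz(part$age, part$lx),
    cal_dagger = trapz(part$age, xlogx_term(part$lx)))
}

#' Cross-sectional average length of life and its entropy
#'
#' `cal()` is the cross-sectional average length of life
#' \eqn{\mathrm{CAL}(t) = \int_0^\omega \ell_c(x, t-x)\,dx}: the integral
#' over age of the survival of every cohort alive at time \eqn{t}, a
#' longevity measure that carries each cohort's full mortality history.
#' `cal_dagger()` is its lifespan-variation analogue
#' \eqn{-\int \ell_c \ln \ell_c\,dx} (the cross-sectional average inequality
#' in lifespan), and `cal_entropy()` assembles the relative inequality
#' measure \eqn{H_{\mathrm{CAL}}(t) = \mathrm{CAL}^\dagger(t) /
#' \mathrm{CAL}(t)}, which is 1 when mortality rates are equal across all
#' ages and cohorts and 0 when all deaths are concentrated at a single age.
#' All integrals are trapezoidal on the curve from [cal_survival()].
#'
#' @inheritParams cal_survival
#' @return `cal()` and `cal_dagger()` return years (single numbers).
#'   `cal_entropy()` returns a one-row tibble with columns `population`,
#'   `year`, `cal`, `cal_dagger`, `h_cal` and `n_cohorts`.
#' @export
cal <- function(surface, year, omega = 110, step = 1) {
  life_expectancy(cal_survival(surface, year, omega, step))
}

#' @rdname cal
#' @export
cal_dagger <- function(surface, year, omega = 110, step = 1) {
  e_dagger(cal_survival(surface, year, omega, step))
}

#' @rdname cal
#' @export
cal_entropy <- function(surface, year, omega = 110, step = 1) {
  curve <- cal_survival(surface, year, omega, step)
  cal_v <- life_expectancy(curve)
  if (cal_v <= 0) {
    abort("degenerate cross-section: CAL is 0.")
  }
  dag <- e_dagger(curve)
  h <- dag / cal_v
  if (h > 1 + 1e-9) {
    warn(sprintf("CAL-entropy %.6f exceeds 1; flagged, not clamped.", h))
  }
  new_tibble(
    list(
      population = attr(surface, "population") %||% "unnamed",
      year = as.integer(year), cal = cal_v, cal_dagger = dag, h_cal = h,
      n_cohorts = as.integer(attr(curve, "n_cohorts"))
    ),
    class = "cal_series"
  )
}

#' Time series of cross-sectional entropy results
#'
#' Computes `cal_entropy()` for a range of years. Coverage is checked for
#' every requested year up front: by default the first uncovered year is an
#' error (no silent partial output); with `partial = TRUE` uncovered years
#' are dropped with a warning instead.
#'
#' @inheritParams cal_survival
#' @param years Integer vector of calendar years (may be empty).
#' @param partial Drop uncovered years instead of failing?
#' @return A tibble of class `cal_series`, one row per year in year order,
#'   with columns `population`, `year`, `cal`, `cal_dagger`, `h_cal`,
#'   `n_cohorts`.
#' @examples
#' surf <- build_surface(scenario_spec(years = 1900:1960, ages = 0:50))
#' cal_series(surf, 1955:1958, omega = 50)
#' @export
cal_series <- function(surface, years, omega = 110, step = 1,
                       partial = FALSE) {
  check_surface(surface)
  years <- as.integer(years)
  if (length(years) > 0L) {
    covered <- vapply(years, function(y) cal_covered(surface, y, omega),
                      logical(1))
    if (!all(covered)) {
      if (partial) {
        warn(sprintf("dropping %d uncovered year(s): %s",
                     sum(!covered),
                     paste(head(years[!covered], 8L), collapse = ", ")))
        years <- years[covered]
      } else {
        abort(sprintf(
          "year %d lacks cohort coverage for omega = %d (first failure); use partial = TRUE to drop uncovered years.",
          years[which(!covered)[1L]], omega
        ))
      }
    }
  }
  rows <- purrr::map(sort(years), function(y) {
    cal_entropy(surface, y, omega = omega, step = step)
  })
  out <- if (length(rows) == 0L) {
    tibble(
      population = character(), year = integer(), cal = numeric(),
      cal_dagger = numeric(), h_cal = numeric(), n_cohorts = integer()
    )
  } else {
    bind_rows(rows)
  }
  new_tibble(out, class = "cal_series")
}
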
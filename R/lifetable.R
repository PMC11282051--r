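#' Survival curves
#'
#' A survival curve is a tabulated survival function \eqn{\ell(x)} on an age
#' grid starting at 0 with radix 1: `survival_curve()` validates and stamps a
#' tibble with columns `age` and `lx`. Three kinds are distinguished:
#' `"period"` and `"cohort"` curves are genuine life-table survival functions
#' (strictly increasing ages, non-increasing `lx`), while `"cal-diagonal"`
#' curves — assembled age-by-age from distinct cohorts for the
#' cross-sectional average length of life — are only required to satisfy
#' \eqn{\ell(0) = 1} and \eqn{0 \le \ell \le 1}, and may contain repeated
#' ages marking left/right limits where adjacent cohorts meet.
#'
#' @param age Age grid (years), starting at 0.
#' @param lx Survival probabilities, radix 1.
#' @param kind One of `"period"`, `"cohort"`, `"cal-diagonal"`.
#' @param label Provenance text (a calendar year or birth cohort).
#' @return A tibble of class `survival_curve`.
#' @examples
#' # knife-edge survival: everyone dies at exact age 50
#' knife <- survival_curve(0:110, as.numeric(0:110 < 50))
#' life_expectancy(knife)
#' @export
survival_curve <- function(age, lx, kind = c("period", "cohort",
                                             "cal-diagonal"),
                           label = NA_character_) {
  kind <- match.arg(kind)
  if (length(age) != length(lx) || length(age) < 1L) {
    abort("`age` and `lx` must be non-empty vectors of equal length.")
  }
  if (age[1L] != 0) {
    abort("the age grid must start at 0.")
  }
  if (anyNA(age) || anyNA(lx)) {
    abort("`age` and `lx` must not contain missing values.")
  }
  if (any(lx < 0 | lx > 1)) {
    abort("`lx` must lie in [0, 1].")
  }
  if (abs(lx[1L] - 1) > 1e-12) {
    abort("`lx[1]` must be 1 (radix 1).")
  }
  d <- diff(age)
  if (kind == "cal-diagonal") {
    if (any(d < 0)) abort("the age grid must be non-decreasing.")
  } else {
    if (any(d <= 0)) abort("the age grid must be strictly increasing.")
    if (any(diff(lx) > 1e-12)) {
      abort("`lx` must be non-increasing for period/cohort curves.")
    }
  }
  structure(
    tibble(age = as.numeric(age), lx = as.numeric(lx)),
    kind = kind, label = label,
    class = c("survival_curve", class(tibble()))
  )
}

#' @export
print.survival_curve <- function(x, ...) {
  cat(sprintf(
    "<survival_curve> kind=%s%s, ages 0-%s (%d points)\n",
    attr(x, "kind"),
    if (!is.na(attr(x, "label"))) paste0(" [", attr(x, "label"), "]") else "",
    format(max(x$age)), nrow(x)
  ))
  NextMethod()
}

check_curve <- function(curve) {
  if (!inherits(curve, "survival_curve")) {
    abort("expected a survival_curve (see survival_curve() or survival_from_hazard()).")
  }
  invisible(curve)
}

# Shared closure rule: extend a terminal hazard until survival falls below
# `lx_tol`, capped at `hard_cap` years beyond the starting age; any survival
# mass beyond the cap is dropped and recorded.
close_out_tail <- function(age_end, lx_end, m_last, step,
                           lx_tol = 1e-12, hard_cap = 150) {
  if (lx_end <= lx_tol || m_last <= 0) {
    return(list(age = numeric(), lx = numeric(),
                truncated_mass = if (m_last <= 0 && lx_end > lx_tol)
                  NA_real_ else 0))
  }
  years_needed <- log(lx_end / lx_tol) / m_last
  n_sub <- ceiling(min(years_needed, hard_cap) / step)
  extra_age <- age_end + step * seq_len(n_sub)
  extra_lx <- lx_end * exp(-m_last * step * seq_len(n_sub))
  final_lx <- extra_lx[n_sub]
  list(
    age = extra_age, lx = extra_lx,
    truncated_mass = if (final_lx > lx_tol) final_lx / m_last else 0
  )
}

#' Build a survival curve from single-year hazards
#'
#' Constructs \eqn{\ell(x)} from age-specific hazards `mx` for ages
#' `0..length(mx)-1`, assuming a piecewise-constant hazard within each
#' one-year age interval: \eqn{\ell(x+s) = \ell(x) e^{-m(x) s}} for
#' \eqn{0 \le s \le 1}. The grid may be refined below one year via `step`.
#' Beyond the last supplied age the curve is closed by extending the terminal
#' hazard until survival drops below `1e-12`, capped 150 years past the last
#' age (any remaining mass is dropped and recorded in the `truncated_mass`
#' attribute). With a zero terminal hazard no closure is possible and the
#' curve ends at the supplied range.
#'
#' @param mx Non-negative hazards for ages `0, 1, ...` (deaths per
#'   person-year), a data frame with columns `age` (consecutive from 0) and
#'   `mx`, or a hazard function of continuous age. Vector and data-frame
#'   input is held piecewise constant within each one-year interval (the
#'   life-table convention for single-year rates); a function is sampled at
#'   the midpoints of the refined sub-intervals, giving a midpoint-rule
#'   cumulative hazard that converges quadratically for smooth laws.
#' @param step Grid refinement; must divide one year evenly (e.g. 1, 0.5,
#'   0.1).
#' @param closeout Extend the terminal hazard beyond the supplied ages?
#' @param kind,label Passed to [survival_curve()].
#' @param max_age Top age of the construction; required (and only used)
#'   when `mx` is a function.
#' @return A [survival_curve()] of the given kind.
#' @examples
#' exp_curve <- survival_from_hazard(rep(0.2, 300), step = 0.1)
#' life_expectancy(exp_curve) # 1 / 0.2, up to quadrature error
#' @export
survival_from_hazard <- function(mx, step = 1, closeout = TRUE,
                                 kind = "period", label = NA_character_,
                                 max_age = NULL) {
  n_sub <- 1 / step
  if (!isTRUE(all.equal(n_sub, round(n_sub))) || step <= 0 || step > 1) {
    abort("`step` must evenly divide one year (e.g. 1, 0.5, 0.25, 0.1).")
  }
  n_sub <- round(n_sub)
  if (is.function(mx)) {
    if (is.null(max_age) || !is_int_scalar(max_age) || max_age < 1) {
      abort("function-valued `mx` needs an integer `max_age` >= 1.")
    }
    mids <- step * (seq_len(max_age * n_sub) - 0.5)
    haz_sub <- mx(mids)
    if (anyNA(haz_sub) || any(haz_sub < 0)) {
      abort("hazards must be non-negative and non-missing.")
    }
    age <- c(0, step * seq_along(haz_sub))
    lx <- c(1, exp(-cumsum(haz_sub * step)))
    truncated <- 0
    if (closeout) {
      tail_part <- close_out_tail(age[length(age)], lx[length(lx)],
                                  haz_sub[length(haz_sub)], step)
      age <- c(age, tail_part$age)
      lx <- c(lx, tail_part$lx)
      truncated <- tail_part$truncated_mass
    }
    out <- survival_curve(age, pmin(lx, 1), kind = kind, label = label)
    attr(out, "step") <- step
    attr(out, "truncated_mass") <- truncated
    return(out)
  }
  if (is.data.frame(mx)) {
    if (!all(c("age", "mx") %in% names(mx))) {
      abort("data-frame input must have columns `age` and `mx`.")
    }
    mx <- arrange(mx, .data$age)
    if (!identical(as.integer(mx$age), seq(0L, nrow(mx) - 1L))) {
      abort("`age` must be consecutive single years starting at 0.")
    }
    mx <- mx$mx
  }
  if (length(mx) == 0L) {
    abort("`mx` must not be empty.")
  }
  if (anyNA(mx) || any(mx < 0)) {
    abort("hazards must be non-negative and non-missing.")
  }
  n_age <- length(mx)
  haz_sub <- rep(mx, each = n_sub)
  age <- c(0, step * seq_along(haz_sub))
  lx <- c(1, exp(-cumsum(haz_sub * step)))
  truncated <- 0
  if (closeout) {
    tail_part <- close_out_tail(age[length(age)], lx[length(lx)],
                                mx[n_age], step)
    age <- c(age, tail_part$age)
    lx <- c(lx, tail_part$lx)
    truncated <- tail_part$truncated_mass
  }
  out <- survival_curve(age, pmin(lx, 1), kind = kind, label = label)
  attr(out, "step") <- step
  attr(out, "truncated_mass") <- truncated
  out
}

#' Life-table summaries of a survival curve
#'
#' `life_expectancy()` integrates \eqn{\ell(x)} by the trapezoidal rule over
#' the curve's age grid: mean years of life, \eqn{e_0}. `e_dagger()`
#' integrates \eqn{-\ell(x) \ln \ell(x)} with the analytic-limit convention
#' \eqn{0 \ln 0 = 1 \ln 1 = 0}: the average life expectancy lost per death,
#' \eqn{e^\dagger}, an absolute measure of lifespan variation.
#' `lifetable_entropy()` combines them into the Keyfitz–Leser life table
#' entropy \eqn{H = e^\dagger / e_0}, a relative (dimensionless) measure of
#' lifespan inequality: 0 when all deaths are concentrated at a single age,
#' 1 when death rates are equal across all ages. Values above 1 (possible
#' under extreme infant mortality) are flagged with a warning, never
#' clamped.
#'
#' @param curve A [survival_curve()].
#' @return `life_expectancy()` and `e_dagger()` return a single number in
#'   years. `lifetable_entropy()` returns a one-row tibble with columns
#'   `e0`, `edagger`, `entropy` and `omega` (the top age of the grid).
#' @examples
#' gomp <- survival_from_hazard(1e-4 * exp(0.1 * 0:120), step = 0.25)
#' lifetable_entropy(gomp)
#' @export
life_expectancy <- function(curve) {
  check_curve(curve)
  trapz(curve$age, curve$lx)
}

#' @rdname life_expectancy
#' @export
e_dagger <- function(curve) {
  check_curve(curve)
  trapz(curve$age, xlogx_term(curve$lx))
}

#' @rdname life_expectancy
#' @export
lifetable_entropy <- function(curve) {
  check_curve(curve)
  e0 <- life_expectancy(curve)
  if (e0 <= 0) {
    abort("degenerate survival curve: life expectancy is 0.")
  }
  ed <- e_dagger(curve)
  h <- ed / e0
  if (h > 1 + 1e-9) {
    warn(sprintf(
      "life table entropy %.6f exceeds 1 (possible under extreme infant mortality).",
      h
    ))
  }
  tibble(e0 = e0, edagger = ed, entropy = h, omega = max(curve$age))
}

#' Period and cohort entropy from a mortality surface
#'
#' `period_entropy()` summarises the period column of one calendar year:
#' survival built from that year's hazards, then \eqn{e_0}, \eqn{e^\dagger}
#' and their ratio. `cohort_entropy()` does the same along the Lexis diagonal
#' of one birth cohort, which must be observable on the surface up to the
#' surface's top age (the tail beyond is closed by the terminal-hazard
#' rule of [survival_from_hazard()]).
#'
#' @inheritParams period_column
#' @param step Grid refinement passed to [survival_from_hazard()].
#' @return A one-row tibble: `year` (or `cohort`), `e0`, `edagger`,
#'   `entropy`, `omega`.
#' @export
period_entropy <- function(surface, year, step = 1) {
  check_surface(surface)
  curve <- survival_from_hazard(period_column(surface, year)$mx, step = step,
                                kind = "period", label = as.character(year))
  dplyr::bind_cols(tibble(year = as.integer(year)), lifetable_entropy(curve))
}

#' @rdname period_entropy
#' @param birth_year Birth year of the cohort to follow to extinction.
#' @export
cohort_entropy <- function(surface, birth_year, step = 1) {
  check_surface(surface)
  top <- max(surface$age)
  last_year <- max(surface$year)
  if (!is_int_scalar(birth_year) || birth_year + top > last_year) {
    abort(sprintf(
      "cohort %s is not observable to the top age %d (needs years through %s, surface ends %d).",
      format(birth_year), top,
      format(if (is_int_scalar(birth_year)) birth_year + top else NA), last_year
    ))
  }
  diag <- cohort_diagonal(surface, birth_year, top)
  curve <- survival_from_hazard(diag$mx, step = step, kind = "cohort",
                                label = as.character(birth_year))
  dplyr::bind_cols(tibble(cohort = as.integer(birth_year)),
                   lifetable_entropy(curve))
}
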
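#' Trend summaries of entropy series
#'
#' `fit_linear()` fits an ordinary least-squares line to a measure over
#' calendar years. `fit_piecewise()` fits a continuous two-segment
#' (hinge-parameterised) least-squares line, choosing the breakpoint by
#' exhaustive search over the observed interior years — at least three
#' points on each side — to minimise the total sum of squared errors, with
#' ties broken toward the earliest year. The piecewise fit nests the linear
#' fit, so its SSE never exceeds the linear one.
#'
#' @param data A data frame holding the series.
#' @param value Column with the measure (tidy-eval).
#' @param year Column with the calendar year (tidy-eval, default `year`).
#' @param min_segment Minimum number of points per segment for the
#'   breakpoint search.
#' @return An object of class `trend_fit`: supports [tidy()], [glance()],
#'   [autoplot()] and `print()`. Fields include `slope_per_year` (linear),
#'   `segment_slopes` and `breakpoint_year` (piecewise), `intercept`,
#'   `r_squared`, `sse` and the fitted series.
#' @examples
#' d <- data.frame(year = 1900:1950, h = 0.5 - 0.001 * (0:50))
#' fit_linear(d, h)
#' @export
fit_linear <- function(data, value, year = year) {
  series <- extract_series(data, {{ value }}, {{ year }}, min_points = 3L)
  fit <- lm(v ~ I(t - t0), data = list(v = series$v, t = series$t,
                                       t0 = series$t[1L]))
  sse <- sum(stats::residuals(fit)^2)
  new_trend_fit(
    model = "linear",
    years = series$t, values = series$v,
    fitted = as.numeric(stats::fitted(fit)),
    slope_per_year = unname(coef(fit)[2L]),
    intercept = unname(coef(fit)[1L]),
    breakpoint_year = NA_integer_,
    segment_slopes = NULL,
    sse = sse,
    r_squared = r_squared_from_sse(series$v, sse)
  )
}

#' @rdname fit_linear
#' @export
fit_piecewise <- function(data, value, year = year, min_segment = 3L) {
  series <- extract_series(data, {{ value }}, {{ year }},
                           min_points = 2L * min_segment + 1L)
  t <- series$t
  v <- series$v
  n <- length(t)
  candidates <- t[seq(min_segment, n - min_segment + 1L)]
  best <- NULL
  for (bp in candidates) {
    hinge <- pmax(t - bp, 0)
    fit <- lm(v ~ I(t - t[1L]) + hinge)
    sse <- sum(stats::residuals(fit)^2)
    if (is.null(best) || sse < best$sse - 1e-12) {
      best <- list(fit = fit, sse = sse, bp = bp)
    }
  }
  b <- coef(best$fit)
  new_trend_fit(
    model = "piecewise",
    years = t, values = v,
    fitted = as.numeric(stats::fitted(best$fit)),
    slope_per_year = NA_real_,
    intercept = unname(b[1L]),
    breakpoint_year = as.integer(best$bp),
    segment_slopes = c(before = unname(b[2L]),
                       after = unname(b[2L] + b[3L])),
    sse = best$sse,
    r_squared = r_squared_from_sse(v, best$sse)
  )
}

extract_series <- function(data, value, year, min_points) {
  if (!is.data.frame(data)) {
    abort("`data` must be a data frame.")
  }
  v <- dplyr::pull(data, {{ value }})
  t <- dplyr::pull(data, {{ year }})
  keep <- is.finite(v) & is.finite(t)
  v <- v[keep]
  t <- t[keep]
  if (length(unique(t)) < 2L) {
    abort("`year` must take at least two distinct values.")
  }
  if (length(v) < min_points) {
    abort(sprintf("need at least %d finite points, got %d.",
                  min_points, length(v)))
  }
  ord <- order(t)
  list(t = t[ord], v = v[ord])
}

r_squared_from_sse <- function(v, sse) {
  sst <- sum((v - mean(v))^2)
  if (sst < 1e-300) {
    return(1)
  }
  max(0, min(1, 1 - sse / sst))
}

new_trend_fit <- function(...) {
  structure(list(...), class = "trend_fit")
}

#' @export
print.trend_fit <- function(x, ...) {
  cat(sprintf("<trend_fit> %s over %d-%d (n = %d), R^2 = %.4f\n",
              x$model, min(x$years), max(x$years), length(x$years),
              x$r_squared))
  if (x$model == "linear") {
    cat(sprintf("  slope: %.6g per year\n", x$slope_per_year))
  } else {
    cat(sprintf("  breakpoint: %d; slopes %.6g (before), %.6g (after) per year\n",
                x$breakpoint_year, x$segment_slopes[["before"]],
                x$segment_slopes[["after"]]))
  }
  invisible(x)
}

#' @rdname fit_linear
#' @param x A `trend_fit` object.
#' @param ... Unused.
#' @method tidy trend_fit
#' @export
tidy.trend_fit <- function(x, ...) {
  if (x$model == "linear") {
    tibble(term = c("intercept", "slope_per_year"),
           estimate = c(x$intercept, x$slope_per_year))
  } else {
    tibble(
      term = c("intercept", "slope_before", "slope_after",
               "breakpoint_year"),
      estimate = c(x$intercept, x$segment_slopes[["before"]],
                   x$segment_slopes[["after"]], x$breakpoint_year)
    )
  }
}

#' @rdname fit_linear
#' @method glance trend_fit
#' @export
glance.trend_fit <- function(x, ...) {
  tibble(
    model = x$model,
    r.squared = x$r_squared,
    sse = x$sse,
    nobs = length(x$years),
    breakpoint_year = x$breakpoint_year
  )
}

#' Mean intrinsic rate of change between two dates
#'
#' The annualised logarithmic rate \eqn{\ln(v_2 / v_1) / (t_2 - t_1)},
#' analogous to the instantaneous growth rate of a population: exact for
#' exponential trajectories and invariant to rescaling the series by a
#' positive constant. Multiplied by 100 it reads as percent per year.
#'
#' @param v1,v2 Positive values of the measure at `t1` and `t2`.
#' @param t1,t2 The two dates, `t2 > t1`.
#' @return Per-year log rate (a single number).
#' @examples
#' intrinsic_rate(0.2, 0.1, 2000, 2010) # ln(1/2)/10
#' @export
intrinsic_rate <- function(v1, v2, t1, t2) {
  if (any(!is.finite(c(v1, v2, t1, t2)))) {
    abort("all arguments must be finite.")
  }
  if (v1 <= 0 || v2 <= 0) {
    abort("`v1` and `v2` must be strictly positive.")
  }
  if (t2 <= t1) {
    abort("`t2` must exceed `t1`.")
  }
  log(v2 / v1) / (t2 - t1)
}

#' Write a CSV summary of trend fits
#'
#' One row per fit: measure and population labels, model, slope(s),
#' breakpoint and R-squared.
#'
#' @param fits A named list of `trend_fit` objects; names are used as the
#'   `measure` label, optionally as `"measure/population"`.
#' @param path Output path.
#' @return The summary tibble, invisibly.
#' @export
write_trend_summary <- function(fits, path) {
  if (inherits(fits, "trend_fit")) {
    fits <- list(fit = fits)
  }
  rows <- purrr::imap(fits, function(f, nm) {
    parts <- strsplit(nm, "/", fixed = TRUE)[[1L]]
    tibble(
      measure = parts[1L],
      population = if (length(parts) > 1L) parts[2L] else NA_character_,
      model = f$model,
      slope_per_year = f$slope_per_year,
      slope_before = if (is.null(f$segment_slopes)) NA_real_
                     else f$segment_slopes[["before"]],
      slope_after = if (is.null(f$segment_slopes)) NA_real_
                    else f$segment_slopes[["after"]],
      breakpoint_year = f$breakpoint_year,
      r_squared = f$r_squared
    )
  })
  out <- bind_rows(rows)
  readr::write_csv(out, path)
  invisible(out)
}
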
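# ggplot2 views of the package's result types. Each autoplot() method has a
# thin plot_*() alias.

#' Plot a cross-sectional entropy series
#'
#' Line chart of one measure (`h_cal` by default, or `cal` / `cal_dagger`)
#' over time, coloured by population when several are stacked.
#'
#' @param object A [cal_series()] tibble (possibly several populations
#'   stacked with [dplyr::bind_rows()]).
#' @param measure Column to draw: `"h_cal"`, `"cal"` or `"cal_dagger"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot cal_series
#' @export
autoplot.cal_series <- function(object, measure = c("h_cal", "cal",
                                                    "cal_dagger"), ...) {
  measure <- match.arg(measure)
  lab <- c(h_cal = "CAL-entropy", cal = "CAL (years)",
           cal_dagger = "CAL-dagger (years)")[[measure]]
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$year, y = .data[[measure]],
                               colour = .data$population)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "year", y = lab, colour = NULL) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.cal_series
#' @param x A [cal_series()] tibble.
#' @export
plot_cal_series <- function(x, measure = "h_cal", ...) {
  autoplot.cal_series(x, measure = measure, ...)
}

#' Plot a gap decomposition
#'
#' Stacked bars of the lifespan-variation and longevity contributions per
#' year, with the total gap overlaid as a line with points: bars below zero
#' narrow the population's inequality gap to the benchmark, bars above zero
#' widen it.
#'
#' @param object A [decompose_gap()] tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot gap_decomposition
#' @export
autoplot.gap_decomposition <- function(object, ...) {
  long <- tidyr::pivot_longer(
    as_tibble(object),
    cols = c("contrib_variation", "contrib_longevity"),
    names_to = "component", values_to = "contribution",
    names_prefix = "contrib_"
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$year)) +
    ggplot2::geom_col(ggplot2::aes(y = .data$contribution,
                                   fill = .data$component)) +
    ggplot2::geom_line(data = as_tibble(object),
                       ggplot2::aes(y = .data$gap)) +
    ggplot2::geom_point(data = as_tibble(object),
                        ggplot2::aes(y = .data$gap), size = 0.8) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dotted") +
    ggplot2::labs(x = "year", y = "CAL-entropy gap vs benchmark",
                  fill = NULL) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.gap_decomposition
#' @param x A [decompose_gap()] tibble.
#' @export
plot_gap_decomposition <- function(x, ...) {
  autoplot.gap_decomposition(x, ...)
}

#' Plot a gap-change decomposition
#'
#' Stacked bars of the benchmark, variation and longevity terms of each
#' year-on-year change in the entropy gap, with the total change overlaid.
#'
#' @param object A [decompose_gap_change()] tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot gap_change_decomposition
#' @export
autoplot.gap_change_decomposition <- function(object, ...) {
  long <- tidyr::pivot_longer(
    as_tibble(object),
    cols = c("term_benchmark", "term_variation", "term_longevity"),
    names_to = "component", values_to = "contribution",
    names_prefix = "term_"
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$year)) +
    ggplot2::geom_col(ggplot2::aes(y = .data$contribution,
                                   fill = .data$component)) +
    ggplot2::geom_line(data = as_tibble(object),
                       ggplot2::aes(y = .data$total_change)) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dotted") +
    ggplot2::labs(x = "year", y = "change in CAL-entropy gap", fill = NULL) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.gap_change_decomposition
#' @param x A [decompose_gap_change()] tibble.
#' @export
plot_gap_change_decomposition <- function(x, ...) {
  autoplot.gap_change_decomposition(x, ...)
}

#' Plot a trend fit
#'
#' Observed points with the fitted line (both segments for a piecewise
#' fit); the breakpoint, when present, is marked with a dashed vertical
#' line.
#'
#' @param object A `trend_fit` from [fit_linear()] or [fit_piecewise()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot trend_fit
#' @export
autoplot.trend_fit <- function(object, ...) {
  d <- tibble(year = object$years, value = object$values,
              fitted = object$fitted)
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$year)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$value), size = 0.8) +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted), colour = "red") +
    ggplot2::labs(x = "year", y = "value") +
    ggplot2::theme_minimal()
  if (!is.na(object$breakpoint_year)) {
    p <- p + ggplot2::geom_vline(xintercept = object$breakpoint_year,
                                 linetype = "dashed")
  }
  p
}

#' @rdname autoplot.trend_fit
#' @param x A `trend_fit` object.
#' @export
plot_trend_fit <- function(x, ...) {
  autoplot.trend_fit(x, ...)
}
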
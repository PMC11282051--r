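# Cross-population decomposition of CAL-entropy gaps and of their change
# over time. The continuous population index is realised as the finite
# difference population-minus-benchmark; relative derivatives X-dot/X become
# log-ratios, which makes the gap split exactly additive:
#
#   gap = H_pop - H_bench = H~ * ln(H_pop / H_bench)
#       = H~ * ln(CALdag_pop / CALdag_bench) - H~ * ln(CAL_pop / CAL_bench)
#
# with H~ the logarithmic mean of the two entropies (arithmetic-mean
# fallback when the gap is numerically zero, e.g. the 10/50 vs 15/75 pair).

# Effective benchmark variation level: a mean-of-entropy benchmark has
# H != CALdag/CAL in general (Jensen gap); imposing CALdag_eff = H * CAL
# restores the identity ln H = ln CALdag - ln CAL that the additive split
# rests on, allocating the (small) inconsistency to the variation term.
check_cal_cols <- function(x, arg) {
  cols <- c("year", "cal", "cal_dagger", "h_cal")
  if (!is.data.frame(x) || !all(cols %in% names(x))) {
    abort(sprintf(
      "`%s` must be a data frame with columns year, cal, cal_dagger, h_cal (see cal_series()).",
      arg
    ))
  }
  if (any(x$cal <= 0) || any(x$cal_dagger <= 0) || any(x$h_cal <= 0)) {
    abort(sprintf("`%s` must have strictly positive cal, cal_dagger and h_cal.", arg))
  }
  invisible(x)
}

#' Benchmark average of cross-sectional entropy results
#'
#' Builds the per-year benchmark level against which individual populations
#' are compared. The default mode, `"mean-of-entropy"`, takes the unweighted
#' arithmetic mean of the member populations' CAL-entropy (and of CAL and
#' CAL-dagger) at each year, giving every population the same weight. The
#' sensitivity mode `"entropy-of-mean-rates"` instead averages the member
#' mortality surfaces cell-wise and computes the cross-sectional measures on
#' the averaged surface.
#'
#' @param results For `"mean-of-entropy"`: a list of [cal_series()] tibbles
#'   (or one stacked tibble with a `population` column), at least two
#'   populations covering identical years with identical `n_cohorts`.
#' @param mode Averaging mode, see above.
#' @param surfaces For `"entropy-of-mean-rates"`: a list of at least two
#'   [mortality_surface][as_mortality_surface] objects on identical grids.
#' @param omega,step Cross-section parameters used in the
#'   `"entropy-of-mean-rates"` mode.
#' @return A tibble shaped like a [cal_series()] with
#'   `population = "benchmark"`. In the default mode `h_cal` is the mean of
#'   the member entropies (and therefore not exactly `cal_dagger / cal`).
#' @export
benchmark_average <- function(results = NULL,
                              mode = c("mean-of-entropy",
                                       "entropy-of-mean-rates"),
                              surfaces = NULL, omega = 110, step = 1) {
  mode <- match.arg(mode)
  if (mode == "entropy-of-mean-rates") {
    if (is.null(surfaces) || length(surfaces) < 2L) {
      abort("`surfaces` must list at least two mortality surfaces for entropy-of-mean-rates.")
    }
    purrr::walk(surfaces, check_surface)
    grids <- purrr::map(surfaces, function(s) {
      list(a = surface_ages(s), y = surface_years(s))
    })
    same <- purrr::every(grids, function(g) identical(g, grids[[1L]]))
    if (!same) {
      abort("all surfaces must share the same age and year grids.")
    }
    mean_m <- Reduce(`+`, purrr::map(surfaces, surface_matrix)) /
      length(surfaces)
    avg <- as_mortality_surface(
      tibble(
        year = rep(grids[[1L]]$y, each = length(grids[[1L]]$a)),
        age = rep(grids[[1L]]$a, length(grids[[1L]]$y)),
        mx = as.vector(mean_m)
      ),
      population = "benchmark", sex = attr(surfaces[[1L]], "sex")
    )
    years <- surface_years(avg)
    covered <- years[years - omega >= years[1L]]
    out <- cal_series(avg, covered, omega = omega, step = step)
    return(out)
  }
  if (is.data.frame(results)) {
    if (!"population" %in% names(results)) {
      abort("a stacked `results` tibble needs a `population` column.")
    }
    results <- split(as_tibble(results), results$population)
  }
  if (!is.list(results) || length(results) < 2L) {
    abort("`results` must contain at least two populations.")
  }
  purrr::iwalk(results, function(x, i) check_cal_cols(x, paste0("results[", i, "]")))
  years0 <- sort(results[[1L]]$year)
  ok <- purrr::every(results, function(x) {
    identical(sort(x$year), years0) &&
      identical(sort(unique(x$n_cohorts %||% NA_integer_)),
                sort(unique(results[[1L]]$n_cohorts %||% NA_integer_)))
  })
  if (!ok) {
    abort("all populations must cover identical years with identical omega (n_cohorts).")
  }
  stacked <- bind_rows(purrr::map(results, function(x) {
    as_tibble(x)[c("year", "cal", "cal_dagger", "h_cal", "n_cohorts")]
  }))
  out <- stacked |>
    group_by(.data$year) |>
    summarise(
      cal = mean(.data$cal),
      cal_dagger = mean(.data$cal_dagger),
      h_cal = mean(.data$h_cal),
      n_cohorts = .data$n_cohorts[1L],
      .groups = "drop"
    ) |>
    mutate(population = "benchmark", .before = 1L)
  new_tibble(out, class = "cal_series")
}

# One-pair split of gap = H_pop - H_bench into variation and longevity
# contributions; vectorised over years.
gap_split <- function(h_pop, cal_pop, h_bench, cal_bench) {
  gap <- h_pop - h_bench
  h_tilde <- log_mean(h_pop, h_bench)
  dag_pop_eff <- h_pop * cal_pop
  dag_bench_eff <- h_bench * cal_bench
  contrib_variation <- h_tilde * log(dag_pop_eff / dag_bench_eff)
  contrib_longevity <- -h_tilde * log(cal_pop / cal_bench)
  list(
    gap = gap, h_tilde = h_tilde,
    r_dagger = log(dag_pop_eff / dag_bench_eff),
    r_cal = log(cal_pop / cal_bench),
    contrib_variation = contrib_variation,
    contrib_longevity = contrib_longevity
  )
}

#' Decompose the CAL-entropy gap between a population and a benchmark
#'
#' Splits each year's entropy gap \eqn{H_{pop} - H_{bench}} into an exactly
#' additive lifespan-variation contribution and longevity contribution. The
#' split uses the identity \eqn{\ln H = \ln \mathrm{CAL}^\dagger - \ln
#' \mathrm{CAL}}: with the logarithmic-mean entropy level \eqn{\tilde H =
#' (H_{pop} - H_{bench}) / \ln(H_{pop}/H_{bench})} (arithmetic mean when the
#' gap is numerically zero),
#' \deqn{\mathrm{contrib}_{var} = \tilde H\,
#'   \ln(\mathrm{CAL}^\dagger_{pop}/\mathrm{CAL}^\dagger_{bench}), \qquad
#'   \mathrm{contrib}_{lon} = -\tilde H\,
#'   \ln(\mathrm{CAL}_{pop}/\mathrm{CAL}_{bench}),}
#' so the two contributions sum to the gap by construction. A
#' mean-of-entropy benchmark is made internally consistent by using
#' \eqn{H_{bench} \cdot \mathrm{CAL}_{bench}} as its effective variation
#' level. A negative contribution narrows the population's inequality
#' relative to the benchmark; a positive one widens it.
#'
#' @param pop A [cal_series()] tibble for the population.
#' @param bench A benchmark series from [benchmark_average()] (or any
#'   cal_series-shaped tibble) covering the same years.
#' @return A tibble of class `gap_decomposition` with columns `year`,
#'   `population`, `gap`, `contrib_variation`, `contrib_longevity`.
#' @examples
#' # the worked pair: same entropy 0.2 from (10, 50) and (15, 75)
#' pop <- tibble::tibble(population = "P", year = 2000L, cal = 50,
#'                       cal_dagger = 10, h_cal = 0.2, n_cohorts = 111L)
#' bench <- tibble::tibble(population = "B", year = 2000L, cal = 75,
#'                         cal_dagger = 15, h_cal = 0.2, n_cohorts = 111L)
#' decompose_gap(pop, bench)
#' @export
decompose_gap <- function(pop, bench) {
  check_cal_cols(pop, "pop")
  check_cal_cols(bench, "bench")
  joined <- inner_join(
    as_tibble(pop)[c("year", "cal", "cal_dagger", "h_cal")],
    as_tibble(bench)[c("year", "cal", "cal_dagger", "h_cal")],
    by = "year", suffix = c("_pop", "_bench")
  )
  if (nrow(joined) == 0L) {
    abort("`pop` and `bench` share no years.")
  }
  parts <- gap_split(joined$h_cal_pop, joined$cal_pop,
                     joined$h_cal_bench, joined$cal_bench)
  out <- tibble(
    year = as.integer(joined$year),
    population = if ("population" %in% names(pop)) pop$population[1L]
                 else "population",
    gap = parts$gap,
    contrib_variation = parts$contrib_variation,
    contrib_longevity = parts$contrib_longevity
  ) |>
    arrange(.data$year)
  new_tibble(out, class = "gap_decomposition")
}

#' Decompose the change over time in a CAL-entropy gap
#'
#' Differences-of-differences: the year-on-year change in the entropy gap
#' between a population and the benchmark is split into three terms — the
#' contribution of changes in the benchmark-average entropy level, of
#' changes in lifespan variation, and of changes in longevity — plus a
#' reported residual. Writing the gap as \eqn{\tilde H(t) \, [R^\dagger(t) -
#' R(t)]} with the log-ratio brackets \eqn{R^\dagger = \ln(\mathrm{CAL}^
#' \dagger_{pop}/\mathrm{CAL}^\dagger_{bench})}, \eqn{R = \ln(\mathrm{CAL}_
#' {pop}/\mathrm{CAL}_{bench})}, the discretisation uses first differences
#' for the differenced factors and two-year midpoint averages for the
#' others:
#' \deqn{\Delta\mathrm{gap} = \Delta\tilde H \cdot [\bar R^\dagger - \bar R]
#'   + \bar{\tilde H}\,\Delta R^\dagger - \bar{\tilde H}\,\Delta R +
#'   \mathrm{residual}.}
#' By the exact midpoint product rule the residual is zero to machine
#' precision; it is computed and reported rather than folded into a term so
#' that any future change of scheme stays honest.
#'
#' @inheritParams decompose_gap
#' @return A tibble of class `gap_change_decomposition` with columns
#'   `year_from`, `year`, `population`, `total_change`, `term_benchmark`,
#'   `term_variation`, `term_longevity`, `residual`; one row per consecutive
#'   year pair.
#' @export
decompose_gap_change <- function(pop, bench) {
  check_cal_cols(pop, "pop")
  check_cal_cols(bench, "bench")
  joined <- inner_join(
    as_tibble(pop)[c("year", "cal", "cal_dagger", "h_cal")],
    as_tibble(bench)[c("year", "cal", "cal_dagger", "h_cal")],
    by = "year", suffix = c("_pop", "_bench")
  ) |>
    arrange(.data$year)
  if (nrow(joined) < 2L) {
    abort("need at least two shared years to difference.")
  }
  if (any(diff(joined$year) != 1L)) {
    abort("shared years must be consecutive for year-on-year differencing.")
  }
  parts <- gap_split(joined$h_cal_pop, joined$cal_pop,
                     joined$h_cal_bench, joined$cal_bench)
  n <- nrow(joined)
  i1 <- seq_len(n - 1L) # t - 1
  i2 <- i1 + 1L         # t
  bracket <- parts$r_dagger - parts$r_cal
  d_h <- parts$h_tilde[i2] - parts$h_tilde[i1]
  mid_h <- (parts$h_tilde[i2] + parts$h_tilde[i1]) / 2
  mid_bracket <- (bracket[i2] + bracket[i1]) / 2
  term_benchmark <- d_h * mid_bracket
  term_variation <- mid_h * (parts$r_dagger[i2] - parts$r_dagger[i1])
  term_longevity <- -mid_h * (parts$r_cal[i2] - parts$r_cal[i1])
  total <- parts$gap[i2] - parts$gap[i1]
  out <- tibble(
    year_from = as.integer(joined$year[i1]),
    year = as.integer(joined$year[i2]),
    population = if ("population" %in% names(pop)) pop$population[1L]
                 else "population",
    total_change = total,
    term_benchmark = term_benchmark,
    term_variation = term_variation,
    term_longevity = term_longevity,
    residual = total - (term_benchmark + term_variation + term_longevity)
  )
  new_tibble(out, class = "gap_change_decomposition")
}

#' Component shares of a decomposition, with rolling means
#'
#' For each year, a component's share is its absolute contribution over the
#' total absolute contribution of all components: for a gap decomposition
#' the lifespan-variation and longevity contributions; for a gap-change
#' decomposition the benchmark, variation and longevity terms. Raw shares
#' sum to 1 at each year; years where every component is zero are emitted as
#' missing and excluded from the rolling mean. Shares are then smoothed by a
#' centred rolling mean of width `window` (odd; shrinking at the series
#' edges) to avoid outliers from specific years.
#'
#' @param decomp A [decompose_gap()] or [decompose_gap_change()] tibble.
#' @param window Odd rolling-mean window in years; `1` leaves shares raw.
#' @return A long tibble with columns `year`, `component`, `share_raw`,
#'   `share` (rolling mean) and `window`.
#' @export
component_shares <- function(decomp, window = 5) {
  if (!is_int_scalar(window) || window < 1 || window %% 2 == 0) {
    abort("`window` must be an odd integer >= 1.")
  }
  comp_cols <- if (inherits(decomp, "gap_change_decomposition") ||
                   all(c("term_benchmark", "term_variation",
                         "term_longevity") %in% names(decomp))) {
    c("term_benchmark", "term_variation", "term_longevity")
  } else if (all(c("contrib_variation", "contrib_longevity") %in%
                 names(decomp))) {
    c("contrib_variation", "contrib_longevity")
  } else {
    abort("`decomp` must come from decompose_gap() or decompose_gap_change().")
  }
  if (nrow(decomp) == 0L) {
    abort("`decomp` has no rows.")
  }
  mat <- abs(as.matrix(as_tibble(decomp)[comp_cols]))
  totals <- rowSums(mat)
  share_raw <- mat / ifelse(totals > 0, totals, NA_real_)
  out <- purrr::map(seq_along(comp_cols), function(j) {
    raw <- share_raw[, j]
    tibble(
      year = as.integer(decomp$year),
      component = sub("^(contrib|term)_", "", comp_cols[j]),
      share_raw = raw,
      share = rolling_mean(raw, window),
      window = as.integer(window)
    )
  })
  bind_rows(out)
}

#' Detect crossover years in a gap series
#'
#' A crossover is a year whose gap has the strictly opposite sign of the
#' previous year's — the population moves to the other side of the
#' benchmark average. Zero gaps attach to the following sign (a trailing
#' run of zeros attaches to the preceding sign), so a `-, 0, +` sequence
#' yields one crossover, reported at the zero year where the sign flips.
#'
#' @param gaps A data frame with columns `year` and `gap` (e.g. from
#'   [decompose_gap()]), at least two years.
#' @return An integer vector of crossover years (possibly empty).
#' @export
detect_crossovers <- function(gaps) {
  if (!is.data.frame(gaps) || !all(c("year", "gap") %in% names(gaps))) {
    abort("`gaps` must have columns year and gap.")
  }
  gaps <- arrange(as_tibble(gaps), .data$year)
  if (nrow(gaps) < 2L) {
    abort("need at least two years.")
  }
  s <- sign(gaps$gap)
  nz <- which(s != 0)
  if (length(nz) == 0L) {
    return(integer())
  }
  # zeros attach to the following nonzero sign; trailing zeros to previous
  for (i in rev(seq_along(s))) {
    if (s[i] == 0) {
      s[i] <- if (i < length(s)) s[i + 1L] else 0
    }
  }
  for (i in seq_along(s)) {
    if (s[i] == 0) {
      s[i] <- if (i > 1L) s[i - 1L] else 0
    }
  }
  flips <- which(diff(s) != 0 & s[-length(s)] != 0 & s[-1L] != 0) + 1L
  as.integer(gaps$year[flips])
}
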
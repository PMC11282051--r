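#' Mortality surfaces
#'
#' A mortality surface is a rectangular age-by-calendar-year grid of
#' age-specific mortality rates \eqn{m(x, t)} (deaths per person-year), the
#' Lexis surface that every measure in this package reads from. It is stored
#' as a long tibble with columns `year`, `age` and `mx`, one row per cell,
#' carrying the population label and sex as attributes. Ages are single years
#' starting at 0 (age `x` labels the interval \eqn{[x, x+1)}); years are
#' consecutive calendar years (year `t` labels \eqn{[t, t+1)}). Cohorts run
#' along the diagonals: the cohort born in year \eqn{c} experiences
#' \eqn{m(a, c + a)} at age \eqn{a}.
#'
#' `as_mortality_surface()` validates a long data frame and stamps the class;
#' it is the single gatekeeper, so every reader and generator funnels through
#' it. Validation is strict: missing cells, negative or non-finite rates,
#' duplicated cells, or gaps in the age or year grids are errors, never
#' silently imputed — a silently absorbed gap would contaminate every later
#' cross-sectional measure.
#'
#' @param data A data frame with columns `year`, `age`, `mx` covering a
#'   complete rectangular grid.
#' @param population Free-text population label.
#' @param sex One of `"female"`, `"male"`, `"total"`.
#' @return A tibble of class `mortality_surface`.
#' @examples
#' grid <- expand.grid(year = 2000:2002, age = 0:4)
#' grid$mx <- 0.1
#' as_mortality_surface(grid, population = "demo")
#' @export
as_mortality_surface <- function(data, population = "unnamed", sex = "total") {
  data <- as_tibble(data)
  required <- c("year", "age", "mx")
  missing_cols <- setdiff(required, names(data))
  if (length(missing_cols) > 0L) {
    abort(paste0(
      "`data` must have columns year, age, mx; missing: ",
      paste(missing_cols, collapse = ", ")
    ))
  }
  sex <- match.arg(sex, c("female", "male", "total"))
  data <- data[required]
  if (nrow(data) == 0L) {
    abort("`data` has no rows.")
  }
  if (anyNA(data$year) || anyNA(data$age)) {
    abort("`year` and `age` must not contain missing values.")
  }
  if (any(data$year != round(data$year)) || any(data$age != round(data$age))) {
    abort("`year` and `age` must be integers (single-year Lexis cells).")
  }
  dup <- duplicated(data[c("year", "age")])
  if (any(dup)) {
    first <- data[which(dup)[1L], ]
    abort(sprintf(
      "duplicated (year, age) cell: (%d, %d)", first$year, first$age
    ))
  }
  ages <- sort(unique(data$age))
  years <- sort(unique(data$year))
  if (ages[1L] != 0L) {
    abort("ages must start at 0.")
  }
  if (!identical(as.integer(ages), as.integer(seq(0L, max(ages))))) {
    abort("ages must be consecutive single years starting at 0.")
  }
  if (!identical(as.integer(years), as.integer(seq(min(years), max(years))))) {
    abort("years must be consecutive calendar years.")
  }
  if (nrow(data) != length(ages) * length(years)) {
    full <- tidyr::expand_grid(year = years, age = ages)
    gaps <- dplyr::anti_join(full, data, by = c("year", "age"))
    abort(paste0(
      "incomplete surface; missing (year, age) cells: ",
      paste(sprintf("(%d, %d)", head(gaps$year, 5L), head(gaps$age, 5L)),
            collapse = ", "),
      if (nrow(gaps) > 5L) sprintf(" and %d more", nrow(gaps) - 5L) else ""
    ))
  }
  bad <- !is.finite(data$mx) | data$mx < 0
  if (any(bad)) {
    first <- data[which(bad)[1L], ]
    abort(sprintf(
      "rates must be finite and >= 0; offending cell (year %d, age %d): %s",
      first$year, first$age, format(first$mx)
    ))
  }
  out <- arrange(data, .data$year, .data$age)
  out$year <- as.integer(out$year)
  out$age <- as.integer(out$age)
  structure(
    out,
    population = population,
    sex = sex,
    class = c("mortality_surface", class(as_tibble(out)))
  )
}

#' @export
print.mortality_surface <- function(x, ...) {
  cat(sprintf(
    "<mortality_surface> %s (%s): ages 0-%d, years %d-%d\n",
    attr(x, "population") %||% "unnamed", attr(x, "sex") %||% "total",
    max(x$age), min(x$year), max(x$year)
  ))
  NextMethod()
}

# Wide ages x years matrix view; rows ages 0..omega_max, columns years.
surface_matrix <- function(surface) {
  ages <- sort(unique(surface$age))
  years <- sort(unique(surface$year))
  m <- matrix(NA_real_, length(ages), length(years),
              dimnames = list(ages, years))
  m[cbind(surface$age + 1L, surface$year - years[1L] + 1L)] <- surface$mx
  m
}

surface_years <- function(surface) sort(unique(surface$year))
surface_ages <- function(surface) sort(unique(surface$age))

check_surface <- function(surface) {
  if (!inherits(surface, "mortality_surface")) {
    abort("`surface` must be a mortality_surface (see as_mortality_surface()).")
  }
  invisible(surface)
}

#' Extract a period hazard column
#'
#' Returns the age-specific hazards of one calendar year — the vertical line
#' on the Lexis surface that a period life table summarises.
#'
#' @param surface A [mortality_surface][as_mortality_surface].
#' @param year Calendar year within the surface.
#' @return A tibble with columns `age` and `mx`.
#' @export
period_column <- function(surface, year) {
  check_surface(surface)
  years <- surface_years(surface)
  if (!is_int_scalar(year) || year < years[1L] || year > years[length(years)]) {
    abort(sprintf(
      "`year` (%s) outside the surface years %d-%d.",
      format(year), years[1L], years[length(years)]
    ))
  }
  out <- filter(surface, .data$year == !!as.integer(year))
  tibble(age = out$age, mx = out$mx)
}

#' Extract a cohort hazard diagonal
#'
#' Follows one birth cohort down the Lexis diagonal: the cohort born in year
#' \eqn{c} experiences hazard \eqn{m(a, c + a)} at age \eqn{a}. Returns ages
#' `0..max_age`; every required cell must lie on the surface.
#'
#' @inheritParams period_column
#' @param birth_year Birth year of the cohort.
#' @param max_age Highest age (inclusive) to follow the cohort to.
#' @return A tibble with columns `age`, `year` and `mx` (rows `max_age + 1`).
#' @export
cohort_diagonal <- function(surface, birth_year, max_age) {
  check_surface(surface)
  if (!is_int_scalar(birth_year) || !is_int_scalar(max_age) || max_age < 0) {
    abort("`birth_year` and `max_age` must be integers, max_age >= 0.")
  }
  years <- surface_years(surface)
  ages <- surface_ages(surface)
  need_age <- 0:max_age
  need_year <- birth_year + need_age
  bad <- need_year < years[1L] | need_year > years[length(years)] |
    need_age > ages[length(ages)]
  if (any(bad)) {
    i <- which(bad)[1L]
    abort(sprintf(
      "cohort %d not covered: cell (age %d, year %d) outside the surface.",
      birth_year, need_age[i], need_year[i]
    ))
  }
  m <- surface_matrix(surface)
  tibble(
    age = as.integer(need_age),
    year = as.integer(need_year),
    mx = m[cbind(need_age + 1L, need_year - years[1L] + 1L)]
  )
}

#' Check cohort coverage for a cross-sectional (CAL) computation
#'
#' The cross-sectional average length of life at year \eqn{t} with top age
#' \eqn{\omega} needs, for every \eqn{x = 0..\omega}, the survival of the
#' cohort born in \eqn{t - x} up to age \eqn{x}: the triangle of Lexis cells
#' between the diagonal of the cohort born \eqn{t - \omega} and the period
#' column of year \eqn{t}. This reports which cohorts fall outside the
#' surface.
#'
#' @inheritParams period_column
#' @param omega Top age of the cross-sectional integral.
#' @return A tibble with one row per missing cohort (`cohort`, the birth
#'   year; `first_missing_year`, the first calendar year required but absent),
#'   with attribute `complete` (`TRUE` if no cohort is missing). Use
#'   [cal_covered()] for the bare logical.
#' @export
cal_coverage <- function(surface, year, omega) {
  check_surface(surface)
  if (!is_int_scalar(year) || !is_int_scalar(omega) || omega < 0) {
    abort("`year` and `omega` must be integers, omega >= 0.")
  }
  years <- surface_years(surface)
  ages <- surface_ages(surface)
  report <- tibble(cohort = integer(), first_missing_year = integer())
  if (year < years[1L] || year > years[length(years)]) {
    report <- tibble(
      cohort = as.integer(year - (omega:0)),
      first_missing_year = as.integer(year)
    )
  } else {
    if (omega > ages[length(ages)]) {
      abort(sprintf(
        "omega (%d) exceeds the surface top age (%d).",
        omega, ages[length(ages)]
      ))
    }
    cohorts <- year - (omega:0)
    missing <- cohorts < years[1L]
    report <- tibble(
      cohort = as.integer(cohorts[missing]),
      first_missing_year = as.integer(pmax(cohorts[missing], years[1L] - 1L))
    )
    # a missing cohort's first absent cell is its birth year
    report$first_missing_year <- report$cohort
  }
  structure(report, complete = nrow(report) == 0L)
}

#' @rdname cal_coverage
#' @return `cal_covered()`: `TRUE` iff every cohort required by
#'   `(year, omega)` lies fully on the surface.
#' @export
cal_covered <- function(surface, year, omega) {
  isTRUE(attr(cal_coverage(surface, year, omega), "complete"))
}
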
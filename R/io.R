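#' Read a Human Mortality Database style 1x1 death-rate file
#'
#' Parses the plain-text layout used for HMD `Mx_1x1` files: at least two
#' header lines (a title and a column header), then whitespace-separated
#' columns `Year Age Female Male Total`, ages `"0".."109"` plus the open age
#' class `"110+"` (mapped to the top age, whose rate is retained as the
#' terminal open-interval rate), and `"."` marking a missing cell. Missing
#' cells in the requested sex column are an error listing the offending
#' (year, age) pairs — the package never imputes.
#'
#' @param path Path to the rates file.
#' @param sex Which column to read: `"female"`, `"male"` or `"total"`.
#' @param population Population label for the resulting surface; defaults to
#'   the file's first header line.
#' @return A [mortality_surface][as_mortality_surface].
#' @export
read_hmd_rates <- function(path, sex = c("female", "male", "total"),
                           population = NULL) {
  sex <- match.arg(sex)
  lines <- readLines(path)
  is_header <- function(tokens) {
    length(tokens) >= 5L && tokens[1L] == "Year" && tokens[2L] == "Age"
  }
  tokens <- lapply(trimws(lines), function(l) strsplit(l, "\\s+")[[1L]])
  header_at <- which(vapply(tokens, is_header, logical(1)))
  if (length(header_at) == 0L || header_at[1L] < 2L) {
    abort(sprintf(
      "'%s' does not look like an HMD 1x1 rates file: no 'Year Age ...' header after a title line.",
      path
    ))
  }
  header_at <- header_at[1L]
  cols <- tokens[[header_at]]
  sex_col <- match(
    c(female = "Female", male = "Male", total = "Total")[[sex]], cols
  )
  if (is.na(sex_col)) {
    abort(sprintf("line %d: header lacks a '%s' column.", header_at, sex))
  }
  body <- tokens[seq_along(tokens) > header_at]
  body_lines <- which(seq_along(tokens) > header_at)
  keep <- lengths(body) > 0L
  body <- body[keep]
  body_lines <- body_lines[keep]
  bad_len <- lengths(body) < max(2L, sex_col)
  if (any(bad_len)) {
    abort(sprintf(
      "line %d: expected at least %d whitespace-separated fields, found %d.",
      body_lines[which(bad_len)[1L]], max(2L, sex_col),
      lengths(body)[which(bad_len)[1L]]
    ))
  }
  year_chr <- vapply(body, `[[`, character(1), 1L)
  age_chr <- vapply(body, `[[`, character(1), 2L)
  mx_chr <- vapply(body, `[[`, character(1), sex_col)
  year <- suppressWarnings(as.integer(year_chr))
  if (anyNA(year)) {
    abort(sprintf(
      "line %d: unparseable Year '%s'.",
      body_lines[which(is.na(year))[1L]], year_chr[which(is.na(year))[1L]]
    ))
  }
  open_age <- grepl("^[0-9]+\\+$", age_chr)
  age <- suppressWarnings(as.integer(sub("\\+$", "", age_chr)))
  if (anyNA(age)) {
    abort(sprintf(
      "line %d: unparseable Age '%s'.",
      body_lines[which(is.na(age))[1L]], age_chr[which(is.na(age))[1L]]
    ))
  }
  missing <- mx_chr == "."
  if (any(missing)) {
    cells <- sprintf("(%d, %s)", year[missing], age_chr[missing])
    abort(paste0(
      "missing rate cells (year, age) for sex '", sex, "': ",
      paste(head(cells, 10L), collapse = ", "),
      if (sum(missing) > 10L) sprintf(" and %d more", sum(missing) - 10L)
      else ""
    ))
  }
  mx <- suppressWarnings(as.numeric(mx_chr))
  if (anyNA(mx)) {
    abort(sprintf(
      "line %d: unparseable rate '%s'.",
      body_lines[which(is.na(mx))[1L]], mx_chr[which(is.na(mx))[1L]]
    ))
  }
  if (is.null(population)) {
    population <- trimws(lines[1L])
    if (!nzchar(population)) population <- "unnamed"
  }
  as_mortality_surface(
    tibble(year = year, age = age, mx = mx),
    population = population, sex = sex
  )
}

#' Write a mortality surface in the HMD 1x1 rates layout
#'
#' Emits a title line, a blank line, the `Year Age Female Male Total` header,
#' and one row per Lexis cell. The surface's own sex column carries the rates
#' at full double precision (so a write-read round trip is exact); the other
#' sex columns are written as the missing marker `"."`. The top age is
#' written as the open class `"<top>+"`.
#'
#' @param surface A [mortality_surface][as_mortality_surface].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_hmd_rates <- function(surface, path) {
  check_surface(surface)
  sex <- attr(surface, "sex")
  top <- max(surface$age)
  dat <- arrange(surface, .data$year, .data$age)
  age_chr <- ifelse(dat$age == top, paste0(top, "+"), format(dat$age))
  mx_chr <- formatC(dat$mx, digits = 17, format = "g")
  col <- function(s) if (identical(s, sex)) mx_chr else "."
  lines <- c(
    sprintf("%s, Death rates (period 1x1)", attr(surface, "population")),
    "",
    sprintf("%8s %6s %12s %12s %12s", "Year", "Age", "Female", "Male", "Total"),
    sprintf(
      "%8d %6s %12s %12s %12s",
      dat$year, age_chr, col("female"), col("male"), col("total")
    )
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read and write mortality surfaces as long CSV
#'
#' The CSV dialect is a long table with header `year,age,mx`, one row per
#' Lexis cell. Duplicated cells, negative rates, or an incomplete grid are
#' errors (validation is delegated to [as_mortality_surface()]).
#'
#' @param path Path to a CSV file with columns `year`, `age`, `mx`.
#' @param population,sex Passed to [as_mortality_surface()].
#' @return `read_surface_csv()`: a [mortality_surface][as_mortality_surface].
#' @export
read_surface_csv <- function(path, population = "unnamed", sex = "total") {
  dat <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  as_mortality_surface(dat, population = population, sex = sex)
}

#' @rdname read_surface_csv
#' @param surface A [mortality_surface][as_mortality_surface].
#' @return `write_surface_csv()`: `path`, invisibly.
#' @export
write_surface_csv <- function(surface, path) {
  check_surface(surface)
  readr::write_csv(tibble(year = surface$year, age = surface$age,
                          mx = surface$mx), path)
  invisible(path)
}

#' Write per-year cross-sectional results to CSV
#'
#' Columns `year, cal, cal_dagger, h_cal, n_cohorts`, one row per year.
#'
#' @param x A tibble from [cal_series()] (or [cal_entropy()] rows).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cal_series <- function(x, path) {
  cols <- c("year", "cal", "cal_dagger", "h_cal", "n_cohorts")
  if (!all(cols %in% names(x))) {
    abort("`x` must have columns year, cal, cal_dagger, h_cal, n_cohorts.")
  }
  readr::write_csv(as_tibble(x)[cols], path)
  invisible(path)
}

#' Write gap and gap-change decompositions to CSV
#'
#' Tabular counterparts of the decomposition bar charts: per-year
#' contributions of lifespan variation and longevity to the entropy gap, and
#' (for the change decomposition) the benchmark, variation and longevity
#' terms plus the reported residual.
#'
#' @param x A tibble from [decompose_gap()] or [decompose_gap_change()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gap_decomposition <- function(x, path) {
  readr::write_csv(as_tibble(x), path)
  invisible(path)
}

#' Write a computed period life table in HMD column layout
#'
#' Emits `Year Age mx qx ax lx dx Lx Tx ex` for one period column, with the
#' survival column scaled to radix 100000 on output only. Within-interval
#' survival is piecewise exponential (constant hazard), consistent with
#' [survival_from_hazard()]; the top age is treated as an open interval
#' closed by the terminal hazard.
#'
#' @inheritParams period_column
#' @param path Output path.
#' @return The life table tibble, invisibly.
#' @export
write_lifetable <- function(surface, year, path) {
  check_surface(surface)
  col <- period_column(surface, year)
  mx <- col$mx
  n <- length(mx)
  px <- exp(-mx)
  lx <- c(1, cumprod(px))[seq_len(n)]
  qx <- 1 - px
  dx <- lx * qx
  lx_next <- lx * px
  Lx <- ifelse(mx > 0, lx * (1 - px) / mx, lx)
  # open terminal interval: exponential tail at the last observed rate
  Lx[n] <- if (mx[n] > 0) lx[n] / mx[n] else lx[n]
  dx[n] <- lx[n]
  qx[n] <- 1
  ax <- ifelse(dx > 0, (Lx - lx_next) / dx, 0.5)
  ax[n] <- if (lx[n] > 0) Lx[n] / lx[n] else 0.5
  Tx <- rev(cumsum(rev(Lx)))
  ex <- ifelse(lx > 0, Tx / lx, 0)
  radix <- 1e5
  tab <- tibble(
    Year = as.integer(year), Age = col$age,
    mx = mx, qx = qx, ax = ax,
    lx = lx * radix, dx = dx * radix, Lx = Lx * radix, Tx = Tx * radix,
    ex = ex
  )
  header <- sprintf(
    "%6s %4s %9s %9s %6s %9s %9s %9s %10s %7s",
    "Year", "Age", "mx", "qx", "ax", "lx", "dx", "Lx", "Tx", "ex"
  )
  rows <- sprintf(
    "%6d %4d %9.5f %9.5f %6.2f %9.0f %9.0f %9.0f %10.0f %7.2f",
    tab$Year, tab$Age, tab$mx, tab$qx, tab$ax, tab$lx, tab$dx, tab$Lx,
    tab$Tx, tab$ex
  )
  writeLines(c(header, rows), path)
  invisible(tab)
}
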
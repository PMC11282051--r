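# Internal numerical helpers shared across modules.

# Trapezoidal rule on (x, y). Tolerates repeated x values (zero-width panels),
# which survival curves assembled from distinct cohorts use to represent
# left/right limits at integer ages.
trapz <- function(x, y) {
  n <- length(x)
  if (n < 2L) {
    return(0)
  }
  sum((y[-1L] + y[-n]) * diff(x)) / 2
}

# -l * log(l) with the analytic-limit convention 0*log(0) = 1*log(1) = 0.
xlogx_term <- function(lx) {
  out <- numeric(length(lx))
  inside <- lx > 0 & lx < 1
  out[inside] <- -lx[inside] * log(lx[inside])
  out
}

# Logarithmic mean of two positive numbers: (a - b) / log(a / b), with the
# arithmetic-mean limit when a and b are (numerically) equal.
log_mean <- function(a, b, tol = 1e-12) {
  d <- log(a) - log(b)
  ifelse(abs(d) > tol, (a - b) / d, (a + b) / 2)
}

# Centered rolling mean of width `window` (odd), shrinking at the edges;
# NA values are dropped from each window.
rolling_mean <- function(x, window) {
  stopifnot(window >= 1, window %% 2 == 1)
  half <- (window - 1L) %/% 2L
  n <- length(x)
  vapply(seq_len(n), function(i) {
    idx <- max(1L, i - half):min(n, i + half)
    v <- x[idx]
    v <- v[!is.na(v)]
    if (length(v) == 0L) NA_real_ else mean(v)
  }, numeric(1))
}

is_int_scalar <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x == round(x)
}
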
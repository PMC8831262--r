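#' @keywords internal
"_PACKAGE"

## Internal helpers shared across modules.

stop_input <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

assert_that <- function(cond, ...) {
  if (!isTRUE(cond)) stop_input(...)
  invisible(TRUE)
}

is_scalar_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}

#' Cycle-periodic trapezoidal mean
#'
#' Mean of a periodic signal sampled at `times` over one period of length
#' `period`, using the trapezoidal rule with the last interval wrapping back
#' to the first sample. `x` may be a vector (one signal) or a matrix with one
#' row per signal and one column per time sample.
#'
#' @param x numeric vector or matrix of samples.
#' @param times strictly increasing sample times, all within `[t0, t0 + period)`.
#' @param period cycle length, same units as `times`.
#' @return the periodic time average (vector of length `nrow(x)` for a matrix).
#' @keywords internal
periodic_trapz_mean <- function(x, times, period) {
  n <- length(times)
  assert_that(n >= 2L, "need at least 2 time samples")
  assert_that(all(diff(times) > 0), "times must be strictly increasing")
  span <- times[n] - times[1]
  assert_that(span < period + 1e-12, "times must span at most one period")
  # weight of sample i: half the sum of its adjacent interval lengths,
  # with the wrap interval closing the cycle from the last sample back to
  # the first one period later
  dt <- diff(times)
  wrap <- period - span
  w <- (c(wrap, dt) + c(dt, wrap))/2
  if (is.matrix(x)) {
    as.vector(x %*% w)/period
  } else {
    sum(x * w)/period
  }
}

## 3D vector helpers (row-wise on n x 3 matrices)

row_norms <- function(m) sqrt(rowSums(m * m))

normalize_rows <- function(m) {
  n <- row_norms(m)
  assert_that(all(n > 0), "cannot normalize zero-length vector")
  m/n
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

## Seed bookkeeping: derive reproducible sub-seeds that stay within 32-bit
## integer range regardless of the parent seed the caller supplies.
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 48271 + 1099 * as.numeric(k)) %% 2147483647)
}
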
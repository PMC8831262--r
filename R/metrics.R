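#' Time-resolved WSS vectors on a lumen surface
#'
#' Container for per-vertex wall shear stress vectors sampled over exactly
#' one cardiac cycle. `wss` is an array `[n_vertex, n_time, 3]` of vector
#' components in Pa; `times` are the sample times in seconds and `period`
#' the cycle length (the last sampling interval wraps periodically back to
#' the first sample).
#'
#' @param vertices numeric matrix `n x 3` of vertex coordinates, mm.
#' @param times strictly increasing sample times within one cycle, s.
#' @param wss numeric array `[n, n_time, 3]` of WSS vectors, Pa.
#' @param period cycle length, s; default assumes uniform sampling,
#'   `n_time * dt`.
#' @return an object of class `surface_wss_series`.
#' @export
surface_wss_series <- function(vertices, times, wss, period = NULL) {
  vertices <- as.matrix(vertices)
  assert_that(ncol(vertices) == 3, "vertices must be n x 3")
  nt <- length(times)
  assert_that(nt >= 4, "need at least 4 time samples")
  assert_that(all(diff(times) > 0), "times must be strictly increasing")
  assert_that(length(dim(wss)) == 3 &&
                dim(wss)[1] == nrow(vertices) &&
                dim(wss)[2] == nt && dim(wss)[3] == 3,
              "wss must be an [n_vertex, n_time, 3] array")
  assert_that(all(is.finite(wss)), "wss components must be finite")
  if (is.null(period)) {
    dt <- diff(times)
    assert_that(all(abs(dt - dt[1]) < 1e-9 * dt[1]),
                "period must be given for non-uniform sampling")
    period <- nt * dt[1]
  }
  assert_that(times[nt] - times[1] < period, "times must span < one period")
  structure(list(vertices = vertices, times = as.numeric(times),
                 wss = wss, period = period),
            class = "surface_wss_series")
}

#' Time-averaged wall shear stress per vertex
#'
#' TAWSS = (1/T) integral over the cycle of |tau_w(t)| dt, computed with the
#' periodic trapezoidal rule (the interval from the last sample wraps to the
#' first sample one period later).
#'
#' @param series a [surface_wss_series()].
#' @return numeric vector of TAWSS values in Pa, one per vertex.
#' @export
tawss <- function(series) {
  stopifnot(inherits(series, "surface_wss_series"))
  mag <- sqrt(series$wss[, , 1]^2 + series$wss[, , 2]^2 + series$wss[, , 3]^2)
  if (is.null(dim(mag))) mag <- matrix(mag, nrow = 1)
  periodic_trapz_mean(mag, series$times, series$period)
}

#' Oscillatory shear index per vertex
#'
#' OSI = 0.5 * (1 - |cycle integral of the WSS vector| / cycle integral of
#' its magnitude), in `[0, 0.5]`: 0 for purely unidirectional shear, 0.5 for
#' purely oscillatory shear with zero mean. Vertices whose shear magnitude
#' integrates to zero are assigned OSI 0 and flagged in the
#' `zero_shear` attribute.
#'
#' @param series a [surface_wss_series()].
#' @return numeric vector of OSI values with a logical `zero_shear` attribute.
#' @export
osi <- function(series) {
  stopifnot(inherits(series, "surface_wss_series"))
  tm <- series$times
  T <- series$period
  mean_vec <- sapply(1:3, function(k) {
    x <- series$wss[, , k]
    if (is.null(dim(x))) x <- matrix(x, nrow = 1)
    periodic_trapz_mean(x, tm, T)
  })
  if (is.null(dim(mean_vec))) mean_vec <- matrix(mean_vec, nrow = 1)
  num <- sqrt(rowSums(mean_vec^2))
  den <- tawss(series)
  zero <- den <= 0
  val <- ifelse(zero, 0, 0.5 * (1 - num/pmax(den, .Machine$double.xmin)))
  # clamp tiny negative excursions from floating-point cancellation
  val <- pmin(pmax(val, 0), 0.5)
  attr(val, "zero_shear") <- zero
  val
}

#' Bundle TAWSS and OSI with the mesh
#'
#' @param series a [surface_wss_series()].
#' @return an object of class `metric_map` with fields `vertices`, `tawss`,
#'   `osi`, `zero_shear`.
#' @export
metric_map <- function(series) {
  stopifnot(inherits(series, "surface_wss_series"))
  ta <- tawss(series)
  os <- osi(series)
  assert_that(all(ta >= 0), "TAWSS must be non-negative")
  structure(list(vertices = series$vertices, tawss = as.numeric(ta),
                 osi = as.numeric(os),
                 zero_shear = attr(os, "zero_shear")),
            class = "metric_map")
}
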
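# Shared fixture builders. Everything is generated in code; no files.

# series with a single vertex following a closed-form vector signal
one_vertex_series <- function(f, n_time = 256, period = 1) {
  tt <- (seq_len(n_time) - 1) * period/n_time
  wss <- array(0, dim = c(1, n_time, 3))
  for (i in seq_len(n_time)) wss[1, i, ] <- f(tt[i])
  surface_wss_series(matrix(0, 1, 3), tt, wss, period = period)
}

# independent quadrature oracle: midpoint rule on the piecewise-linear
# periodic interpolant of a sampled non-negative signal (exact for the
# interpolant, so it independently reproduces what periodic trapezoid claims)
pl_periodic_mean <- function(samples, times, period, subdiv = 256) {
  n <- length(times)
  ts <- c(times, times[1] + period)
  xs <- c(samples, samples[1])
  total <- 0
  for (i in seq_len(n)) {
    h <- (ts[i + 1] - ts[i])/subdiv
    mid <- ts[i] + (seq_len(subdiv) - 0.5) * h
    w <- stats::approx(ts[i:(i + 1)], xs[i:(i + 1)], xout = mid)$y
    total <- total + sum(w) * h
  }
  total/period
}

# circle contour (closed polygon, first point not repeated)
circle_contour <- function(radius, n = 180, center = c(0, 0)) {
  phi <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  cbind(center[1] + radius * cos(phi), center[2] + radius * sin(phi))
}

# phantom mask: circular lumen + intima annulus, with an annular NC band at
# a given cap distance behind the lumen over selected sectors
phantom_mask <- function(lumen_radius = 3, cap = 1, nc_width = 0.6,
                         wall = 2.5, pixel = 0.05, nc_sectors = 0:7,
                         aref = c(1, 0)) {
  outer_r <- lumen_radius + wall
  half <- outer_r + 0.3
  n <- 2L * ceiling(half/pixel) + 1L
  origin <- rep(-(n - 1)/2 * pixel, 2)
  xs <- origin[1] + (seq_len(n) - 1) * pixel
  X <- matrix(rep(xs, each = n), n, n)
  Y <- matrix(rep(xs, n), n, n)
  r <- sqrt(X^2 + Y^2)
  e2 <- c(-aref[2], aref[1])
  th <- atan2(X * e2[1] + Y * e2[2], X * aref[1] + Y * aref[2]) %% (2 * pi)
  sec <- pmin(floor(th/(pi/4)), 7)
  cc <- mask_class_codes()
  px <- matrix(cc[["background"]], n, n)
  px[r > lumen_radius & r <= outer_r] <- cc[["intima"]]
  nc_zone <- r >= lumen_radius + cap & r <= lumen_radius + cap + nc_width &
    matrix(sec %in% nc_sectors, n)
  px[nc_zone & px == cc[["intima"]]] <- cc[["nc"]]
  section_label_mask(px, pixel, center = c(0, 0), angular_reference = aref,
                     lumen_contour = circle_contour(lumen_radius),
                     origin = origin)
}

# minimal bin-record table for statistics tests, outcomes drawn directly
# from the tertile effect model
simulated_records <- function(n_patients, bins_per_patient, effects,
                              seed, tawss_scale_range = c(0.6, 1.8)) {
  set.seed(seed)
  rows <- list()
  intercepts <- sapply(effects, function(e)
    stats::rnorm(n_patients, 0, e$patient_sd))
  intercepts <- matrix(intercepts, nrow = n_patients,
                       dimnames = list(NULL, names(effects)))
  for (p in seq_len(n_patients)) {
    s <- stats::runif(1, tawss_scale_range[1], tawss_scale_range[2])
    tawss <- s * stats::rlnorm(bins_per_patient, 0, 0.7)
    osi <- 0.5 * stats::rbeta(bins_per_patient, 1, 6)
    d <- data.frame(patient_id = sprintf("P%02d", p),
                    section_id = sprintf("P%02d_S%02d", p,
                                         seq_len(bins_per_patient)),
                    bin_index = 0L,
                    tawss_mean = tawss, osi_mean = osi,
                    included = TRUE, exclusion_reason = "")
    d$tawss_tertile <- patient_tertiles(tawss)$labels
    d$osi_tertile <- patient_tertiles(osi)$labels
    out <- shearplaque:::simulate_bin_outcomes(
      d, effects, as.list(intercepts[p, ]))
    d$nc_area_mm2 <- out$nc
    d$fibrin_area_mm2 <- out$fibrin %||% NULL
    d$macrophage_area_mm2 <- out$macrophage %||% NULL
    d$cap_thickness_mm <- out$cap %||% NULL
    rows[[p]] <- d
  }
  do.call(rbind, rows)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
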
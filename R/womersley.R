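## Womersley pulsatile flow in a rigid straight tube.
##
## For each harmonic of the flow waveform, the axial velocity profile and
## wall shear follow the classical oscillatory-pipe-flow solution in terms
## of Bessel functions J0, J1 evaluated at the complex argument
## beta = i^{3/2} * alpha, with Womersley number alpha = R * sqrt(omega*rho/mu).
## Written in flow-rate form: given the complex flow amplitude Q_n, the
## velocity harmonic is
##   u_n(r) = Q_n/(pi R^2) * (1 - J0(beta r/R)/J0(beta)) / (1 - F),
##   F = 2 J1(beta) / (beta J0(beta)),
## which integrates to Q_n exactly, and the (signed, flow-direction-positive)
## wall shear harmonic is
##   tau_n = -mu * du_n/dr |_{r=R} = -(mu Q_n / (pi R^3)) * (beta^2/2) F/(1-F).
## The steady harmonic is plain Poiseuille: tau_0 = 4 mu Q_0/(pi R^3).

# J0 and J1 at complex argument via their ascending power series. On the
# Womersley ray arg(z) = 3*pi/4 cancellation is mild (the result grows like
# exp(|Im z|)); the alpha <= 50 guard keeps the loss below ~7 digits.
bessel_j01_complex <- function(z) {
  zz <- -(z * z)/4   # series in (-z^2/4)
  term0 <- rep(1 + 0i, length(z))
  term1 <- rep(1 + 0i, length(z))
  j0 <- term0
  j1s <- term1       # J1(z) = (z/2) * j1s
  for (k in 1:200) {
    term0 <- term0 * zz/(k * k)
    term1 <- term1 * zz/(k * (k + 1))
    j0 <- j0 + term0
    j1s <- j1s + term1
    if (max(Mod(term0), Mod(term1)) < 1e-17 * max(Mod(j0), Mod(j1s))) break
  }
  list(j0 = j0, j1 = (z/2) * j1s)
}

#' Womersley pulsatile velocity profile and wall shear
#'
#' Solves oscillatory laminar flow in a rigid straight tube of radius
#' `radius` driven by the harmonics of `waveform`, returning the axial
#' velocity profile on a radial grid and the signed axial wall shear series
#' over one cycle. The solution is Newtonian with viscosity `fluid$mu_ref`.
#' The steady harmonic contributes the Poiseuille wall shear
#' \eqn{4\mu Q_0/(\pi R^3)}; each oscillatory harmonic uses the complex
#' Bessel-function solution at \eqn{i^{3/2}\alpha_n},
#' \eqn{\alpha_n = R\sqrt{\omega_n\rho/\mu}}.
#'
#' @param waveform a [flow_waveform()] (ml/s).
#' @param radius tube radius in mm.
#' @param fluid a [fluid_properties()]; `mu_ref` and `density` are used.
#' @param n_time number of uniformly spaced output times over one cycle.
#' @param n_harmonics number of waveform harmonics retained (default 8).
#' @param n_radial number of radial grid points from 0 to R inclusive
#'   (odd values allow Simpson quadrature of the flow integral).
#' @return an object of class `womersley_result` with fields `times` (s),
#'   `wall_shear_series` (Pa, signed, positive in the mean-flow direction),
#'   `alpha` (Womersley number per retained harmonic), `r` (radial grid, mm),
#'   `velocity_profile` (m/s matrix, `n_radial` x `n_time`), `radius`,
#'   `waveform`, `n_harmonics`.
#' @examples
#' wf <- flow_waveform(rep(5, 16), period = 1)   # steady 5 ml/s
#' w <- womersley_wall_shear(wf, radius = 3)
#' mean(w$wall_shear_series)                     # 4 mu Q / (pi R^3)
#' @export
womersley_wall_shear <- function(waveform, radius, fluid = fluid_properties(),
                                 n_time = 64, n_harmonics = 8,
                                 n_radial = 129) {
  stopifnot(inherits(waveform, "flow_waveform"))
  if (!is_scalar_number(radius) || radius <= 0) {
    stop_input("radius must be a positive number (mm)")
  }
  assert_that(n_time >= 8, "n_time must be >= 8")
  R <- radius * 1e-3                       # m
  mu <- fluid$mu_ref
  rho <- fluid$density
  T <- waveform$period
  nh <- min(n_harmonics, length(waveform$harmonics))
  times <- (seq_len(n_time) - 1) * T/n_time
  r <- seq(0, R, length.out = n_radial)

  Q0 <- waveform$mean_flow * 1e-6          # m^3/s
  tau <- rep(4 * mu * Q0/(pi * R^3), n_time)
  u <- matrix(rep(2 * Q0/(pi * R^2) * (1 - (r/R)^2), n_time),
              nrow = n_radial)

  alpha <- numeric(0)
  if (nh >= 1) {
    nvec <- seq_len(nh)
    omega <- 2 * pi * nvec/T
    alpha <- R * sqrt(omega * rho/mu)
    if (any(alpha > 50)) {
      stop_input("Womersley number %.1f exceeds 50: Bessel series guard",
                 max(alpha))
    }
    for (n in nvec) {
      beta <- complex(modulus = 1, argument = 3 * pi/4) * alpha[n]
      bw <- bessel_j01_complex(beta)
      F <- 2 * bw$j1/(beta * bw$j0)
      Qn <- waveform$harmonics[n] * 1e-6
      phase <- exp(1i * omega[n] * times)
      tau_n <- -(mu * Qn/(pi * R^3)) * (beta^2/2) * F/(1 - F)
      tau <- tau + Re(tau_n * phase)
      prof <- bessel_j01_complex(beta * r/R)$j0/bw$j0
      u_n <- (Qn/(pi * R^2)) * (1 - prof)/(1 - F)
      u <- u + Re(outer(u_n, phase))
    }
  }
  structure(list(times = times, wall_shear_series = tau, alpha = alpha,
                 r = r * 1e3, velocity_profile = u, radius = radius,
                 waveform = waveform, n_harmonics = nh),
            class = "womersley_result")
}

#' Cycle-averaged wall shear magnitude of a Womersley solution
#' @param w a `womersley_result`.
#' @return TAWSS in Pa (mean of `|wall_shear_series|` over the cycle).
#' @export
womersley_tawss <- function(w) {
  stopifnot(inherits(w, "womersley_result"))
  # uniform sampling over a full period: the periodic trapezoid is the mean
  mean(abs(w$wall_shear_series))
}

#' Scale a waveform to a target time-averaged wall shear stress
#'
#' Finds the multiplicative factor on the flow waveform such that the
#' cycle-averaged wall shear magnitude of the Womersley solution in a
#' straight tube of radius `cca_radius` equals `target_tawss` (default
#' 0.9 Pa, the common-carotid setpoint). Because the wall shear is linear in
#' the flow and TAWSS is positively homogeneous, the factor is
#' `target / TAWSS(waveform)`; the result is verified by recomputation and a
#' bracketing root-finder is used as fallback should the direct factor miss
#' the 1e-3 Pa tolerance.
#'
#' @param waveform a `flow_waveform` with nonzero TAWSS.
#' @param cca_radius common-carotid radius in mm.
#' @param fluid a [fluid_properties()].
#' @param target_tawss target cycle-averaged wall shear magnitude, Pa.
#' @param n_time,n_harmonics passed to [womersley_wall_shear()].
#' @return list with `waveform` (scaled), `factor`, and `achieved_tawss`.
#' @export
scale_waveform_to_target_wss <- function(waveform, cca_radius,
                                         fluid = fluid_properties(),
                                         target_tawss = 0.9,
                                         n_time = 64, n_harmonics = 8) {
  stopifnot(inherits(waveform, "flow_waveform"))
  assert_that(is_scalar_number(target_tawss) && target_tawss > 0,
              "target_tawss must be > 0")
  tawss_of <- function(s) {
    womersley_tawss(womersley_wall_shear(scale_waveform(waveform, s),
                                         cca_radius, fluid,
                                         n_time = n_time,
                                         n_harmonics = n_harmonics))
  }
  base <- tawss_of(1)
  if (!is.finite(base) || base <= 0) {
    stop_input("waveform has zero time-averaged wall shear; cannot scale")
  }
  factor <- target_tawss/base
  achieved <- tawss_of(factor)
  if (abs(achieved - target_tawss) > 1e-3) {
    root <- stats::uniroot(function(s) tawss_of(s) - target_tawss,
                           interval = c(factor/4, factor * 4),
                           tol = 1e-10)
    factor <- root$root
    achieved <- tawss_of(factor)
  }
  list(waveform = scale_waveform(waveform, factor), factor = factor,
       achieved_tawss = achieved)
}

#' Outflow split between internal and external carotid artery
#'
#' Maps the ICA stenosis degree to the fraction of the common-carotid flow
#' leaving through the ICA versus the ECA. The exact clinical mapping is not
#' standardized; the default is a monotone table giving the literature-typical
#' 64/36 ICA/ECA split below 50% stenosis and linearly decreasing ICA flow
#' down to zero at total occlusion. Any monotone table
#' (`data.frame(degree, ica_fraction)`) may be supplied.
#'
#' @param stenosis_degree_ica ICA stenosis degree, in `[0, 1]`.
#' @param split_table data.frame with columns `degree` and `ica_fraction`
#'   (non-increasing in degree); linearly interpolated.
#' @return list with `ica_fraction` and `eca_fraction` (summing to 1).
#' @export
split_outflow <- function(stenosis_degree_ica,
                          split_table = default_split_table()) {
  assert_that(is.numeric(stenosis_degree_ica) &&
                all(is.finite(stenosis_degree_ica)),
              "stenosis degree must be finite numeric")
  if (any(stenosis_degree_ica < 0 | stenosis_degree_ica > 1)) {
    stop_input("stenosis degree must lie in [0, 1]")
  }
  assert_that(all(c("degree", "ica_fraction") %in% names(split_table)),
              "split_table needs columns degree, ica_fraction")
  assert_that(all(diff(split_table$ica_fraction) <= 0),
              "ica_fraction must be non-increasing in degree")
  f <- stats::approx(split_table$degree, split_table$ica_fraction,
                     xout = stenosis_degree_ica, rule = 2)$y
  list(ica_fraction = f, eca_fraction = 1 - f)
}

#' @rdname split_outflow
#' @export
default_split_table <- function() {
  data.frame(degree = c(0, 0.5, 1), ica_fraction = c(0.64, 0.64, 0))
}
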
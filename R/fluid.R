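#' Blood fluid properties
#'
#' Container for the fluid constants used by the boundary-condition layer:
#' density, the Carreau-Yasuda shear-thinning parameters, and a Newtonian
#' reference viscosity used by the analytic Womersley formulas (which are
#' only defined for Newtonian flow).
#'
#' The Carreau-Yasuda defaults are literature-typical values for whole blood;
#' they are configuration, not measured constants, and can be overridden per
#' study. Density defaults to 1060 kg/m3.
#'
#' @param density blood density in kg/m3.
#' @param cy_mu0 zero-shear viscosity mu_0, Pa s.
#' @param cy_muinf infinite-shear viscosity mu_inf, Pa s (must be <= `cy_mu0`).
#' @param cy_lambda relaxation time lambda, s.
#' @param cy_a Yasuda transition exponent a (dimensionless).
#' @param cy_n power-law index n (dimensionless; shear-thinning for n < 1).
#' @param mu_ref Newtonian reference viscosity for analytic formulas, Pa s.
#' @return an object of class `fluid_properties`.
#' @examples
#' fl <- fluid_properties()
#' carreau_yasuda_viscosity(100, fl)
#' @export
fluid_properties <- function(density = 1060,
                             cy_mu0 = 0.022,
                             cy_muinf = 0.0022,
                             cy_lambda = 0.11,
                             cy_a = 0.644,
                             cy_n = 0.392,
                             mu_ref = 0.0035) {
  assert_that(is_scalar_number(density) && density > 0, "density must be > 0")
  assert_that(is_scalar_number(cy_mu0) && cy_mu0 > 0, "cy_mu0 must be > 0")
  assert_that(is_scalar_number(cy_muinf) && cy_muinf > 0, "cy_muinf must be > 0")
  assert_that(cy_muinf <= cy_mu0, "cy_muinf must not exceed cy_mu0")
  assert_that(is_scalar_number(cy_lambda) && cy_lambda >= 0, "cy_lambda must be >= 0")
  assert_that(is_scalar_number(cy_a) && cy_a > 0, "cy_a must be > 0")
  assert_that(is_scalar_number(cy_n), "cy_n must be a finite number")
  assert_that(is_scalar_number(mu_ref) && mu_ref > 0, "mu_ref must be > 0")
  structure(list(density = density, cy_mu0 = cy_mu0, cy_muinf = cy_muinf,
                 cy_lambda = cy_lambda, cy_a = cy_a, cy_n = cy_n,
                 mu_ref = mu_ref),
            class = "fluid_properties")
}

#' Carreau-Yasuda viscosity
#'
#' Shear-thinning apparent viscosity
#' \deqn{\mu(\dot\gamma) = \mu_\infty + (\mu_0 - \mu_\infty)
#'   \left[1 + (\lambda\dot\gamma)^a\right]^{(n-1)/a}}
#' interpolating between the zero-shear plateau `mu_0` and the infinite-shear
#' plateau `mu_inf`.
#'
#' @param shear_rate scalar or vector of shear rates, 1/s, all >= 0.
#' @param fluid a [fluid_properties()] object.
#' @return apparent viscosity in Pa s, same length as `shear_rate`.
#' @export
carreau_yasuda_viscosity <- function(shear_rate, fluid = fluid_properties()) {
  stopifnot(inherits(fluid, "fluid_properties"))
  assert_that(is.numeric(shear_rate) && all(is.finite(shear_rate)),
              "shear_rate must be finite numeric")
  if (any(shear_rate < 0)) stop_input("shear_rate must be >= 0")
  with(fluid, {
    cy_muinf + (cy_mu0 - cy_muinf) *
      (1 + (cy_lambda * shear_rate)^cy_a)^((cy_n - 1)/cy_a)
  })
}
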
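#' Physical properties of the two blood phases
#'
#' Bundles the densities and viscosities of the pure phases together with the
#' RBC size that enters the interphase force scales. Defaults are the standard
#' microvessel values: plasma density 1027 kg/m^3, plasma viscosity 0.96 cP,
#' RBC density 1093 kg/m^3 and RBC size a = 8 um.
#'
#' @param plasma_density Plasma mass density, kg/m^3.
#' @param plasma_viscosity Plasma dynamic viscosity, Pa s (0.96 cP = 0.96e-3).
#' @param rbc_density RBC phase mass density, kg/m^3.
#' @param rbc_size_a RBC size entering the drag and lift scales, m.
#' @return An object of class `fluid_properties`.
#' @examples
#' fluid_properties()
#' @export
fluid_properties <- function(plasma_density = 1027,
                             plasma_viscosity = 0.96e-3,
                             rbc_density = 1093,
                             rbc_size_a = 8e-6) {
  vals <- c(plasma_density, plasma_viscosity, rbc_density, rbc_size_a)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all fluid properties must be finite and strictly positive")
  }
  structure(
    list(
      plasma_density = plasma_density,
      plasma_viscosity = plasma_viscosity,
      rbc_density = rbc_density,
      rbc_size_a = rbc_size_a
    ),
    class = "fluid_properties"
  )
}

#' @export
print.fluid_properties <- function(x, ...) {
  cat("<fluid_properties>\n")
  cat(sprintf("  plasma: rho = %g kg/m^3, mu = %g Pa.s\n",
              x$plasma_density, x$plasma_viscosity))
  cat(sprintf("  RBC:    rho = %g kg/m^3, a = %g m\n",
              x$rbc_density, x$rbc_size_a))
  invisible(x)
}

#' Coefficients of the RBC-phase viscosity law
#'
#' The RBC continuum is shear-thinning with hematocrit-dependent zero-shear and
#' infinite-shear viscosities given by quadratic polynomials in the volume
#' fraction phi (fitted to whole-blood viscometry), and a relaxation time
#' constant k that sets the shear-rate scale of the thinning:
#' mu0 = 537.002 phi^2 + 55.006 phi - 0.129 (cP),
#' mu_inf = 27.873 phi^2 - 21.218 phi + 14.439 (cP), k = 11 s.
#' Polynomial outputs are interpreted as centipoise and converted to Pa s by
#' `output_unit_scale`.
#'
#' @param mu0_poly Coefficients (quadratic, linear, constant) of the zero-shear
#'   viscosity polynomial, cP.
#' @param muinf_poly Coefficients of the infinite-shear viscosity polynomial, cP.
#' @param k_time_const Shear-thinning time constant, s.
#' @param output_unit_scale Conversion factor from the polynomial unit (cP) to
#'   Pa s.
#' @param mu_floor Minimum viscosity returned by the floored evaluators, Pa s.
#'   The zero-shear polynomial is negative for phi < ~0.0023, so all floored
#'   viscosities are clipped from below; default one tenth of the plasma
#'   viscosity. The model is recommended for phi in [0.05, 0.6].
#' @param lambda_r Second (bulk-type) viscosity coefficient of the RBC phase,
#'   Pa s; it multiplies tr(Dr) in the RBC stress and defaults to 0.
#' @return An object of class `rheology_coefficients`.
#' @examples
#' rheology_coefficients()
#' @export
rheology_coefficients <- function(mu0_poly = c(537.002, 55.006, -0.129),
                                  muinf_poly = c(27.873, -21.218, 14.439),
                                  k_time_const = 11,
                                  output_unit_scale = 1e-3,
                                  mu_floor = 0.96e-4,
                                  lambda_r = 0) {
  stopifnot(length(mu0_poly) == 3, length(muinf_poly) == 3,
            is.finite(k_time_const), k_time_const > 0,
            is.finite(output_unit_scale), output_unit_scale > 0,
            is.finite(mu_floor), mu_floor > 0)
  structure(
    list(
      mu0_poly = as.numeric(mu0_poly),
      muinf_poly = as.numeric(muinf_poly),
      k_time_const = k_time_const,
      output_unit_scale = output_unit_scale,
      mu_floor = mu_floor,
      lambda_r = lambda_r
    ),
    class = "rheology_coefficients"
  )
}

#' @export
print.rheology_coefficients <- function(x, ...) {
  cat("<rheology_coefficients>\n")
  cat(sprintf("  mu0   = %g phi^2 + %g phi + %g  (cP)\n",
              x$mu0_poly[1], x$mu0_poly[2], x$mu0_poly[3]))
  cat(sprintf("  muinf = %g phi^2 + %g phi + %g  (cP)\n",
              x$muinf_poly[1], x$muinf_poly[2], x$muinf_poly[3]))
  cat(sprintf("  k = %g s, unit scale = %g, floor = %g Pa.s, lambda_r = %g\n",
              x$k_time_const, x$output_unit_scale, x$mu_floor, x$lambda_r))
  invisible(x)
}

#' Interphase interaction force parameters
#'
#' Coefficients and switches for the three interphase momentum-exchange terms:
#' Stokes drag with the hindrance function f(phi) = phi (1 + 6.55 phi),
#' Saffman shear-lift (coefficient 6.46) and spin-lift (coefficient 3/4).
#' The Saffman term carries a shear-rate floor that regularizes its
#' 1/sqrt(shear rate) singularity in quiescent fluid.
#'
#' @param saffman_coeff Dimensionless Saffman lift coefficient.
#' @param spin_coeff Dimensionless spin-lift coefficient.
#' @param shear_floor Shear-rate floor used in the Saffman prefactor, 1/s.
#' @param drag,saffman,spin Logical switches for the individual force terms.
#' @param gravity Gravitational acceleration vector (x, y), m/s^2, applied as
#'   a uniform body force to both phases; `c(0, 0)` disables it. The
#'   sudden-expansion validation case uses `c(0, -9.81)` (transverse gravity,
#'   horizontal channel).
#' @return An object of class `interaction_params`.
#' @examples
#' interaction_params(spin = FALSE)
#' @export
interaction_params <- function(saffman_coeff = 6.46,
                               spin_coeff = 3 / 4,
                               shear_floor = 1e-3,
                               drag = TRUE,
                               saffman = TRUE,
                               spin = TRUE,
                               gravity = c(0, 0)) {
  stopifnot(saffman_coeff > 0, spin_coeff > 0, shear_floor > 0,
            is.logical(drag), is.logical(saffman), is.logical(spin),
            length(gravity) == 2, all(is.finite(gravity)))
  structure(
    list(
      saffman_coeff = saffman_coeff,
      spin_coeff = spin_coeff,
      shear_floor = shear_floor,
      drag = drag,
      saffman = saffman,
      spin = spin,
      gravity = as.numeric(gravity)
    ),
    class = "interaction_params"
  )
}

#' @export
print.interaction_params <- function(x, ...) {
  cat("<interaction_params>\n")
  cat(sprintf("  drag: %s  saffman: %s (C=%g, floor=%g/s)  spin: %s (C=%g)\n",
              x$drag, x$saffman, x$saffman_coeff, x$shear_floor,
              x$spin, x$spin_coeff))
  cat(sprintf("  gravity = (%g, %g) m/s^2\n", x$gravity[1], x$gravity[2]))
  invisible(x)
}
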
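#' Zero-shear and infinite-shear RBC viscosities
#'
#' Quadratic polynomial fits in the RBC volume fraction phi, evaluated in cP
#' and converted to Pa s. `mu_zero` is the zero-shear-rate limit viscosity
#' mu0(phi) = 537.002 phi^2 + 55.006 phi - 0.129 (cP); `mu_inf` is the
#' high-shear limit mu_inf(phi) = 27.873 phi^2 - 21.218 phi + 14.439 (cP).
#' Because the mu0 polynomial crosses zero near phi = 0.0023, the returned
#' value is floored at `coeffs$mu_floor` unless `raw = TRUE`, which returns the
#' unfloored polynomial (still in Pa s) for testing and diagnostics.
#'
#' @param phi RBC volume fraction(s) in [0, 1].
#' @param coeffs A [rheology_coefficients] object.
#' @param raw If `TRUE`, skip the viscosity floor.
#' @return Viscosity in Pa s, vectorized over `phi`.
#' @examples
#' mu_zero(0.45)           # 0.133367 Pa.s
#' mu_zero(0, raw = TRUE)  # negative: raw polynomial constant term
#' @export
mu_zero <- function(phi, coeffs = rheology_coefficients(), raw = FALSE) {
  check_phi(phi)
  v <- polyval2(coeffs$mu0_poly, phi) * coeffs$output_unit_scale
  if (raw) v else pmax(v, coeffs$mu_floor)
}

#' @rdname mu_zero
#' @export
mu_inf <- function(phi, coeffs = rheology_coefficients(), raw = FALSE) {
  check_phi(phi)
  v <- polyval2(coeffs$muinf_poly, phi) * coeffs$output_unit_scale
  if (raw) v else pmax(v, coeffs$mu_floor)
}

polyval2 <- function(p, x) p[1] * x^2 + p[2] * x + p[3]

check_phi <- function(phi) {
  if (any(!is.finite(phi)) || any(phi < 0) || any(phi > 1)) {
    stop("phi must lie in [0, 1]")
  }
  invisible(phi)
}

#' Generalized shear rate of a strain-rate field
#'
#' The scalar invariant `sqrt(2 tr(D^2))` of a symmetric strain-rate tensor
#' field, the shear-rate measure driving the shear-thinning RBC viscosity. In
#' axisymmetric mode the hoop component enters the trace.
#'
#' @param D A symmetric [tensor_field] (strain rate, 1/s).
#' @return Non-negative shear rate per cell, 1/s.
#' @examples
#' # simple shear du/dy = 10/s: D off-diagonals are 5
#' generalized_shear_rate(tensor_field(xx = 0, xy = 5, yy = 0))  # 10
#' @export
generalized_shear_rate <- function(D) {
  trD2 <- D$xx^2 + D$yy^2 + D$tt^2 + D$xy * D$yx + D$yx * D$xy
  sqrt(pmax(2 * trD2, 0))
}

#' Shear-thinning RBC-phase viscosity
#'
#' Evaluates the hematocrit-dependent generalized-Newtonian viscosity of the
#' RBC continuum,
#' \deqn{\mu_r = \tfrac12\Big[\mu_\infty + (\mu_0-\mu_\infty)
#'   \frac{1+\ln(1+k\dot\gamma)}{1+k\dot\gamma}\Big](1+\phi),}
#' which decays monotonically from \eqn{\tfrac12\mu_0(1+\phi)} at zero shear to
#' \eqn{\tfrac12\mu_\infty(1+\phi)} at infinite shear. The result is floored at
#' `coeffs$mu_floor` unless `raw = TRUE`.
#'
#' @param phi RBC volume fraction(s) in [0, 1].
#' @param gamma_dot Generalized shear rate(s), 1/s, non-negative.
#' @param coeffs A [rheology_coefficients] object.
#' @param raw If `TRUE`, skip the viscosity floor.
#' @return Viscosity in Pa s, vectorized.
#' @examples
#' rbc_viscosity(0.45, 0)    # = 0.5 * mu0(0.45) * 1.45
#' rbc_viscosity(0.45, 10)   # 0.0122186 Pa.s
#' @export
rbc_viscosity <- function(phi, gamma_dot, coeffs = rheology_coefficients(),
                          raw = FALSE) {
  check_phi(phi)
  if (any(!is.finite(gamma_dot)) || any(gamma_dot < 0)) {
    stop("gamma_dot must be non-negative")
  }
  m0 <- mu_zero(phi, coeffs, raw = TRUE)
  mi <- mu_inf(phi, coeffs, raw = TRUE)
  x <- coeffs$k_time_const * gamma_dot
  thin <- (1 + log1p(x)) / (1 + x)
  v <- 0.5 * (mi + (m0 - mi) * thin) * (1 + phi)
  if (raw) v else pmax(v, coeffs$mu_floor)
}

#' Phase Cauchy stress tensors
#'
#' `plasma_stress` evaluates the Newtonian plasma-phase stress
#' `Tp = -p (1-phi) I + 2 mu_p (1-phi) Dp` (the bulk term drops out because
#' tr(Dp) = 0 for the incompressible plasma); `rbc_stress` evaluates the
#' RBC-phase stress `Tr = [-p phi + lambda_r phi tr(Dr)] I + 2 mu_r phi Dr`
#' with the shear-thinning viscosity [rbc_viscosity] evaluated at the
#' generalized shear rate of `Dr` (`lambda_r` defaults to 0 in
#' [rheology_coefficients]).
#'
#' @param p Pressure per cell, Pa.
#' @param phi RBC volume fraction per cell.
#' @param Dp,Dr Symmetric strain-rate [tensor_field]s of the respective phase.
#' @param props A [fluid_properties] object.
#' @param coeffs A [rheology_coefficients] object.
#' @param viscous_only If `TRUE`, return only the deviatoric viscous part
#'   (pressure removed) — this is the part that enters the wall traction.
#' @return A [tensor_field] of stresses, Pa.
#' @export
plasma_stress <- function(p, phi, Dp, props = fluid_properties(),
                          viscous_only = FALSE) {
  check_phi(phi)
  a <- 1 - phi
  visc <- 2 * props$plasma_viscosity * a
  iso <- if (viscous_only) 0 else -p * a
  tensor_field(
    xx = iso + visc * Dp$xx,
    xy = visc * Dp$xy,
    yy = iso + visc * Dp$yy,
    yx = visc * Dp$yx,
    tt = iso + visc * Dp$tt
  )
}

#' @rdname plasma_stress
#' @export
rbc_stress <- function(p, phi, Dr, coeffs = rheology_coefficients(),
                       viscous_only = FALSE) {
  check_phi(phi)
  gd <- generalized_shear_rate(Dr)
  mur <- rbc_viscosity(phi, gd, coeffs)
  visc <- 2 * mur * phi
  trDr <- Dr$xx + Dr$yy + Dr$tt
  iso <- coeffs$lambda_r * phi * trDr
  if (!viscous_only) iso <- iso - p * phi
  tensor_field(
    xx = iso + visc * Dr$xx,
    xy = visc * Dr$xy,
    yy = iso + visc * Dr$yy,
    yx = visc * Dr$yx,
    tt = iso + visc * Dr$tt
  )
}
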
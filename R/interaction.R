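#' Hindrance function for the interphase drag
#'
#' Concentration correction `f(phi) = phi (1 + 6.55 phi)` multiplying the
#' dilute Stokes drag to account for neighbouring cells.
#'
#' @param phi RBC volume fraction(s) in [0, 1].
#' @return Dimensionless hindrance value(s), >= 0.
#' @examples
#' hindrance(0.2)  # 0.462
#' @export
hindrance <- function(phi) {
  check_phi(phi)
  phi * (1 + 6.55 * phi)
}

#' Interphase momentum-exchange forces
#'
#' The three interaction force densities (N/m^3) exchanged between the plasma
#' and RBC continua, evaluated cell-wise:
#' \itemize{
#'   \item `drag_force`: hindered Stokes drag
#'     `9 mu_p / (2 a^2) f(phi) (vr - vp)`;
#'   \item `saffman_lift`: shear lift
#'     `(3 * 6.46 / (4 pi a)) sqrt(rho_p mu_p) phi [2 tr(Dp^2)]^(-1/4) Dp (vr - vp)`,
#'     with the shear rate floored at `params$shear_floor` to regularize the
#'     quiescent-fluid singularity;
#'   \item `spin_lift`: `(3/4) rho_p phi (Wr - Wp) (vr - vp)`, perpendicular
#'     to the slip in 2D since `Wr - Wp` is antisymmetric.
#' }
#' All terms depend on the velocities only through the slip `vr - vp`
#' (Galilean invariant). The sign convention follows the phase momentum
#' balances: the returned force is added to the plasma momentum equation and
#' subtracted from the RBC one.
#'
#' @param phi RBC volume fraction per cell.
#' @param vp,vr Phase velocities, n x 2 matrices, m/s.
#' @param Dp Plasma strain-rate [tensor_field], 1/s.
#' @param Wp,Wr Phase spin [tensor_field]s (antisymmetric), 1/s.
#' @param props A [fluid_properties] object.
#' @param params An [interaction_params] object.
#' @return An n x 2 matrix of force densities, N/m^3.
#' @examples
#' pr <- fluid_properties()
#' drag_force(0.2, matrix(c(0, 0), 1), matrix(c(0.01, 0), 1), pr)
#' @export
drag_force <- function(phi, vp, vr, props = fluid_properties()) {
  check_phi(phi)
  K <- drag_coefficient(phi, props)
  n <- length(K)
  vp <- as_vector_field(vp, n); vr <- as_vector_field(vr, n)
  K * (vr - vp)
}

## linear drag coefficient K(phi) = 9 mu_p/(2 a^2) f(phi), N s / m^4
drag_coefficient <- function(phi, props) {
  9 * props$plasma_viscosity / (2 * props$rbc_size_a^2) * hindrance(phi)
}

#' @rdname drag_force
#' @export
saffman_lift <- function(phi, Dp, vp, vr, props = fluid_properties(),
                         params = interaction_params()) {
  check_phi(phi)
  n <- length(Dp$xx)
  vp <- as_vector_field(vp, n); vr <- as_vector_field(vr, n)
  gd <- pmax(generalized_shear_rate(Dp), params$shear_floor)
  pref <- 3 * params$saffman_coeff *
    sqrt(props$plasma_density * props$plasma_viscosity) /
    (4 * pi * props$rbc_size_a) * phi / sqrt(gd)
  pref * tensor_vector_product(Dp, vr - vp)
}

#' @rdname drag_force
#' @export
spin_lift <- function(phi, Wp, Wr, vp, vr, props = fluid_properties(),
                      params = interaction_params()) {
  check_phi(phi)
  if (tensor_asymmetry_spin(Wp) > 1e-8 || tensor_asymmetry_spin(Wr) > 1e-8) {
    stop("spin tensors must be antisymmetric")
  }
  n <- length(Wp$xx)
  vp <- as_vector_field(vp, n); vr <- as_vector_field(vr, n)
  dW <- tensor_field(xx = Wr$xx - Wp$xx, xy = Wr$xy - Wp$xy,
                     yy = Wr$yy - Wp$yy, yx = Wr$yx - Wp$yx)
  params$spin_coeff * props$plasma_density * phi *
    tensor_vector_product(dW, vr - vp)
}

## relative deviation from antisymmetry
tensor_asymmetry_spin <- function(W) {
  scale <- max(abs(c(W$xx, W$xy, W$yx, W$yy)), 1e-300)
  max(abs(W$xy + W$yx), abs(W$xx), abs(W$yy)) / scale
}

#' @rdname drag_force
#' @param state A list with fields `phi`, `vp`, `vr` (a `flow_state` works).
#' @param tensors Phase tensors as returned by [compute_velocity_gradients].
#' @export
total_interaction <- function(state, tensors, props = fluid_properties(),
                              params = interaction_params()) {
  n <- length(state$phi)
  fI <- matrix(0, n, 2)
  if (params$drag) {
    fI <- fI + drag_force(state$phi, state$vp, state$vr, props)
  }
  if (params$saffman) {
    fI <- fI + saffman_lift(state$phi, tensors$Dp, state$vp, state$vr,
                            props, params)
  }
  if (params$spin) {
    fI <- fI + spin_lift(state$phi, tensors$Wp, tensors$Wr, state$vp,
                         state$vr, props, params)
  }
  fI
}
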
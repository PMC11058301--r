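#' Boundary conditions for a microvessel case
#'
#' Uniform axial inlet velocity and inlet hematocrit, zero (reference)
#' pressure at the outlet, no-slip walls for both phases and a symmetry/axis
#' centerline. Both phases enter with the same uniform velocity; slip between
#' them develops inside the domain.
#'
#' @param inlet_velocity_Vt Inlet velocity amplitude, m/s (> 0).
#' @param inlet_hematocrit_Ht Inlet RBC volume fraction (0 < Ht < packing
#'   bound).
#' @param outlet_pressure Outlet static pressure, Pa.
#' @return An object of class `boundary_conditions`.
#' @export
boundary_conditions <- function(inlet_velocity_Vt,
                                inlet_hematocrit_Ht,
                                outlet_pressure = 0) {
  stopifnot(inlet_velocity_Vt > 0, is.finite(outlet_pressure),
            inlet_hematocrit_Ht > 0, inlet_hematocrit_Ht < 1)
  structure(
    list(inlet_velocity_Vt = inlet_velocity_Vt,
         inlet_hematocrit_Ht = inlet_hematocrit_Ht,
         outlet_pressure = outlet_pressure),
    class = "boundary_conditions"
  )
}

#' Solver configuration
#'
#' Numerical settings of the steady pseudo-transient SIMPLE iteration. The
#' defaults favour robustness: first-order upwind convection (a minmod-limited
#' TVD deferred correction is selectable), moderate under-relaxation and a
#' volume-fraction packing bound of 0.68.
#'
#' @param max_outer Outer-iteration limit.
#' @param tol Convergence tolerance on the normalized residuals.
#' @param relax_v,relax_p,relax_phi Under-relaxation factors for momentum,
#'   pressure and volume fraction, in (0, 1].
#' @param pseudo_cfl Local pseudo-time CFL number of the volume-fraction
#'   transport step.
#' @param relax_force Under-relaxation factor of the explicitly coupled lift
#'   forces (blended with their previous-iteration values).
#' @param scheme Advection scheme: `"upwind"` or `"tvd"` (minmod).
#' @param phi_bounds Bounds `[phi_min, phi_max]` enforced on the volume
#'   fraction after every transport step.
#' @param verbose Print residuals every `verbose` iterations (0 = silent).
#' @return An object of class `solver_config`.
#' @export
solver_config <- function(max_outer = 600, tol = 1e-6,
                          relax_v = 0.7, relax_p = 0.3, relax_phi = 0.3,
                          pseudo_cfl = 10, relax_force = 0.3,
                          scheme = c("upwind", "tvd"),
                          phi_bounds = c(1e-6, 0.68),
                          verbose = 0) {
  scheme <- match.arg(scheme)
  stopifnot(max_outer >= 1, tol > 0,
            relax_v > 0, relax_v <= 1, relax_p > 0, relax_p <= 1,
            relax_phi > 0, relax_phi <= 1, pseudo_cfl > 0,
            relax_force > 0, relax_force <= 1,
            length(phi_bounds) == 2, phi_bounds[1] < phi_bounds[2])
  structure(
    list(max_outer = max_outer, tol = tol, relax_v = relax_v,
         relax_p = relax_p, relax_phi = relax_phi, pseudo_cfl = pseudo_cfl,
         relax_force = relax_force,
         scheme = scheme, phi_bounds = phi_bounds, verbose = verbose),
    class = "solver_config"
  )
}

## ---------------------------------------------------------------------------
## internal solver workspace helpers

## sparse transport matrix from per-face upwind mass fluxes M (outward from
## owner) and diffusion coefficients Dc (interior faces only), in the
## row-sum-zero (non-conservative) form used for momentum.
## Returns list(diag, off_x) to be combined by the caller.
new_workspace <- function(grid, bc, props, coeffs, params, config) {
  f <- grid$face
  int <- which(f$interior)
  ws <- new.env(parent = emptyenv())
  ws$grid <- grid; ws$bc <- bc; ws$props <- props
  ws$coeffs <- coeffs; ws$params <- params; ws$config <- config
  ws$int <- int
  ws$fo_int <- f$owner[int]; ws$fn_int <- f$neigh[int]
  ws$ii_off <- c(ws$fo_int, ws$fn_int)
  ws$jj_off <- c(ws$fn_int, ws$fo_int)
  ws$b_in <- which(f$tag == "inlet")
  ws$b_out <- which(f$tag == "outlet")
  ws$b_wall <- which(f$tag == "wall")
  ws$b_sym <- which(f$tag == "symmetry")
  ## orthogonal-projection geometric diffusion factor |S|^2 / (S.d) per face
  sdotd <- f$Sx * f$dcx + f$Sy * f$dcy
  ws$gdiff <- (f$Sx^2 + f$Sy^2) / pmax(sdotd, 1e-300)
  n <- grid$n
  Vt <- bc$inlet_velocity_Vt; Ht <- bc$inlet_hematocrit_Ht
  ws$phi <- rep(Ht, n)
  ws$p <- rep(bc$outlet_pressure, n)
  ws$vp <- cbind(rep(Vt, n), rep(0, n))
  ws$vr <- cbind(rep(Vt, n), rep(0, n))
  ## face normal velocity fluxes v.S (owner-outward), per phase
  ws$Up <- init_face_flux(grid, c(Vt, 0))
  ws$Ur <- ws$Up
  ws$aPp <- rep(1, n); ws$aPr <- rep(1, n)
  ws$fLift <- matrix(0, n, 2)
  ws$clipped_mass <- 0
  ws$residuals <- NULL
  ws
}

init_face_flux <- function(grid, v0) {
  f <- grid$face
  U <- v0[1] * f$Sx + v0[2] * f$Sy
  U[f$tag %in% c("wall", "symmetry")] <- 0
  U
}

## upwind face values of a cell field given face fluxes U
upwind_face <- function(grid, vals, U, inlet_value) {
  f <- grid$face
  up <- ifelse(f$interior & U < 0, vals[ifelse(f$interior, f$neigh, 1L)],
               vals[f$owner])
  bin <- f$tag == "inlet"
  up[bin] <- inlet_value
  up
}

## minmod-limited higher-order deferred correction to the upwind face value
ho_face_correction <- function(grid, vals, U, grad, inlet_value) {
  f <- grid$face
  int <- f$interior
  o <- f$owner; nb <- ifelse(int, f$neigh, 1L)
  upcell <- ifelse(U >= 0, o, nb)
  dncell <- ifelse(U >= 0, nb, o)
  ## vector from upwind cell to face midpoint
  rx <- f$xm - grid$xc[upcell]; ry <- f$ym - grid$yc[upcell]
  ext <- grad$x[upcell] * rx + grad$y[upcell] * ry
  dd <- (vals[dncell] - vals[upcell]) / 2
  corr <- pmin(pmax(pmin(ext, dd), 0), pmax(ext, 0)) +
    pmax(pmin(pmax(ext, dd), 0), pmin(ext, 0))  # minmod(ext, dd)
  corr[!int] <- 0
  corr
}

## assemble and solve one phase-component momentum equation
## comp: 1 = x, 2 = y; diag_extra: additional implicit diagonal (drag);
## returns list(v, diag_eff)
solve_momentum_component <- function(ws, phase, comp, Mf, Gam, vfield,
                                     src_extra, vbc_in, diag_extra = 0) {
  grid <- ws$grid; f <- grid$face; n <- grid$n
  cfg <- ws$config
  int <- ws$int
  ## convection (row-sum-zero upwind form)
  Mi <- Mf[int]
  diagc <- numeric(n)
  diagc <- diagc + tab_sum(ws$fo_int, pmax(-Mi, 0), n) +
    tab_sum(ws$fn_int, pmax(Mi, 0), n)
  off <- c(-pmax(-Mi, 0), -pmax(Mi, 0))
  ## diffusion, interior
  Di <- Gam[int] * ws$gdiff[int]
  diagc <- diagc + tab_sum(ws$fo_int, Di, n) + tab_sum(ws$fn_int, Di, n)
  off <- off + c(-Di, -Di)
  src <- src_extra
  ## boundary faces
  ## inlet: Dirichlet velocity + inflow convection
  bi <- ws$b_in
  Dinb <- Gam[bi] * ws$gdiff[bi]
  Minb <- Mf[bi]
  diagc <- diagc + tab_sum(f$owner[bi], Dinb + pmax(-Minb, 0), n)
  src <- src + tab_sum(f$owner[bi], (Dinb + pmax(-Minb, 0)) * vbc_in, n)
  ## wall: no-slip Dirichlet 0
  bw <- ws$b_wall
  Dw <- Gam[bw] * ws$gdiff[bw]
  diagc <- diagc + tab_sum(f$owner[bw], Dw, n)
  ## symmetry: y-component Dirichlet 0; x-component zero-gradient
  if (comp == 2L) {
    bs <- ws$b_sym
    Ds <- Gam[bs] * ws$gdiff[bs]
    diagc <- diagc + tab_sum(f$owner[bs], Ds, n)
    if (grid$mode == "axisymmetric") {
      ## hoop viscous term -Gam v_y / r^2 (implicit)
      diagc <- diagc + Gam_cell(ws, phase) * grid$vol / pmax(grid$yc^2, 1e-300)
    }
  }
  ## outlet: zero-gradient (outflow convection cancels in row-sum-zero form)
  ## implicit interphase drag and similar diagonal terms
  diagc <- diagc + diag_extra
  ## under-relaxation (implicit)
  diag_rel <- diagc / cfg$relax_v
  src <- src + (1 - cfg$relax_v) / cfg$relax_v * diagc * vfield[, comp]
  ## row-equilibrate by the diagonal: thin near-wall cells and the
  ## volume-fraction weighting spread row scales over many decades
  sc <- 1 / diag_rel
  A <- Matrix::sparseMatrix(i = c(seq_len(n), ws$ii_off),
                            j = c(seq_len(n), ws$jj_off),
                            x = c(rep(1, n), sc[ws$ii_off] * off),
                            dims = c(n, n))
  v <- tryCatch(
    as.numeric(Matrix::solve(A, sc * src)),
    error = function(e) stop("momentum linear solve failed: ",
                             conditionMessage(e))
  )
  list(v = v, diag_eff = diag_rel)
}

## cell-centered diffusion coefficient of a phase (used for hoop term)
Gam_cell <- function(ws, phase) {
  if (phase == "p") {
    ws$props$plasma_viscosity * (1 - ws$phi)
  } else {
    ws$mur_cell * ws$phi
  }
}

## fast grouped sum into n bins
tab_sum <- function(idx, vals, n) {
  out <- numeric(n)
  s <- rowsum(vals, idx, reorder = FALSE)
  out[as.integer(rownames(s))] <- s[, 1]
  out
}

## ---------------------------------------------------------------------------

#' Steady two-fluid solve
#'
#' Iterates the segregated SIMPLE-type loop — per-phase momentum equations
#' with the shear-thinning RBC rheology and interphase forces, a shared
#' pressure enforced through mixture-continuity pressure correction with
#' Rhie-Chow momentum interpolation, and conservative upwind transport of the
#' RBC volume fraction — until the normalized residuals fall below
#' `config$tol` or `config$max_outer` is reached. Deterministic: identical
#' inputs give bit-identical iteration histories.
#'
#' @param grid An `fv_grid` from [build_stenosis_grid] or
#'   [build_expansion_grid].
#' @param bc A [boundary_conditions] object.
#' @param props A [fluid_properties] object.
#' @param coeffs A [rheology_coefficients] object.
#' @param params An [interaction_params] object.
#' @param config A [solver_config] object.
#' @return A `flow_state`: list with cell fields `phi`, `p`, `vp`, `vr`,
#'   face fluxes, residual history (one row per outer iteration), and a
#'   `converged` flag.
#' @export
steady_solve <- function(grid, bc, props = fluid_properties(),
                         coeffs = rheology_coefficients(),
                         params = interaction_params(),
                         config = solver_config()) {
  ws <- new_workspace(grid, bc, props, coeffs, params, config)
  n <- grid$n
  f <- grid$face
  hist <- matrix(NA_real_, config$max_outer, 4,
                 dimnames = list(NULL, c("mom_p", "mom_r", "continuity", "phi")))
  converged <- FALSE
  for (it in seq_len(config$max_outer)) {
    res <- outer_iteration(ws)
    hist[it, ] <- res
    if (config$verbose > 0 && it %% config$verbose == 0) {
      message(sprintf("iter %4d  mom_p %.3e mom_r %.3e cont %.3e phi %.3e",
                      it, res[1], res[2], res[3], res[4]))
    }
    if (all(res < config$tol)) { converged <- TRUE; break }
  }
  hist <- hist[seq_len(it), , drop = FALSE]
  state <- list(
    phi = ws$phi, p = ws$p, vp = ws$vp, vr = ws$vr,
    flux = list(Up = ws$Up, Ur = ws$Ur, phi_face = ws$phi_face),
    residual_history = hist,
    converged = converged,
    iterations = it,
    clipped_mass = ws$clipped_mass,
    bc = bc, props = props, coeffs = coeffs, params = params,
    config = config
  )
  class(state) <- "flow_state"
  if (!converged) {
    warning(sprintf(
      "steady_solve: not converged after %d iterations (residuals %.2e %.2e %.2e %.2e)",
      it, hist[it, 1], hist[it, 2], hist[it, 3], hist[it, 4]))
  }
  state
}

#' @export
print.flow_state <- function(x, ...) {
  r <- x$residual_history[nrow(x$residual_history), ]
  cat(sprintf("<flow_state> %d cells, %d outer iterations, %s\n",
              length(x$phi), x$iterations,
              if (x$converged) "converged" else "NOT converged"))
  cat(sprintf("  final residuals: mom_p %.2e mom_r %.2e cont %.2e phi %.2e\n",
              r[1], r[2], r[3], r[4]))
  invisible(x)
}

## one outer iteration: momentum -> pressure correction -> phi transport.
## Returns normalized residuals c(mom_p, mom_r, continuity, phi).
outer_iteration <- function(ws) {
  grid <- ws$grid; f <- grid$face; n <- grid$n
  bc <- ws$bc; props <- ws$props; cfg <- ws$config
  Vt <- bc$inlet_velocity_Vt; Ht <- bc$inlet_hematocrit_Ht
  vol <- grid$vol

  ## ---- closures from current state -------------------------------------
  vbc <- list(wall = c(0, 0), inlet = c(Vt, 0))
  tp <- velocity_tensors(grid, ws$vp, vbc)
  tr <- velocity_tensors(grid, ws$vr, vbc)
  gd_r <- generalized_shear_rate(tr$D)
  ws$mur_cell <- rbc_viscosity(ws$phi, gd_r, ws$coeffs)

  ## face volume fraction: upwind by RBC flux direction
  phi_face <- upwind_face(grid, ws$phi, ws$Ur, Ht)
  phi_face[ws$b_wall] <- ws$phi[f$owner[ws$b_wall]]
  phi_face[ws$b_sym] <- ws$phi[f$owner[ws$b_sym]]
  ws$phi_face <- phi_face
  ap_face <- 1 - phi_face

  ## interphase forces
  state_now <- list(phi = ws$phi, vp = ws$vp, vr = ws$vr)
  tensors <- list(Dp = tp$D, Dr = tr$D, Wp = tp$W, Wr = tr$W)
  Kdrag <- if (ws$params$drag) drag_coefficient(ws$phi, props) else
    numeric(n)
  fLift <- matrix(0, n, 2)
  if (ws$params$saffman) {
    fLift <- fLift + saffman_lift(ws$phi, tp$D, ws$vp, ws$vr, props,
                                  ws$params)
  }
  if (ws$params$spin) {
    fLift <- fLift + spin_lift(ws$phi, tp$W, tr$W, ws$vp, ws$vr, props,
                               ws$params)
  }
  ## explicit lift forces are under-relaxed against the previous iterate to
  ## stabilize the segregated coupling in high-shear near-wall cells
  fLift <- cfg$relax_force * fLift + (1 - cfg$relax_force) * ws$fLift
  ws$fLift <- fLift

  ## pressure gradient (outlet reference value on outlet faces)
  gp <- green_gauss(grid, ws$p, list(outlet = bc$outlet_pressure))

  ## ---- phase momentum --------------------------------------------------
  alpha_p <- 1 - ws$phi
  alpha_r <- ws$phi
  Mp <- props$plasma_density * ap_face * ws$Up      # plasma face mass flux
  Mr <- props$rbc_density * phi_face * ws$Ur        # RBC face mass flux
  Gam_p <- face_values(grid, props$plasma_viscosity * alpha_p)
  Gam_r <- face_values(grid, ws$mur_cell * alpha_r)

  ## deferred corrections: transpose (stress) part + TVD convection
  src_p <- deferred_sources(ws, tp, Gam_p, ws$vp, Mp, c(Vt, 0))
  src_r <- deferred_sources(ws, tr, Gam_r, ws$vr, Mr, c(Vt, 0))

  g <- ws$params$gravity
  vp_old <- ws$vp; vr_old <- ws$vr
  ## plasma: + fI ;  RBC: - fI
  KV <- Kdrag * vol
  res_mom <- c(p = 0, r = 0)
  newv <- list(p = ws$vp, r = ws$vr)
  for (comp in 1:2) {
    srcc_p <- -alpha_p * gp[[c("x", "y")[comp]]] * vol +
      alpha_p * props$plasma_density * g[comp] * vol +
      fLift[, comp] * vol + KV * ws$vr[, comp] + src_p[, comp]
    sol_p <- solve_momentum_component(
      ws, "p", comp, Mp, Gam_p, ws$vp,
      src_extra = srcc_p, vbc_in = if (comp == 1L) Vt else 0,
      diag_extra = KV)
    newv$p[, comp] <- sol_p$v
    if (comp == 1L) ws$aPp <- sol_p$diag_eff
    srcc_r <- -alpha_r * gp[[c("x", "y")[comp]]] * vol +
      alpha_r * props$rbc_density * g[comp] * vol -
      fLift[, comp] * vol + KV * ws$vp[, comp] + src_r[, comp]
    sol_r <- solve_momentum_component(
      ws, "r", comp, Mr, Gam_r, ws$vr,
      src_extra = srcc_r, vbc_in = if (comp == 1L) Vt else 0,
      diag_extra = KV)
    newv$r[, comp] <- sol_r$v
    if (comp == 1L) ws$aPr <- sol_r$diag_eff
  }
  res_mom["p"] <- max(abs(newv$p - vp_old)) / max(Vt, 1e-300)
  res_mom["r"] <- max(abs(newv$r - vr_old)) / max(Vt, 1e-300)
  ws$vp <- newv$p
  ws$vr <- newv$r

  ## ---- pressure correction (mixture continuity) ------------------------
  cont <- pressure_correction(ws, phi_face)

  ## ---- volume fraction transport --------------------------------------
  resphi <- phi_transport(ws)

  c(res_mom["p"], res_mom["r"], cont, resphi)
}

## explicit deferred-correction sources (viscous transpose part + optional
## TVD convection correction) for one phase; returns an n x 2 matrix
deferred_sources <- function(ws, tens, Gam, v, Mf, v_in) {
  grid <- ws$grid; f <- grid$face; n <- grid$n
  int <- f$interior
  ## face-interpolated velocity-gradient components
  gux <- face_values(grid, tens$grad_u$x)
  guy <- face_values(grid, tens$grad_u$y)
  gvx <- face_values(grid, tens$grad_v$x)
  gvy <- face_values(grid, tens$grad_v$y)
  ## full viscous face flux Gam * (grad v + grad v^T) . S minus the implicit
  ## orthogonal part Gam * (v_N - v_P) |S|^2/(S.d):
  flux_x <- Gam * ((2 * gux) * f$Sx + (guy + gvx) * f$Sy)
  flux_y <- Gam * ((gvx + guy) * f$Sx + (2 * gvy) * f$Sy)
  impl_x <- Gam * (gux * f$dcx + guy * f$dcy) * ws$gdiff
  impl_y <- Gam * (gvx * f$dcx + gvy * f$dcy) * ws$gdiff
  cx <- (flux_x - impl_x) * int
  cy <- (flux_y - impl_y) * int
  if (ws$config$scheme == "tvd") {
    hx <- ho_face_correction(grid, v[, 1], Mf, tens$grad_u, v_in[1])
    hy <- ho_face_correction(grid, v[, 2], Mf, tens$grad_v, v_in[2])
    cx <- cx - Mf * hx
    cy <- cy - Mf * hy
  }
  cbind(as.numeric(grid$face_div %*% cx),
        as.numeric(grid$face_div %*% cy))
}

## SIMPLE pressure correction on the mixture volumetric flux
pressure_correction <- function(ws, phi_face) {
  grid <- ws$grid; f <- grid$face; n <- grid$n
  cfg <- ws$config; bc <- ws$bc
  int <- ws$int
  ap_face <- 1 - phi_face
  ## Rhie-Chow face fluxes from the provisional velocities
  gp <- green_gauss(grid, ws$p, list(outlet = bc$outlet_pressure))
  dcp <- (1 - ws$phi) * grid$vol / ws$aPp
  dcr <- ws$phi * grid$vol / ws$aPr
  vpx_f <- face_values(grid, ws$vp[, 1]); vpy_f <- face_values(grid, ws$vp[, 2])
  vrx_f <- face_values(grid, ws$vr[, 1]); vry_f <- face_values(grid, ws$vr[, 2])
  gpx_f <- face_values(grid, gp$x); gpy_f <- face_values(grid, gp$y)
  dcp_f <- face_values(grid, dcp); dcr_f <- face_values(grid, dcr)
  dp_face <- ifelse(f$interior,
                    ws$p[ifelse(f$interior, f$neigh, 1L)] - ws$p[f$owner], 0)
  rc_p <- dcp_f * (dp_face * ws$gdiff - (gpx_f * f$dcx + gpy_f * f$dcy) *
                     ws$gdiff)
  rc_r <- dcr_f * (dp_face * ws$gdiff - (gpx_f * f$dcx + gpy_f * f$dcy) *
                     ws$gdiff)
  Up <- vpx_f * f$Sx + vpy_f * f$Sy - rc_p * f$interior
  Ur <- vrx_f * f$Sx + vry_f * f$Sy - rc_r * f$interior
  ## boundary fluxes
  Vt <- bc$inlet_velocity_Vt
  Up[ws$b_in] <- Vt * f$Sx[ws$b_in]
  Ur[ws$b_in] <- Vt * f$Sx[ws$b_in]
  Up[c(ws$b_wall, ws$b_sym)] <- 0
  Ur[c(ws$b_wall, ws$b_sym)] <- 0
  ## outlet: zero-gradient velocity -> owner value (already via face_values)
  Qmix <- ap_face * Up + phi_face * Ur
  imb <- as.numeric(grid$face_div %*% Qmix)   # net outflow per cell
  Qref <- sum(abs(Qmix[ws$b_in]))
  cont_res <- sum(abs(imb)) / max(Qref, 1e-300)

  ## pressure-correction coefficients
  Gf <- (ap_face * dcp_f + phi_face * dcr_f) * ws$gdiff
  diagc <- tab_sum(ws$fo_int, Gf[int], n) + tab_sum(ws$fn_int, Gf[int], n)
  off <- c(-Gf[int], -Gf[int])
  ## outlet: p' Dirichlet 0
  bo <- ws$b_out
  diagc <- diagc + tab_sum(f$owner[bo], Gf[bo], n)
  sc <- 1 / pmax(diagc, 1e-300)
  A <- Matrix::sparseMatrix(i = c(seq_len(n), ws$ii_off),
                            j = c(seq_len(n), ws$jj_off),
                            x = c(rep(1, n), sc[ws$ii_off] * off),
                            dims = c(n, n))
  pc <- tryCatch(
    as.numeric(Matrix::solve(A, -sc * imb)),
    error = function(e) stop(
      "pressure-correction solve failed (singular system? an outlet pressure reference is required): ",
      conditionMessage(e))
  )
  ## correct pressure (relaxed), velocities and face fluxes (full)
  ws$p <- ws$p + cfg$relax_p * pc
  gpc <- green_gauss(grid, pc, list(outlet = 0))
  ws$vp <- ws$vp - cbind(dcp * gpc$x, dcp * gpc$y)
  ws$vr <- ws$vr - cbind(dcr * gpc$x, dcr * gpc$y)
  dpc_face <- ifelse(f$interior,
                     pc[ifelse(f$interior, f$neigh, 1L)] - pc[f$owner], 0)
  Up[int] <- Up[int] - (dcp_f * ws$gdiff * dpc_face)[int]
  Ur[int] <- Ur[int] - (dcr_f * ws$gdiff * dpc_face)[int]
  ## outlet faces: correct with (0 - pc_owner)
  Up[bo] <- Up[bo] - dcp_f[bo] * ws$gdiff[bo] * (0 - pc[f$owner[bo]])
  Ur[bo] <- Ur[bo] - dcr_f[bo] * ws$gdiff[bo] * (0 - pc[f$owner[bo]])
  ws$Up <- Up
  ws$Ur <- Ur
  cont_res
}

## implicit conservative upwind transport of phi with local pseudo-time
phi_transport <- function(ws) {
  grid <- ws$grid; f <- grid$face; n <- grid$n
  cfg <- ws$config; bc <- ws$bc
  int <- ws$int
  Ur <- ws$Ur
  Ui <- Ur[int]
  diagc <- tab_sum(ws$fo_int, pmax(Ui, 0), n) +
    tab_sum(ws$fn_int, pmax(-Ui, 0), n)
  off <- c(-pmax(-Ui, 0), -pmax(Ui, 0))
  src <- numeric(n)
  ## inlet: inflow at Ht
  bi <- ws$b_in
  src <- src + tab_sum(f$owner[bi], -Ur[bi] * bc$inlet_hematocrit_Ht, n)
  ## outlet: outflow
  bo <- ws$b_out
  diagc <- diagc + tab_sum(f$owner[bo], pmax(Ur[bo], 0), n)
  ## TVD deferred correction on phi
  if (cfg$scheme == "tvd") {
    gphi <- green_gauss(grid, ws$phi, list(inlet = bc$inlet_hematocrit_Ht))
    hph <- ho_face_correction(grid, ws$phi, Ur, gphi,
                              bc$inlet_hematocrit_Ht)
    src <- src - as.numeric(grid$face_div %*% (Ur * hph))
  }
  ## local pseudo-time step scaled by the larger of in/out flux so that
  ## transiently inflow-only cells keep a well-scaled diagonal
  outflow <- tab_sum(ws$fo_int, pmax(Ui, 0), n) +
    tab_sum(ws$fn_int, pmax(-Ui, 0), n) +
    tab_sum(f$owner[bo], pmax(Ur[bo], 0), n) +
    tab_sum(f$owner[bi], pmax(-Ur[bi], 0), n)
  inflow <- tab_sum(ws$fo_int, pmax(-Ui, 0), n) +
    tab_sum(ws$fn_int, pmax(Ui, 0), n) +
    tab_sum(f$owner[bi], pmax(Ur[bi] * 0 - Ur[bi], 0), n)
  thru <- pmax(outflow, inflow)
  dtau_inv <- pmax(thru, 1e-8 * max(thru)) / cfg$pseudo_cfl
  diagc <- diagc + dtau_inv
  src <- src + dtau_inv * ws$phi
  sc <- 1 / pmax(diagc, 1e-300)
  A <- Matrix::sparseMatrix(i = c(seq_len(n), ws$ii_off),
                            j = c(seq_len(n), ws$jj_off),
                            x = c(rep(1, n), sc[ws$ii_off] * off),
                            dims = c(n, n))
  phin <- as.numeric(Matrix::solve(A, sc * src))
  phin <- ws$phi + cfg$relax_phi * (phin - ws$phi)
  lo <- cfg$phi_bounds[1]; hi <- cfg$phi_bounds[2]
  clip <- pmin(pmax(phin, lo), hi)
  ws$clipped_mass <- ws$clipped_mass + sum(abs(clip - phin) * grid$vol)
  ## phi is dimensionless O(0.1); its residual is the absolute change
  resphi <- max(abs(clip - ws$phi))
  ws$phi <- clip
  resphi
}

#' Global per-phase mass balance of a converged state
#'
#' Computes the inlet and outlet volumetric fluxes of each phase from the
#' converged face fluxes (upwinded volume fraction times the Rhie-Chow face
#' velocity flux) and returns the relative imbalances.
#'
#' @param state A `flow_state`.
#' @param grid The `fv_grid` it was solved on.
#' @return Named vector: `plasma_in`, `plasma_out`, `rbc_in`, `rbc_out`
#'   (m^3/s, per radian in axisymmetric mode; inflow positive),
#'   `plasma_imbalance`, `rbc_imbalance` (relative).
#' @export
phase_mass_balance <- function(state, grid) {
  f <- grid$face
  bi <- which(f$tag == "inlet"); bo <- which(f$tag == "outlet")
  phi_face <- upwind_face(grid, state$phi, state$flux$Ur,
                          state$bc$inlet_hematocrit_Ht)
  Qr <- phi_face * state$flux$Ur
  Qp <- (1 - phi_face) * state$flux$Up
  r_in <- -sum(Qr[bi]); r_out <- sum(Qr[bo])
  p_in <- -sum(Qp[bi]); p_out <- sum(Qp[bo])
  c(plasma_in = p_in, plasma_out = p_out, rbc_in = r_in, rbc_out = r_out,
    plasma_imbalance = abs(p_in - p_out) / max(abs(p_in), 1e-300),
    rbc_imbalance = abs(r_in - r_out) / max(abs(r_in), 1e-300))
}
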
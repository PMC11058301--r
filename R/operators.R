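## Green-Gauss discrete operators on an fv_grid.

## Interpolate a cell field to faces; `bc` maps boundary tag -> face value
## (scalar or vector over that tag's faces). Tags not listed keep the owner
## (zero-gradient) value.
face_values <- function(grid, cellvals, bc = list()) {
  fv <- as.numeric(grid$face_interp %*% cellvals)
  for (tag in names(bc)) {
    idx <- which(grid$face$tag == tag)
    if (length(idx)) fv[idx] <- bc[[tag]]
  }
  fv
}

## Green-Gauss gradient of a cell scalar: list(x, y), using planar metrics.
green_gauss <- function(grid, cellvals, bc = list()) {
  fv <- face_values(grid, cellvals, bc)
  list(
    x = as.numeric(grid$face_div %*% (fv * grid$face$Spx)) / grid$vol_plan,
    y = as.numeric(grid$face_div %*% (fv * grid$face$Spy)) / grid$vol_plan
  )
}

## Strain-rate (D) and spin (W) tensor fields of a velocity field v (n x 2).
## vbc: list(tag = c(vx, vy)) Dirichlet values used on those boundary faces;
## symmetry faces always use (owner vx, 0) [mirror condition].
velocity_tensors <- function(grid, v, vbc = list()) {
  bcond_x <- list(); bcond_y <- list()
  for (tag in names(vbc)) {
    bcond_x[[tag]] <- vbc[[tag]][1]
    bcond_y[[tag]] <- vbc[[tag]][2]
  }
  bcond_y[["symmetry"]] <- 0
  gu <- green_gauss(grid, v[, 1], bcond_x)
  gv <- green_gauss(grid, v[, 2], bcond_y)
  tt <- if (grid$mode == "axisymmetric") v[, 2] / pmax(grid$yc, 1e-300) else 0
  list(
    D = tensor_field(xx = gu$x, xy = 0.5 * (gu$y + gv$x), yy = gv$y, tt = tt),
    W = tensor_field(xx = 0, xy = 0.5 * (gu$y - gv$x),
                     yx = -0.5 * (gu$y - gv$x), yy = 0, tt = 0),
    grad_u = gu, grad_v = gv
  )
}

#' Strain-rate and spin tensors of both phases
#'
#' Green-Gauss cell gradients of the two phase velocity fields of a flow
#' state, returning the symmetric parts `Dp`, `Dr` (strain rate; in
#' axisymmetric mode the hoop component v_y/y is carried explicitly) and the
#' antisymmetric parts `Wp`, `Wr` (spin). Wall and inlet faces use the
#' boundary velocities; symmetry faces mirror the transverse component.
#'
#' @param state A `flow_state` (see [steady_solve]).
#' @param grid An `fv_grid`.
#' @param bc A [boundary_conditions] object (for the inlet velocity); if
#'   `NULL`, inlet faces fall back to zero-gradient.
#' @return A list with [tensor_field]s `Dp`, `Dr`, `Wp`, `Wr`.
#' @export
compute_velocity_gradients <- function(state, grid, bc = NULL) {
  vbc <- list(wall = c(0, 0))
  if (!is.null(bc)) vbc$inlet <- c(bc$inlet_velocity_Vt, 0)
  tp <- velocity_tensors(grid, state$vp, vbc)
  tr <- velocity_tensors(grid, state$vr, vbc)
  list(Dp = tp$D, Dr = tr$D, Wp = tp$W, Wr = tr$W)
}
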
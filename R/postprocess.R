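#' Wall shear stress profile
#'
#' For every wall face, forms the one-sided velocity gradient between the
#' adjacent cell and the no-slip wall, builds the plasma-phase viscous stress
#' `2 mu_p (1 - phi) Dp` from it, takes the surface traction `t = T n` and
#' returns the magnitude of its tangential component
#' `tau_wss = |t - (t.n) n|`. Optionally the RBC-phase viscous stress is
#' added (`use_mixture = TRUE`) for sensitivity checks; the default follows
#' the plasma-phase definition.
#'
#' @param state A `flow_state`.
#' @param grid The `fv_grid` it was solved on.
#' @param props A [fluid_properties] object (defaults to the one stored in
#'   the state).
#' @param use_mixture Add the RBC-phase viscous traction.
#' @return A tibble of class `wall_profile` with columns `x`, `y_wall`, `s`
#'   (wall arc length) and `tau_wss` (Pa), ordered by increasing `x`.
#' @export
wall_shear_stress <- function(state, grid, props = NULL, use_mixture = FALSE) {
  if (is.null(props)) props <- state$props
  f <- grid$face
  iw <- grid$wall$faces
  own <- f$owner[iw]
  nx <- f$Spx[iw] / sqrt(f$Spx[iw]^2 + f$Spy[iw]^2)
  ny <- f$Spy[iw] / sqrt(f$Spx[iw]^2 + f$Spy[iw]^2)
  ## wall-normal distance from cell center to the face plane
  dnw <- pmax(abs(f$dcx[iw] * nx + f$dcy[iw] * ny), 1e-300)
  tau <- wall_traction_tangential(state$vp[own, , drop = FALSE], nx, ny, dnw,
                                  props$plasma_viscosity *
                                    (1 - state$phi[own]))
  if (use_mixture) {
    gd <- pmax(sqrt((state$vr[own, 1]^2 + state$vr[own, 2]^2)) / dnw, 0)
    mur <- rbc_viscosity(state$phi[own], gd, state$coeffs)
    tau <- tau + wall_traction_tangential(state$vr[own, , drop = FALSE],
                                          nx, ny, dnw,
                                          mur * state$phi[own])
  }
  out <- tibble::tibble(x = f$xm[iw], y_wall = f$ym[iw], s = grid$wall$s,
                        tau_wss = tau)
  class(out) <- c("wall_profile", class(out))
  out
}

## tangential traction magnitude of the one-sided viscous stress at a no-slip
## wall: grad v = (v_cell - 0) outer n / dn, D = sym(grad v), t = 2 mu D n
wall_traction_tangential <- function(v, nx, ny, dn, mu2) {
  gxx <- v[, 1] * nx / dn; gxy <- v[, 1] * ny / dn
  gyx <- v[, 2] * nx / dn; gyy <- v[, 2] * ny / dn
  dxx <- gxx; dxy <- 0.5 * (gxy + gyx); dyy <- gyy
  tx <- 2 * mu2 * (dxx * nx + dxy * ny)
  ty <- 2 * mu2 * (dxy * nx + dyy * ny)
  tn <- tx * nx + ty * ny
  sqrt(pmax((tx - tn * nx)^2 + (ty - tn * ny)^2, 0))
}

## cell columns of the block containing x (list: block, i, xcol)
locate_column <- function(grid, x) {
  for (b in seq_along(grid$blocks)) {
    blk <- grid$blocks[[b]]
    if (x >= min(blk$X) - 1e-12 && x <= max(blk$X) + 1e-12) {
      ## per-column mean cell-center x of the body-fitted grid
      xcol <- rowMeans(matrix(grid$xc[blk$cell_id], blk$nx, blk$ny))
      return(list(block = b, xcol = xcol))
    }
  }
  stop("x_section outside the meshed domain")
}

## sampled y-profile of cell fields along column i of block b, with boundary
## closures: velocities vanish at the wall, symmetry at y = 0 copies the
## first cell, phi is zero-gradient at both ends.
column_profile <- function(grid, state, b, i) {
  blk <- grid$blocks[[b]]
  ids <- blk$cell_id[i, ]
  yy <- grid$yc[ids]
  ywall <- (blk$Y[i, ncol(blk$Y)] + blk$Y[i + 1L, ncol(blk$Y)]) / 2
  list(
    y = c(0, yy, ywall),
    phi = c(state$phi[ids][1], state$phi[ids], state$phi[ids][length(ids)]),
    up = c(state$vp[ids, 1][1], state$vp[ids, 1], 0),
    ur = c(state$vr[ids, 1][1], state$vr[ids, 1], 0),
    ywall = ywall
  )
}

#' Cross-section profiles of volume fraction and axial velocity
#'
#' Linearly interpolates the RBC volume fraction and the axial velocity of
#' both phases onto a uniform transverse sampling of the cross-section at
#' `x_section`, honouring the boundary closures (no-slip at the wall,
#' symmetry at the centerline/axis).
#'
#' @param state A `flow_state`.
#' @param grid The `fv_grid` it was solved on.
#' @param x_section Axial position of the section, m (within the domain).
#' @param n_sample Number of transverse sample points.
#' @return A tibble of class `section_profile` with columns `y`, `phi`,
#'   `u_plasma`, `u_rbc` and attribute `x_section`.
#' @export
section_profile <- function(state, grid, x_section, n_sample = 64) {
  loc <- locate_column(grid, x_section)
  xcol <- loc$xcol
  b <- loc$block
  i2 <- findInterval(x_section, xcol)
  i1 <- max(min(i2, length(xcol) - 1L), 1L)
  i2 <- i1 + 1L
  w <- (xcol[i2] - x_section) / (xcol[i2] - xcol[i1])
  w <- min(max(w, 0), 1)
  p1 <- column_profile(grid, state, b, i1)
  p2 <- column_profile(grid, state, b, i2)
  ywall <- w * p1$ywall + (1 - w) * p2$ywall
  ys <- seq(0, ywall, length.out = n_sample)
  eta <- ys / ywall
  ## blend the two bracketing columns in the normalized transverse
  ## coordinate y / y_wall, respecting the body-fitted geometry
  blend <- function(fld) {
    v1 <- stats::approx(p1$y / p1$ywall, p1[[fld]], xout = eta, rule = 2)$y
    v2 <- stats::approx(p2$y / p2$ywall, p2[[fld]], xout = eta, rule = 2)$y
    w * v1 + (1 - w) * v2
  }
  out <- tibble::tibble(y = ys, phi = blend("phi"),
                        u_plasma = blend("up"), u_rbc = blend("ur"))
  attr(out, "x_section") <- x_section
  class(out) <- c("section_profile", class(out))
  out
}

#' Conservative volumetric fluxes through a cross-section
#'
#' Sums the solver's own conservative face fluxes over the grid's transverse
#' face family nearest to `x_section`, returning the plasma, RBC and mixture
#' volumetric fluxes (per radian in axisymmetric mode). Because these are
#' exactly the fluxes the scheme transports mass with, a converged state
#' yields equal mixture flux through every section to linear-solver
#' precision; integrating the interpolated [section_profile] instead carries
#' a few percent of cell-to-face reconstruction error on coarse grids.
#'
#' @param state A `flow_state`.
#' @param grid The `fv_grid` it was solved on.
#' @param x_section Axial position, m.
#' @return Named numeric: `plasma`, `rbc`, `mixture` (m^3/s; per radian in
#'   axisymmetric mode), plus `x_actual`, the face-family position used.
#' @export
section_flux <- function(state, grid, x_section) {
  loc <- locate_column(grid, x_section)
  blk <- grid$blocks[[loc$block]]
  xn <- blk$X[, 1]
  i0 <- which.min(abs(xn - x_section))
  f <- grid$face
  phi_face <- upwind_face(grid, state$phi, state$flux$Ur,
                          state$bc$inlet_hematocrit_Ht)
  if (i0 == 1L || i0 == length(xn)) {
    ## boundary family: inlet or outlet faces of this block
    cells <- if (i0 == 1L) blk$cell_id[1L, ] else blk$cell_id[blk$nx, ]
    tag <- if (i0 == 1L) "inlet" else "outlet"
    idx <- which(f$tag == tag & f$owner %in% cells)
    sgn <- if (i0 == 1L) -1 else 1   # measure in +x direction
  } else {
    own <- blk$cell_id[i0 - 1L, ]
    nbr <- blk$cell_id[i0, ]
    idx <- which(f$interior & f$owner %in% own & f$neigh %in% nbr)
    sgn <- 1
  }
  qp <- sgn * sum((1 - phi_face[idx]) * state$flux$Up[idx])
  qr <- sgn * sum(phi_face[idx] * state$flux$Ur[idx])
  c(plasma = qp, rbc = qr, mixture = qp + qr, x_actual = xn[i0])
}

#' Recirculation extent along the wall
#'
#' Locates flow separation and reattachment downstream of x = 0 from sign
#' changes of the near-wall axial plasma velocity (first interior cell row
#' next to the wall), with linear interpolation between cell centers.
#'
#' @param state A `flow_state`.
#' @param grid The `fv_grid` it was solved on.
#' @return Named numeric `c(x_sep, x_reattach)`, `NA` if no reversal exists
#'   (reattachment `NA` if the reversed region reaches the outlet).
#' @export
recirculation_extent <- function(state, grid) {
  f <- grid$face
  iw <- grid$wall$faces
  own <- f$owner[iw]
  x <- f$xm[iw]
  u <- state$vp[own, 1]
  keep <- !duplicated(own)
  x <- x[keep]; u <- u[keep]
  sep <- NA_real_; reat <- NA_real_
  neg <- which(u < 0 & x > 0)
  if (length(neg)) {
    i0 <- neg[1]
    sep <- if (i0 > 1) zero_cross(x[i0 - 1], x[i0], u[i0 - 1], u[i0]) else x[i0]
    after <- which(u >= 0 & x > x[i0])
    if (length(after)) {
      i1 <- after[1]
      reat <- zero_cross(x[i1 - 1], x[i1], u[i1 - 1], u[i1])
    }
  }
  c(x_sep = sep, x_reattach = reat)
}

zero_cross <- function(x0, x1, u0, u1) {
  if (u1 == u0) return((x0 + x1) / 2)
  x0 - u0 * (x1 - x0) / (u1 - u0)
}

#' Cell-free and cell-rich layer metrics
#'
#' Thresholds the RBC volume fraction against the inlet hematocrit: a cell is
#' cell-free where `phi < c_free * Ht` and cell-rich where
#' `phi > c_rich * Ht`. Wall-adjacent connected components (runs of
#' consecutive wall columns whose wall cell qualifies) are measured for axial
#' extent and maximum transverse thickness (consecutive qualifying cells from
#' the wall inward). The thresholds are this package's quantitative reading
#' of regions usually judged from contour plots, and are configurable.
#'
#' @param state A `flow_state`.
#' @param grid The `fv_grid` it was solved on.
#' @param Ht Reference hematocrit (defaults to the inlet value of the state).
#' @param c_free,c_rich Dimensionless thresholds.
#' @return A list of class `layer_metrics`: `cfl_thickness` (tibble `x`,
#'   `thickness` of the wall-adjacent cell-free layer per wall column),
#'   `cell_free_components` and `cell_rich_components` (tibbles with
#'   `x_start`, `x_end`, `max_thickness`).
#' @export
layer_metrics <- function(state, grid, Ht = NULL, c_free = 0.5,
                          c_rich = 1.2) {
  if (is.null(Ht)) Ht <- state$bc$inlet_hematocrit_Ht
  free <- state$phi < c_free * Ht
  rich <- state$phi > c_rich * Ht
  xs <- numeric(0); th_free <- numeric(0); th_rich <- numeric(0)
  for (b in seq_along(grid$blocks)) {
    blk <- grid$blocks[[b]]
    ny <- blk$ny
    for (i in seq_len(blk$nx)) {
      ids <- blk$cell_id[i, ny:1]          # wall inward
      dy <- cell_heights(grid, blk, i)
      xs <- c(xs, mean(grid$xc[blk$cell_id[i, ]]))
      th_free <- c(th_free, run_thickness(free[ids], dy))
      th_rich <- c(th_rich, run_thickness(rich[ids], dy))
    }
  }
  ord <- order(xs)
  xs <- xs[ord]; th_free <- th_free[ord]; th_rich <- th_rich[ord]
  out <- list(
    cfl_thickness = tibble::tibble(x = xs, thickness = th_free),
    cell_free_components = components_table(xs, th_free),
    cell_rich_components = components_table(xs, th_rich),
    thresholds = c(c_free = c_free, c_rich = c_rich, Ht = Ht)
  )
  class(out) <- "layer_metrics"
  out
}

## cell heights of column i, wall inward
cell_heights <- function(grid, blk, i) {
  yn <- (blk$Y[i, ] + blk$Y[i + 1L, ]) / 2
  rev(diff(yn))
}

## thickness of the wall-adjacent qualifying run
run_thickness <- function(flag, dy) {
  k <- which(!flag)
  m <- if (length(k)) k[1] - 1L else length(flag)
  if (m == 0L) 0 else sum(dy[seq_len(m)])
}

components_table <- function(x, thickness) {
  on <- thickness > 0
  if (!any(on)) {
    return(tibble::tibble(x_start = numeric(0), x_end = numeric(0),
                          max_thickness = numeric(0)))
  }
  r <- rle(on)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  tibble::tibble(
    x_start = x[starts[keep]],
    x_end = x[ends[keep]],
    max_thickness = vapply(keep, function(k) {
      max(thickness[starts[k]:ends[k]])
    }, numeric(1))
  )
}

#' @export
print.layer_metrics <- function(x, ...) {
  cat("<layer_metrics>\n")
  cat(sprintf("  cell-free components: %d, cell-rich components: %d\n",
              nrow(x$cell_free_components), nrow(x$cell_rich_components)))
  invisible(x)
}

## fixed schema of the run summary
SUMMARY_KEYS <- c(
  "case", "converged", "iterations", "max_tau_wss", "max_tau_wss_x",
  "recirc_x_sep", "recirc_x_reattach", "n_cell_free_components",
  "n_cell_rich_components", "residual_mom_p", "residual_mom_r",
  "residual_continuity", "residual_phi", "clipped_mass"
)

#' Write standard outputs of a run
#'
#' Writes, into `out_dir`: a legacy ASCII VTK structured-grid file per grid
#' block with point data `p`, `phi`, `vp`, `vr`; a CSV wall profile
#' (`x`, `y_wall`, `tau_wss`); one CSV per requested cross-section
#' (`y`, `phi`, `u_plasma`, `u_rbc`); and a YAML run summary with the keys
#' in the fixed schema (`hemoflow:::SUMMARY_KEYS`).
#'
#' @param state A `flow_state`.
#' @param grid The `fv_grid` it was solved on.
#' @param out_dir Output directory (created if missing).
#' @param sections Axial positions (m) of section CSVs.
#' @param case Case label recorded in the summary.
#' @return Invisibly, the list of files written.
#' @export
write_outputs <- function(state, grid, out_dir, sections = numeric(0),
                          case = "case") {
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)) {
    stop("cannot create output directory: ", out_dir)
  }
  files <- character(0)
  for (b in seq_along(grid$blocks)) {
    fn <- file.path(out_dir, sprintf("fields_block%d.vtk", b))
    write_vtk_structured(grid, b, state, fn)
    files <- c(files, fn)
  }
  wp <- wall_shear_stress(state, grid)
  fn <- file.path(out_dir, "wall_profile.csv")
  utils::write.csv(wp[, c("x", "y_wall", "tau_wss")], fn, row.names = FALSE)
  files <- c(files, fn)
  for (xs in sections) {
    sp <- section_profile(state, grid, xs)
    fn <- file.path(out_dir, sprintf("section_x_%+.1fum.csv", xs * 1e6))
    utils::write.csv(as.data.frame(sp), fn, row.names = FALSE)
    files <- c(files, fn)
  }
  lm <- layer_metrics(state, grid)
  rc <- recirculation_extent(state, grid)
  res <- state$residual_history[nrow(state$residual_history), ]
  summ <- list(
    case = case,
    converged = state$converged,
    iterations = state$iterations,
    max_tau_wss = max(wp$tau_wss),
    max_tau_wss_x = wp$x[which.max(wp$tau_wss)],
    recirc_x_sep = as.numeric(rc["x_sep"]),
    recirc_x_reattach = as.numeric(rc["x_reattach"]),
    n_cell_free_components = nrow(lm$cell_free_components),
    n_cell_rich_components = nrow(lm$cell_rich_components),
    residual_mom_p = as.numeric(res[1]),
    residual_mom_r = as.numeric(res[2]),
    residual_continuity = as.numeric(res[3]),
    residual_phi = as.numeric(res[4]),
    clipped_mass = state$clipped_mass
  )
  fn <- file.path(out_dir, "summary.yaml")
  yaml::write_yaml(summ, fn)
  files <- c(files, fn)
  invisible(files)
}
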
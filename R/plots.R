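#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a flow state into a per-cell tibble
#'
#' @param x A `flow_state`.
#' @param grid The `fv_grid` it was solved on (needed for coordinates; if
#'   omitted, only the fields are returned).
#' @param ... Unused.
#' @return A tibble with one row per cell: `x`, `y`, `phi`, `p`, `u_plasma`,
#'   `v_plasma`, `u_rbc`, `v_rbc`.
#' @method tidy flow_state
#' @export
tidy.flow_state <- function(x, grid = NULL, ...) {
  out <- tibble::tibble(
    phi = x$phi, p = x$p,
    u_plasma = x$vp[, 1], v_plasma = x$vp[, 2],
    u_rbc = x$vr[, 1], v_rbc = x$vr[, 2])
  if (!is.null(grid)) {
    out <- tibble::add_column(out, x = grid$xc, y = grid$yc, .before = 1)
  }
  out
}

#' One-row summary of a flow solve
#'
#' @param x A `flow_state`.
#' @param ... Unused.
#' @return A one-row tibble: convergence flag, iteration count, final
#'   residuals, clipped volume-fraction mass.
#' @method glance flow_state
#' @export
glance.flow_state <- function(x, ...) {
  r <- x$residual_history[nrow(x$residual_history), ]
  tibble::tibble(
    converged = x$converged, iterations = x$iterations,
    residual_mom_p = r[[1]], residual_mom_r = r[[2]],
    residual_continuity = r[[3]], residual_phi = r[[4]],
    clipped_mass = x$clipped_mass)
}

#' Plot a wall shear stress profile
#'
#' @param object A `wall_profile` from [wall_shear_stress].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot wall_profile
#' @export
autoplot.wall_profile <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$x * 1e6,
                                       y = .data$tau_wss)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "axial position x (µm)",
                  y = expression(tau[wss] ~ "(Pa)"),
                  title = "Wall shear stress") +
    ggplot2::theme_minimal()
}

#' Plot a cross-section profile
#'
#' Shows the RBC volume fraction and the axial velocities of both phases
#' against the transverse coordinate.
#'
#' @param object A `section_profile` from [section_profile].
#' @param what `"phi"` or `"velocity"`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot section_profile
#' @export
autoplot.section_profile <- function(object, what = c("phi", "velocity"),
                                     ...) {
  what <- match.arg(what)
  xs <- attr(object, "x_section")
  if (what == "phi") {
    ggplot2::ggplot(object, ggplot2::aes(x = .data$y * 1e6,
                                         y = .data$phi)) +
      ggplot2::geom_line() +
      ggplot2::labs(x = "transverse position y (µm)",
                    y = expression(phi),
                    title = sprintf("RBC volume fraction at x = %g µm",
                                    xs * 1e6)) +
      ggplot2::theme_minimal()
  } else {
    df <- tibble::tibble(
      y = rep(object$y, 2) * 1e6,
      u = c(object$u_plasma, object$u_rbc),
      phase = rep(c("plasma", "RBC"), each = nrow(object)))
    ggplot2::ggplot(df, ggplot2::aes(x = .data$y, y = .data$u,
                                     colour = .data$phase)) +
      ggplot2::geom_line() +
      ggplot2::labs(x = "transverse position y (µm)",
                    y = "axial velocity (m/s)",
                    title = sprintf("Axial velocity at x = %g µm",
                                    xs * 1e6)) +
      ggplot2::theme_minimal()
  }
}

#' @importFrom ggplot2 .data
NULL
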
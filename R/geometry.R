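#' Cosine-profile stenosed microvessel geometry
#'
#' Parametric description of an axisymmetric (or planar) microvessel with a
#' smooth cosine constriction centered at x = 0. The wall ordinate is
#' \deqn{y(x) = \frac{H+h_s}{2} - \frac{H-h_s}{2}\cos\left(\frac{2\pi x}{L_s}\right)}
#' for |x| <= Ls/2 and y = H outside the stenosed segment, so y(0) = hs
#' (the throat) and y(+/- Ls/2) = H, continuously.
#'
#' The default parameters are H = 50 um, hs = 25 um, Ls = 70 um with 500 um of
#' straight vessel both upstream and downstream of the throat, giving the
#' stenosed-height ratio eta_h = hs/H = 0.5 and stenosed-length ratio
#' eta_L = Ls/H = 1.4.
#'
#' @param H Unobstructed half-height (planar) or radius (axisymmetric), m.
#' @param hs Minimum half-height/radius at the throat, m; 0 < hs < H.
#' @param Ls Axial length of the stenosed segment, m.
#' @param L_up,L_down Straight entry/exit lengths measured from the throat, m.
#' @param mode `"axisymmetric"` (tube; y is the radial coordinate) or
#'   `"planar"` (channel half-model with a symmetry plane at y = 0).
#' @return An object of class `stenosis_geometry`.
#' @examples
#' geom <- stenosis_geometry()
#' dimensionless_ratios(geom)               # eta_h = 0.5, eta_L = 1.4
#' stenosis_wall_radius(0, geom)            # 25e-6 (throat)
#' stenosis_wall_radius(geom$Ls / 2, geom)  # 50e-6 (= H)
#' @export
stenosis_geometry <- function(H = 50e-6, hs = 25e-6, Ls = 70e-6,
                              L_up = 500e-6, L_down = 500e-6,
                              mode = c("axisymmetric", "planar")) {
  mode <- match.arg(mode)
  stopifnot(H > 0, Ls > 0, L_up > 0, L_down > 0)
  if (!(hs > 0 && hs <= H)) stop("stenosis requires 0 < hs <= H")
  if (Ls / 2 > L_up || Ls / 2 > L_down) {
    stop("stenosed segment must fit inside the entry/exit lengths")
  }
  structure(
    list(H = H, hs = hs, Ls = Ls, L_up = L_up, L_down = L_down, mode = mode),
    class = c("stenosis_geometry", "case_geometry")
  )
}

#' @export
print.stenosis_geometry <- function(x, ...) {
  r <- dimensionless_ratios(x)
  cat(sprintf(
    "<stenosis_geometry> %s: H=%g m, hs=%g m, Ls=%g m (eta_h=%.3g, eta_L=%.3g), x in [%g, %g] m\n",
    x$mode, x$H, x$hs, x$Ls, r[["eta_h"]], r[["eta_L"]], -x$L_up, x$L_down))
  invisible(x)
}

#' Wall ordinate of the stenosis profile
#'
#' Evaluates the piecewise cosine wall profile of a [stenosis_geometry] at
#' axial positions `x` (origin at the throat).
#'
#' @param x Axial coordinate(s), m, within `[-L_up, L_down]`.
#' @param geom A [stenosis_geometry].
#' @return Wall ordinate(s) y(x), m.
#' @export
stenosis_wall_radius <- function(x, geom) {
  stopifnot(inherits(geom, "stenosis_geometry"))
  if (any(x < -geom$L_up - 1e-12 * geom$H) ||
      any(x > geom$L_down + 1e-12 * geom$H)) {
    stop("x outside the vessel domain [-L_up, L_down]")
  }
  y <- rep(geom$H, length(x))
  inside <- abs(x) <= geom$Ls / 2
  y[inside] <- (geom$H + geom$hs) / 2 -
    (geom$H - geom$hs) / 2 * cos(2 * pi * x[inside] / geom$Ls)
  y
}

#' Dimensionless stenosis ratios
#'
#' Returns the stenosed-height ratio `eta_h = hs / H` and stenosed-length
#' ratio `eta_L = Ls / H`.
#'
#' @param geom A [stenosis_geometry].
#' @return Named numeric vector `c(eta_h = , eta_L = )`.
#' @export
dimensionless_ratios <- function(geom) {
  stopifnot(inherits(geom, "stenosis_geometry"))
  c(eta_h = geom$hs / geom$H, eta_L = geom$Ls / geom$H)
}

#' Sudden-expansion channel geometry
#'
#' Planar half-model of a rectangular microvessel with a 1:2 sudden expansion:
#' an upstream channel of half-height `h_up` and length `L_up` opening at
#' x = 0 into a downstream channel of half-height `h_down` and length
#' `L_down`. The centerline y = 0 is a symmetry plane; the stepped upper
#' boundary is a no-slip wall. Defaults follow the benchmark configuration:
#' full heights 100 um / 200 um (half-model 50 um / 100 um), lengths
#' 1 mm / 2 mm.
#'
#' @param h_up,h_down Upstream/downstream half-heights, m (`h_down > h_up`).
#' @param L_up,L_down Upstream/downstream lengths, m.
#' @return An object of class `expansion_geometry`.
#' @export
expansion_geometry <- function(h_up = 50e-6, h_down = 100e-6,
                               L_up = 1e-3, L_down = 2e-3) {
  stopifnot(h_up > 0, L_up > 0, L_down > 0)
  if (!(h_down > h_up)) stop("expansion requires h_down > h_up")
  structure(
    list(h_up = h_up, h_down = h_down, L_up = L_up, L_down = L_down,
         mode = "planar"),
    class = c("expansion_geometry", "case_geometry")
  )
}

#' @export
print.expansion_geometry <- function(x, ...) {
  cat(sprintf(
    "<expansion_geometry> planar half-model: %g -> %g m half-height at x=0, x in [%g, %g] m\n",
    x$h_up, x$h_down, -x$L_up, x$L_down))
  invisible(x)
}
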
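## Body-fitted structured finite-volume grids.
##
## A grid is one or two structured quadrilateral blocks flattened into a
## single global cell list plus an explicit face list (owner/neighbour with
## outward area vectors) consumed by the collocated FV solver. Cell and block
## indices are 1-based. Every face is stored with directed endpoints
## P1 -> P2 chosen so the owner cell lies to the LEFT of the edge; the area
## vector S = (dy, -dx) then points outward from the owner (toward the
## neighbour on interior faces). Two metric sets are kept: planar area
## vectors (used by Green-Gauss gradients, which are local differential
## operators) and mode-weighted ones (axisymmetric: multiplied by the
## face-midpoint radius, i.e. per-radian fluxes). Axisymmetric cell volumes
## are exact per-radian integrals of r over each quad.

## exact planar area, per-radian volume and centroid of CCW quads
quad_metrics <- function(px, py) {
  nxt <- c(2L, 3L, 4L, 1L)
  A <- 0; V <- 0; Cx <- 0; Cy <- 0
  for (k in 1:4) {
    x1 <- px[, k]; y1 <- py[, k]
    x2 <- px[, nxt[k]]; y2 <- py[, nxt[k]]
    cross <- x1 * y2 - x2 * y1
    A <- A + cross / 2
    V <- V - (x2 - x1) * (y1^2 + y1 * y2 + y2^2) / 6
    Cx <- Cx + (x1 + x2) * cross
    Cy <- Cy + (y1 + y2) * cross
  }
  list(area = A, vol_axi = V, cx = Cx / (6 * A), cy = Cy / (6 * A))
}

## Assemble an fv_grid from one or two structured blocks.
## blocks[[b]]: list(X, Y, tags = list(imin, imax, jmin, jmax))
## interfaces: list of c(a, b): block a's imax glued to block b's imin over
## the lower conforming span of b (remaining span of b's imin is a wall).
build_fv_grid <- function(blocks, mode, interfaces = list(), geom = NULL) {
  nb <- length(blocks)
  ncell_b <- vapply(blocks, function(b) (nrow(b$X) - 1L) * (ncol(b$X) - 1L),
                    integer(1))
  offset <- c(0L, cumsum(ncell_b))[seq_len(nb)]
  cell_id <- vector("list", nb)
  px <- py <- NULL
  for (b in seq_len(nb)) {
    X <- blocks[[b]]$X; Y <- blocks[[b]]$Y
    nx <- nrow(X) - 1L; ny <- ncol(X) - 1L
    cell_id[[b]] <- matrix(seq_len(nx * ny) + offset[b], nx, ny)
    ii <- rep(seq_len(nx), ny); jj <- rep(seq_len(ny), each = nx)
    px <- rbind(px, cbind(X[cbind(ii, jj)], X[cbind(ii + 1L, jj)],
                          X[cbind(ii + 1L, jj + 1L)], X[cbind(ii, jj + 1L)]))
    py <- rbind(py, cbind(Y[cbind(ii, jj)], Y[cbind(ii + 1L, jj)],
                          Y[cbind(ii + 1L, jj + 1L)], Y[cbind(ii, jj + 1L)]))
  }
  qm <- quad_metrics(px, py)
  if (any(qm$area <= 0)) stop("degenerate grid: non-positive cell area")
  vol_plan <- qm$area
  vol <- if (mode == "axisymmetric") qm$vol_axi else qm$area
  if (any(vol <= 0)) stop("degenerate grid: non-positive cell volume")
  xc <- qm$cx; yc <- qm$cy
  n <- length(xc)

  glued_imax <- rep(FALSE, nb); glued_imin <- vector("list", nb)
  for (pair in interfaces) {
    a <- pair[1]; b <- pair[2]
    nya <- ncol(blocks[[a]]$X) - 1L
    ya <- blocks[[a]]$Y[nrow(blocks[[a]]$Y), ]
    yb <- blocks[[b]]$Y[1, seq_len(nya + 1L)]
    if (ncol(blocks[[b]]$X) - 1L < nya ||
        max(abs(ya - yb)) > 1e-9 * max(abs(ya), 1e-12)) {
      stop("non-conforming block resolutions at interface")
    }
    glued_imax[a] <- TRUE
    glued_imin[[b]] <- list(other = a, span = nya)
  }

  fo <- fn <- integer(0)
  e1x <- e1y <- e2x <- e2y <- numeric(0)
  ftag <- character(0)
  add <- function(o, nbr, x1, y1, x2, y2, tag) {
    m <- length(o)
    fo <<- c(fo, o); fn <<- c(fn, nbr)
    e1x <<- c(e1x, x1); e1y <<- c(e1y, y1)
    e2x <<- c(e2x, x2); e2y <<- c(e2y, y2)
    ftag <<- c(ftag, rep_len(tag, m))
  }
  for (b in seq_len(nb)) {
    X <- blocks[[b]]$X; Y <- blocks[[b]]$Y
    nx <- nrow(X) - 1L; ny <- ncol(X) - 1L
    id <- cell_id[[b]]; tg <- blocks[[b]]$tags
    j <- seq_len(ny); i <- seq_len(nx)
    ## interior i-faces: owner (i-1,j) left of edge (i,j)->(i,j+1)
    for (ii in 2:nx) {
      add(id[ii - 1L, j], id[ii, j],
          X[ii, j], Y[ii, j], X[ii, j + 1L], Y[ii, j + 1L], "interior")
    }
    ## imin boundary: owner (1,j), outward -x: edge (1,j+1)->(1,j)
    if (is.null(glued_imin[[b]])) {
      add(id[1L, j], rep(NA_integer_, ny),
          X[1L, j + 1L], Y[1L, j + 1L], X[1L, j], Y[1L, j], tg$imin)
    } else {
      gl <- glued_imin[[b]]; sp <- gl$span
      oth <- cell_id[[gl$other]]
      js <- seq_len(sp)
      add(oth[nrow(oth), js], id[1L, js],
          X[1L, js], Y[1L, js], X[1L, js + 1L], Y[1L, js + 1L], "interior")
      if (sp < ny) {
        jw <- (sp + 1L):ny
        add(id[1L, jw], rep(NA_integer_, length(jw)),
            X[1L, jw + 1L], Y[1L, jw + 1L], X[1L, jw], Y[1L, jw], "wall")
      }
    }
    ## imax boundary: owner (nx,j), outward +x: edge (nx+1,j)->(nx+1,j+1)
    if (!glued_imax[b]) {
      add(id[nx, j], rep(NA_integer_, ny),
          X[nx + 1L, j], Y[nx + 1L, j], X[nx + 1L, j + 1L], Y[nx + 1L, j + 1L],
          tg$imax)
    }
    ## interior j-faces: owner (i,j-1) below; left-of-edge rule needs -x
    ## traversal: edge (i+1,jj)->(i,jj)
    for (jj in 2:ny) {
      add(id[i, jj - 1L], id[i, jj],
          X[i + 1L, jj], Y[i + 1L, jj], X[i, jj], Y[i, jj], "interior")
    }
    ## jmin boundary: owner (i,1), outward -y: edge (i,1)->(i+1,1)
    add(id[i, 1L], rep(NA_integer_, nx),
        X[i, 1L], Y[i, 1L], X[i + 1L, 1L], Y[i + 1L, 1L], tg$jmin)
    ## jmax boundary: owner (i,ny), outward +y: edge (i+1,ny+1)->(i,ny+1)
    add(id[i, ny], rep(NA_integer_, nx),
        X[i + 1L, ny + 1L], Y[i + 1L, ny + 1L], X[i, ny + 1L], Y[i, ny + 1L],
        tg$jmax)
  }

  dx <- e2x - e1x; dy <- e2y - e1y
  Spx <- dy; Spy <- -dx
  xm <- (e1x + e2x) / 2; ym <- (e1y + e2y) / 2
  w_axi <- if (mode == "axisymmetric") ym else 1
  Sx <- Spx * w_axi; Sy <- Spy * w_axi
  int <- !is.na(fn)
  ## owner -> neighbour (or face-midpoint) displacement
  dcx <- ifelse(int, xc[ifelse(int, fn, 1L)] - xc[fo], xm - xc[fo])
  dcy <- ifelse(int, yc[ifelse(int, fn, 1L)] - yc[fo], ym - yc[fo])
  dn <- sqrt(dcx^2 + dcy^2)
  ## distance-weighted interpolation factor (owner weight)
  do_f <- sqrt((xm - xc[fo])^2 + (ym - yc[fo])^2)
  dn_f <- ifelse(int, sqrt((xm - xc[ifelse(int, fn, 1L)])^2 +
                             (ym - yc[ifelse(int, fn, 1L)])^2), 0)
  wf <- ifelse(int, dn_f / pmax(do_f + dn_f, 1e-300), 1)

  nf <- length(fo)
  face_div <- Matrix::sparseMatrix(
    i = c(fo, fn[int]), j = c(seq_len(nf), which(int)),
    x = c(rep(1, nf), rep(-1, sum(int))), dims = c(n, nf))
  face_interp <- Matrix::sparseMatrix(
    i = c(seq_len(nf), which(int)),
    j = c(fo, fn[int]),
    x = c(wf, 1 - wf[int]), dims = c(nf, n))

  g <- list(
    mode = mode, n = n, geom = geom,
    blocks = lapply(seq_len(nb), function(b) {
      list(X = blocks[[b]]$X, Y = blocks[[b]]$Y, cell_id = cell_id[[b]],
           nx = nrow(blocks[[b]]$X) - 1L, ny = ncol(blocks[[b]]$X) - 1L)
    }),
    xc = xc, yc = yc, vol = vol, vol_plan = vol_plan,
    face = list(owner = fo, neigh = fn, tag = ftag, interior = int,
                Sx = Sx, Sy = Sy, Spx = Spx, Spy = Spy,
                xm = xm, ym = ym, len = sqrt(dx^2 + dy^2),
                area = sqrt(Sx^2 + Sy^2),
                dcx = dcx, dcy = dcy, dn = dn, wf = wf),
    face_div = face_div, face_interp = face_interp
  )
  ## wall faces ordered by axial position, with arc-length coordinate
  iw <- which(ftag == "wall")
  iw <- iw[order(xm[iw], ym[iw])]
  s <- c(0, cumsum(sqrt(diff(xm[iw])^2 + diff(ym[iw])^2)))
  g$wall <- list(faces = iw, s = s)
  class(g) <- "fv_grid"
  g
}

#' @export
print.fv_grid <- function(x, ...) {
  cat(sprintf("<fv_grid> %s, %d cells in %d block(s), %d faces\n",
              x$mode, x$n, length(x$blocks), length(x$face$owner)))
  invisible(x)
}

## one-sided stretching of [0,1]: beta > 0 clusters points near eta = 1
## (the wall end), beta < 0 clusters near eta = 0 (the axis/core)
stretch_wallward <- function(eta, beta) {
  if (beta == 0) return(eta)
  if (beta > 0) tanh(beta * eta) / tanh(beta)
  else 1 - tanh(-beta * (1 - eta)) / tanh(-beta)
}

#' Build a body-fitted grid for the stenosed vessel
#'
#' Algebraic transfinite grid: `nx` columns along the axis (optionally
#' concentrated near the throat) each mapped from the centerline/axis
#' (y = 0) to the local wall ordinate [stenosis_wall_radius], with optional
#' wall-normal clustering.
#'
#' @param geom A [stenosis_geometry].
#' @param nx,ny Cell counts in the axial and transverse directions (>= 4).
#' @param cluster_wall Wall-normal stretching strength: 0 gives uniform
#'   spacing, positive values (~1.5) concentrate cells near the wall,
#'   negative values concentrate them near the axis/core (coarser wall
#'   cells, which the segregated two-fluid iteration tolerates better in
#'   the strongly sheared throat region).
#' @param cluster_throat Axial refinement factor near the stenosed segment
#'   (1 = uniform spacing; 3 concentrates roughly three times finer spacing
#'   around the throat).
#' @return An object of class `fv_grid`.
#' @examples
#' g <- build_stenosis_grid(stenosis_geometry(), nx = 8, ny = 4)
#' g$n  # 32 cells
#' @export
build_stenosis_grid <- function(geom, nx, ny, cluster_wall = 0,
                                cluster_throat = 1) {
  stopifnot(inherits(geom, "stenosis_geometry"), nx >= 4, ny >= 4)
  if (geom$hs <= 0) stop("degenerate geometry: hs <= 0")
  ## axial node distribution via inverse CDF of a throat-peaked density
  if (cluster_throat > 1) {
    xs <- seq(-geom$L_up, geom$L_down, length.out = 4096)
    wdens <- 1 + (cluster_throat - 1) * exp(-2 * (xs / geom$Ls)^2)
    cdf <- cumsum(wdens); cdf <- (cdf - cdf[1]) / (cdf[length(cdf)] - cdf[1])
    xn <- stats::approx(cdf, xs, xout = seq(0, 1, length.out = nx + 1))$y
    xn[1] <- -geom$L_up; xn[nx + 1] <- geom$L_down
  } else {
    xn <- seq(-geom$L_up, geom$L_down, length.out = nx + 1)
  }
  eta <- stretch_wallward(seq(0, 1, length.out = ny + 1), cluster_wall)
  yw <- stenosis_wall_radius(xn, geom)
  X <- matrix(xn, nx + 1, ny + 1)
  Y <- outer(yw, eta)
  jmin <- if (geom$mode == "axisymmetric") "symmetry" else "symmetry"
  blocks <- list(list(X = X, Y = Y,
                      tags = list(imin = "inlet", imax = "outlet",
                                  jmin = jmin, jmax = "wall")))
  build_fv_grid(blocks, mode = geom$mode, geom = geom)
}

#' Build a two-block grid for the sudden-expansion channel
#'
#' Conforming two-block grid: an upstream block over the narrow channel and a
#' downstream block over the wide one, sharing the interface at the expansion
#' corner x = 0. The vertical spacing must match across the interface, i.e.
#' `ny_down / ny_up` must equal `h_down / h_up` (an error is raised
#' otherwise). The step face at x = 0 above the narrow channel is a wall.
#'
#' @param geom An [expansion_geometry].
#' @param nx_up,ny_up Upstream block cell counts.
#' @param nx_down,ny_down Downstream block cell counts (`ny_down` defaults to
#'   the conforming value).
#' @return An object of class `fv_grid`.
#' @export
build_expansion_grid <- function(geom, nx_up, ny_up,
                                 nx_down = 2 * nx_up,
                                 ny_down = NULL) {
  stopifnot(inherits(geom, "expansion_geometry"),
            nx_up >= 4, ny_up >= 4, nx_down >= 4)
  ratio <- geom$h_down / geom$h_up
  if (is.null(ny_down)) ny_down <- as.integer(round(ny_up * ratio))
  if (abs(ny_down / ny_up - ratio) > 1e-9) {
    stop("non-conforming block resolutions: need ny_down/ny_up = h_down/h_up")
  }
  X1 <- matrix(seq(-geom$L_up, 0, length.out = nx_up + 1), nx_up + 1, ny_up + 1)
  Y1 <- matrix(seq(0, geom$h_up, length.out = ny_up + 1), nx_up + 1,
               ny_up + 1, byrow = TRUE)
  X2 <- matrix(seq(0, geom$L_down, length.out = nx_down + 1), nx_down + 1,
               ny_down + 1)
  Y2 <- matrix(seq(0, geom$h_down, length.out = ny_down + 1), nx_down + 1,
               ny_down + 1, byrow = TRUE)
  blocks <- list(
    list(X = X1, Y = Y1, tags = list(imin = "inlet", imax = "interface",
                                     jmin = "symmetry", jmax = "wall")),
    list(X = X2, Y = Y2, tags = list(imin = "interface", imax = "outlet",
                                     jmin = "symmetry", jmax = "wall"))
  )
  build_fv_grid(blocks, mode = "planar", interfaces = list(c(1L, 2L)),
                geom = geom)
}

#' Geometric closure residual of a grid
#'
#' For every cell, sums the outward face area vectors. In planar mode the sum
#' is zero for a closed polygon; in axisymmetric (per-radian) mode the lateral
#' faces close against the hoop contribution, so the identity is
#' `sum(S) = (0, A_planar)`. Returns the maximum residual magnitude
#' normalized by the largest face area, which should be at machine-precision
#' level on a valid grid.
#'
#' @param grid An `fv_grid`.
#' @return Scalar dimensionless residual.
#' @export
grid_closure_residual <- function(grid) {
  f <- grid$face
  sx <- as.numeric(grid$face_div %*% f$Sx)
  ## face_div subtracts neighbour contributions; per-cell outward sums need
  ## +S for owner and -(-S)=+... the neighbour's outward face is -S, so the
  ## per-cell outward sum is exactly what face_div gives for owner rows and
  ## the negative for neighbours: face_div already encodes owner +1 / neigh -1,
  ## which matches "outward from each cell".
  sy <- as.numeric(grid$face_div %*% f$Sy)
  if (grid$mode == "axisymmetric") sy <- sy - grid$vol_plan
  max(sqrt(sx^2 + sy^2)) / max(f$area)
}

## wall ordinate function for any case geometry
wall_ordinate <- function(geom, x) {
  if (inherits(geom, "stenosis_geometry")) {
    stenosis_wall_radius(x, geom)
  } else {
    ifelse(x < 0, geom$h_up, geom$h_down)
  }
}
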
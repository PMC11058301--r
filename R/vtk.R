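## Legacy ASCII VTK structured-grid output (one file per grid block).
## Point data are obtained from the cell fields by averaging the cells
## adjacent to each node (1, 2 or 4 of them). Values are printed with 17
## significant digits so a re-read reproduces the fields bit-exactly.

## cell field (length n) -> node matrix ((nx+1) x (ny+1)) for block b
cells_to_nodes <- function(grid, b, vals) {
  blk <- grid$blocks[[b]]
  nx <- blk$nx; ny <- blk$ny
  V <- matrix(vals[blk$cell_id], nx, ny)
  acc <- matrix(0, nx + 1, ny + 1)
  cnt <- matrix(0, nx + 1, ny + 1)
  for (di in 0:1) for (dj in 0:1) {
    acc[(1:nx) + di, (1:ny) + dj] <- acc[(1:nx) + di, (1:ny) + dj] + V
    cnt[(1:nx) + di, (1:ny) + dj] <- cnt[(1:nx) + di, (1:ny) + dj] + 1
  }
  acc / cnt
}

num17 <- function(x) sprintf("%.17g", x)

#' Write one grid block as a legacy VTK structured grid
#'
#' ASCII legacy-format `STRUCTURED_GRID` with point data `p`, `phi` (scalars)
#' and `vp`, `vr` (vectors, z = 0), node values averaged from the adjacent
#' cells. A file written by this function is re-read bit-exactly by
#' [read_vtk_structured].
#'
#' @param grid An `fv_grid`.
#' @param b Block index.
#' @param state A `flow_state` (fields `p`, `phi`, `vp`, `vr`).
#' @param file Output path.
#' @return Invisibly, `file`.
#' @export
write_vtk_structured <- function(grid, b, state, file) {
  blk <- grid$blocks[[b]]
  nx1 <- blk$nx + 1L; ny1 <- blk$ny + 1L
  con <- file(file, "w")
  on.exit(close(con))
  wl <- function(...) writeLines(c(...), con)
  wl("# vtk DataFile Version 3.0",
     "two-fluid microvessel flow fields",
     "ASCII",
     "DATASET STRUCTURED_GRID",
     sprintf("DIMENSIONS %d %d 1", nx1, ny1),
     sprintf("POINTS %d double", nx1 * ny1))
  ## VTK point ordering: x fastest, then y
  xs <- as.vector(blk$X); ys <- as.vector(blk$Y)
  wl(paste(num17(xs), num17(ys), "0"))
  wl(sprintf("POINT_DATA %d", nx1 * ny1))
  scalars <- list(p = state$p, phi = state$phi)
  for (nm in names(scalars)) {
    nv <- as.vector(cells_to_nodes(grid, b, scalars[[nm]]))
    wl(sprintf("SCALARS %s double 1", nm), "LOOKUP_TABLE default")
    wl(num17(nv))
  }
  vectors <- list(vp = state$vp, vr = state$vr)
  for (nm in names(vectors)) {
    vx <- as.vector(cells_to_nodes(grid, b, vectors[[nm]][, 1]))
    vy <- as.vector(cells_to_nodes(grid, b, vectors[[nm]][, 2]))
    wl(sprintf("VECTORS %s double", nm))
    wl(paste(num17(vx), num17(vy), "0"))
  }
  invisible(file)
}

#' Read back a legacy VTK structured grid written by [write_vtk_structured]
#'
#' @param file Path to the VTK file.
#' @return List with `dims`, `points` (matrix x, y, z) and `data` (named list
#'   of scalar vectors / vector matrices in point order).
#' @export
read_vtk_structured <- function(file) {
  ln <- readLines(file)
  dims <- as.integer(strsplit(trimws(sub("DIMENSIONS", "", ln[5])),
                              "\\s+")[[1]])
  npts <- prod(dims)
  stopifnot(grepl("^POINTS", ln[6]))
  pts <- ln[7:(6 + npts)]
  pm <- matrix(as.numeric(unlist(strsplit(pts, "\\s+"))), ncol = 3,
               byrow = TRUE)
  i <- 6 + npts + 1
  stopifnot(grepl("^POINT_DATA", ln[i]))
  i <- i + 1
  data <- list()
  while (i <= length(ln)) {
    if (grepl("^SCALARS", ln[i])) {
      nm <- strsplit(ln[i], "\\s+")[[1]][2]
      i <- i + 2  # skip LOOKUP_TABLE
      data[[nm]] <- as.numeric(ln[i:(i + npts - 1)])
      i <- i + npts
    } else if (grepl("^VECTORS", ln[i])) {
      nm <- strsplit(ln[i], "\\s+")[[1]][2]
      vm <- matrix(as.numeric(unlist(strsplit(ln[(i + 1):(i + npts)],
                                              "\\s+"))),
                   ncol = 3, byrow = TRUE)
      data[[nm]] <- vm[, 1:2]
      i <- i + npts + 1
    } else {
      i <- i + 1
    }
  }
  list(dims = dims, points = pm, data = data)
}
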
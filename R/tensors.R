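#' Cell-wise 2D tensor fields
#'
#' A `tensor_field` stores per-cell 2x2 tensor components (`xx`, `xy`, `yx`,
#' `yy`) plus an explicit hoop component `tt` used in axisymmetric mode.
#' Symmetric-part fields (strain rates, stresses) satisfy `xy == yx`; spin
#' tensors are antisymmetric with `xx == yy == tt == 0`.
#'
#' @param xx,xy,yy Component vectors (recycled to a common length).
#' @param yx The (2,1) component; defaults to `xy` (symmetric tensor).
#' @param tt The hoop (theta-theta) component; defaults to 0 (planar).
#' @return An object of class `tensor_field`: a list of equal-length component
#'   vectors.
#' @examples
#' D <- tensor_field(xx = 0, xy = 5, yy = 0)   # simple shear du/dy = 10/s
#' generalized_shear_rate(D)
#' @export
tensor_field <- function(xx, xy, yy, yx = xy, tt = 0) {
  n <- max(length(xx), length(xy), length(yy), length(yx), length(tt))
  out <- list(
    xx = rep_len(as.numeric(xx), n),
    xy = rep_len(as.numeric(xy), n),
    yx = rep_len(as.numeric(yx), n),
    yy = rep_len(as.numeric(yy), n),
    tt = rep_len(as.numeric(tt), n)
  )
  class(out) <- "tensor_field"
  out
}

#' @export
print.tensor_field <- function(x, ...) {
  cat(sprintf("<tensor_field> %d cells\n", length(x$xx)))
  invisible(x)
}

#' @export
length.tensor_field <- function(x) length(x$xx)

#' Tensor-vector product per cell
#'
#' Computes `T %*% v` cell-wise for a [tensor_field] and an n x 2 vector
#' field (the hoop component does not enter the in-plane product).
#'
#' @param tf A [tensor_field].
#' @param v An n x 2 matrix of vectors.
#' @return An n x 2 matrix.
#' @export
tensor_vector_product <- function(tf, v) {
  v <- as_vector_field(v, length(tf$xx))
  cbind(tf$xx * v[, 1] + tf$xy * v[, 2],
        tf$yx * v[, 1] + tf$yy * v[, 2])
}

## coerce scalars / vectors to an n x 2 vector-field matrix
as_vector_field <- function(v, n) {
  if (is.matrix(v)) {
    stopifnot(ncol(v) == 2)
    if (nrow(v) == 1L) v <- matrix(v, n, 2, byrow = TRUE)
    stopifnot(nrow(v) == n)
    return(v)
  }
  stopifnot(length(v) == 2)
  matrix(v, n, 2, byrow = TRUE)
}

## maximum absolute asymmetry |xy - yx| relative to scale
tensor_asymmetry <- function(tf) {
  scale <- max(abs(unlist(tf[c("xx", "xy", "yx", "yy")])), 1e-300)
  max(abs(tf$xy - tf$yx)) / scale
}
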
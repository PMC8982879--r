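# Internal helpers shared across modules.

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a

#' Apply a function elementwise over two parallel nested lists of arrays.
#' @keywords internal
param_map2 <- function(f, a, b) {
  if (is.list(a)) {
    stopifnot(is.list(b), length(a) == length(b))
    out <- mapply(function(x, y) param_map2(f, x, y), a, b, SIMPLIFY = FALSE)
    names(out) <- names(a)
    out
  } else if (is.null(a)) {
    NULL
  } else {
    f(a, b)
  }
}

#' Apply a function elementwise over one nested list of arrays.
#' @keywords internal
param_map1 <- function(f, a) {
  if (is.list(a)) {
    out <- lapply(a, function(x) param_map1(f, x))
    names(out) <- names(a)
    out
  } else if (is.null(a)) {
    NULL
  } else {
    f(a)
  }
}

#' Check two nested parameter lists have identical structure.
#' @keywords internal
param_same_shape <- function(a, b) {
  if (is.list(a) != is.list(b)) return(FALSE)
  if (is.list(a)) {
    if (length(a) != length(b) || !identical(names(a), names(b))) return(FALSE)
    all(mapply(param_same_shape, a, b))
  } else if (is.null(a) || is.null(b)) {
    is.null(a) && is.null(b)
  } else {
    identical(dim(a) %||% length(a), dim(b) %||% length(b))
  }
}

#' Draw a uniformly random proper rotation matrix (det = +1).
#'
#' Uses the QR decomposition of a Gaussian matrix with sign correction,
#' which gives Haar-distributed rotations.
#' @param n dimension (default 3)
#' @return an n x n orthonormal matrix with determinant +1
#' @export
random_rotation <- function(n = 3) {
  qr_ <- qr(matrix(stats::rnorm(n * n), n, n))
  q <- qr.Q(qr_)
  d <- sign(diag(qr.R(qr_)))
  d[d == 0] <- 1
  q <- q %*% diag(d, n)
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

#' Apply a rigid (rotation + translation) transform to coordinates.
#'
#' @param coords N x 3 coordinate matrix
#' @param rotation 3 x 3 rotation matrix
#' @param translation length-3 vector
#' @return transformed N x 3 matrix
#' @export
rigid_transform <- function(coords, rotation, translation = c(0, 0, 0)) {
  stopifnot(ncol(coords) == 3)
  sweep(coords %*% t(rotation), 2, translation, `+`)
}

#' @keywords internal
unit_vector <- function(x) {
  nrm <- sqrt(sum(x^2))
  if (nrm == 0) stop("cannot normalize a zero-norm vector")
  x / nrm
}

#' @keywords internal
row_normalize <- function(m) {
  nrm <- sqrt(rowSums(m^2))
  nrm[nrm == 0] <- 1
  m / nrm
}
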
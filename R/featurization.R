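# Complete C-alpha graph construction and invariant raw node features.
#
# A structure of N_r residues becomes (i) a dense N_r x N_r adjacency matrix
# A_ij = omega / max(D_ij, epsilon) over C-alpha Euclidean distances, and
# (ii) an N_r x 2^M raw node-feature matrix: 2^M - 1 distances from each
# residue to a hierarchy of fragment-centroid reference points, plus one
# bend-angle cosine column. Both are invariant to rigid motions of the input
# coordinates because they only involve distances and angles.

#' Build the normalized complete-graph adjacency matrix
#'
#' `A_ij = omega / max(D_ij, epsilon)` where `D_ij` is the Euclidean
#' C-alpha--C-alpha distance. With the defaults `omega = 4, epsilon = 2`
#' every entry lies in (0, 2] and the diagonal equals 2, which builds the
#' self-loop and the normalization into the graph itself; no further row
#' normalization is applied.
#'
#' @param coords N x 3 coordinate matrix.
#' @param omega,epsilon positive normalization constants.
#' @return symmetric N x N matrix.
#' @export
build_adjacency <- function(coords, omega = 4, epsilon = 2) {
  coords <- as.matrix(coords)
  if (!all(is.finite(coords))) stop("non-finite coordinates")
  if (nrow(coords) < 1) stop("need at least one coordinate")
  stopifnot(omega > 0, epsilon > 0)
  d <- as.matrix(stats::dist(coords))
  omega / pmax(d, epsilon)
}

#' Hierarchical fragment-centroid reference points
#'
#' Reference points are organized in `M` groups; group `m` (0-based) holds
#' `2^m` points, the centroids of `2^m` contiguous chain fragments. Fragment
#' `g` of group `m` covers 0-based residue indices
#' `[floor((g-1) N_r / 2^m), ceiling(g N_r / 2^m))`. Points are returned in
#' (m ascending, g ascending) order, `2^M - 1` in total; the first point is
#' the centroid of the whole chain.
#'
#' @param coords N x 3 coordinate matrix.
#' @param M number of groups (default 5, i.e. 31 reference points).
#' @return (2^M - 1) x 3 matrix of reference-point coordinates.
#' @export
compute_reference_points <- function(coords, M = 5) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  if (n < 2^(M - 1)) {
    stop("structure has ", n, " residues; at least ", 2^(M - 1),
         " are required for M = ", M)
  }
  pts <- matrix(0, 2^M - 1, 3)
  t <- 1L
  for (m in 0:(M - 1)) {
    for (g in 1:(2^m)) {
      lo <- floor((g - 1) * n / 2^m)        # 0-based inclusive
      hi <- ceiling(g * n / 2^m)            # 0-based exclusive
      frag <- coords[(lo + 1):hi, , drop = FALSE]
      pts[t, ] <- colMeans(frag)
      t <- t + 1L
    }
  }
  pts
}

#' Distance-based raw node features
#'
#' Row i holds the Euclidean distances from residue i to each of the
#' `2^M - 1` reference points of [compute_reference_points].
#'
#' @inheritParams compute_reference_points
#' @return N x (2^M - 1) matrix.
#' @export
distance_node_features <- function(coords, M = 5) {
  coords <- as.matrix(coords)
  p <- compute_reference_points(coords, M)
  # ||v_i - p_t|| for all i, t at once
  cross <- coords %*% t(p)
  d2 <- outer(rowSums(coords^2), rowSums(p^2), `+`) - 2 * cross
  sqrt(pmax(d2, 0))
}

#' Bend-angle cosine node feature
#'
#' For interior residue i the feature is the cosine of the angle between the
#' two consecutive virtual bonds, `cos(theta_i) = (v_i - v_{i-1}) . (v_{i+1}
#' - v_i) / (|v_i - v_{i-1}| |v_{i+1} - v_i|)`. Terminal residues get 0;
#' a zero-length segment (duplicate coordinates) also yields 0 with a
#' warning.
#'
#' @param coords N x 3 coordinate matrix.
#' @return length-N numeric vector.
#' @export
angle_node_features <- function(coords) {
  coords <- as.matrix(coords)
  if (!all(is.finite(coords))) stop("non-finite coordinates")
  n <- nrow(coords)
  out <- numeric(n)
  if (n < 3) return(out)
  seg <- coords[-1, , drop = FALSE] - coords[-n, , drop = FALSE]  # (n-1) x 3
  len <- sqrt(rowSums(seg^2))
  dots <- rowSums(seg[-(n - 1), , drop = FALSE] * seg[-1, , drop = FALSE])
  denom <- len[-(n - 1)] * len[-1]
  zero <- denom == 0
  if (any(zero)) {
    warning("zero-length C-alpha segment(s); angle feature set to 0")
    denom[zero] <- 1
    dots[zero] <- 0
  }
  out[2:(n - 1)] <- dots / denom
  out
}

#' Featurize a structure into its graph representation
#'
#' Combines [build_adjacency] with the raw node features: `2^M - 1` distance
#' columns followed by one angle column, `d = 2^M` columns in total (32 at
#' the default `M = 5`).
#'
#' @param s a [protein_structure].
#' @param M reference-point group count.
#' @param omega,epsilon adjacency normalization constants.
#' @return an object of class `structure_graph` with fields `structure_id`,
#'   `adjacency`, `node_features`, `n_residues`.
#' @export
featurize <- function(s, M = 5, omega = 4, epsilon = 2) {
  stopifnot(inherits(s, "protein_structure"))
  x <- cbind(distance_node_features(s$ca_coords, M),
             angle_node_features(s$ca_coords))
  structure(
    list(structure_id = s$id,
         adjacency = build_adjacency(s$ca_coords, omega, epsilon),
         node_features = x,
         n_residues = s$n_residues),
    class = "structure_graph"
  )
}

#' @export
print.structure_graph <- function(x, ...) {
  cat(sprintf("<structure_graph> %s: %d nodes, %d raw features\n",
              x$structure_id, x$n_residues, ncol(x$node_features)))
  invisible(x)
}
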
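# Structure superposition from residue-level descriptors.
#
# Residue embeddings of two structures give a cosine-similarity matrix;
# Needleman-Wunsch global alignment on that matrix (gap open 0, gap extend
# 0.1 per gap column) yields a residue correspondence, and the Kabsch
# algorithm computes the optimal rigid superposition and RMSD over the
# paired C-alpha atoms.

#' Cosine-similarity matrix between two residue-embedding sets
#'
#' @param e_a,e_b row-normalized embedding matrices (L1 x L and L2 x L).
#' @return L1 x L2 matrix of cosine similarities in [-1, 1].
#' @export
cosine_similarity_matrix <- function(e_a, e_b) {
  e_a <- as.matrix(e_a); e_b <- as.matrix(e_b)
  if (nrow(e_a) == 0 || nrow(e_b) == 0) stop("empty embeddings")
  tcrossprod(e_a, e_b)
}

#' Needleman-Wunsch global alignment over a similarity matrix
#'
#' Maximizes the summed similarity of matched cells minus gap penalties.
#' With `gap_open = 0` the affine model degenerates to a linear cost of
#' `gap_extend` per gap column (every gap column, including the first, costs
#' `gap_open + gap_extend`). Traceback ties break diagonal > up > left,
#' giving a deterministic, monotone, non-crossing pairing.
#'
#' @param C finite numeric similarity matrix (rows = sequence A).
#' @param gap_open,gap_extend gap penalties (defaults 0 and 0.1).
#' @return list with `pairs` (m x 2 matrix of 1-based row/col indices,
#'   strictly increasing in both columns) and `score` (the DP optimum).
#' @export
nw_align <- function(C, gap_open = 0, gap_extend = 0.1) {
  C <- as.matrix(C)
  stopifnot(all(is.finite(C)))
  n <- nrow(C); m <- ncol(C)
  gap <- gap_open + gap_extend
  F <- matrix(0, n + 1, m + 1)
  F[, 1] <- -gap * (0:n)
  F[1, ] <- -gap * (0:m)
  ptr <- matrix(0L, n + 1, m + 1)  # 1 = diag, 2 = up (gap in B), 3 = left
  ptr[2:(n + 1), 1] <- 2L
  ptr[1, 2:(m + 1)] <- 3L
  for (i in 1:n) {
    diag_sc <- F[i, 1:m] + C[i, ]
    up_col <- F[i, 2:(m + 1)] - gap
    left_prev <- F[i + 1, 1]
    for (j in 1:m) {
      left_sc <- left_prev - gap
      best <- diag_sc[j]; ptr_ij <- 1L
      if (up_col[j] > best) { best <- up_col[j]; ptr_ij <- 2L }
      if (left_sc > best) { best <- left_sc; ptr_ij <- 3L }
      F[i + 1, j + 1] <- best
      ptr[i + 1, j + 1] <- ptr_ij
      left_prev <- best
    }
  }
  # traceback
  i <- n + 1L; j <- m + 1L
  pr <- integer(0); pc <- integer(0)
  while (i > 1L || j > 1L) {
    p <- ptr[i, j]
    if (p == 1L) {
      pr <- c(i - 1L, pr); pc <- c(j - 1L, pc)
      i <- i - 1L; j <- j - 1L
    } else if (p == 2L) {
      i <- i - 1L
    } else {
      j <- j - 1L
    }
  }
  list(pairs = cbind(a = pr, b = pc), score = F[n + 1, m + 1])
}

#' Kabsch optimal rigid superposition
#'
#' Least-squares optimal proper rotation (SVD with determinant correction)
#' and translation superposing the paired coordinates of B onto A, plus the
#' RMSD over the pairs.
#'
#' @param coords_a,coords_b N x 3 coordinate matrices.
#' @param pairs m x 2 matrix of (index in A, index in B) pairs (m >= 3).
#' @return object of class `superposition_result`: `pairs`, `rotation`
#'   (applied to centered B), `translation`, `rmsd`. The superposed copy of
#'   B is `sweep(coords_b %*% t(rotation), 2, translation, '+')`.
#' @export
kabsch <- function(coords_a, coords_b, pairs) {
  pairs <- as.matrix(pairs)
  if (nrow(pairs) < 3) stop("need at least 3 residue pairs")
  pa <- as.matrix(coords_a)[pairs[, 1], , drop = FALSE]
  pb <- as.matrix(coords_b)[pairs[, 2], , drop = FALSE]
  ca <- colMeans(pa); cb <- colMeans(pb)
  a0 <- sweep(pa, 2, ca); b0 <- sweep(pb, 2, cb)
  h <- crossprod(b0, a0)          # 3x3 covariance
  sv <- svd(h)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)  # rotates centered B onto A
  bt <- b0 %*% t(R)
  rmsd <- sqrt(mean(rowSums((a0 - bt)^2)))
  translation <- ca - as.vector(R %*% cb)
  structure(
    list(pairs = pairs, rotation = R, translation = translation, rmsd = rmsd),
    class = "superposition_result"
  )
}

#' @export
print.superposition_result <- function(x, ...) {
  cat(sprintf("<superposition_result> %d aligned pairs, RMSD = %.3f A\n",
              nrow(x$pairs), x$rmsd))
  invisible(x)
}

#' Superpose two structures via residue-level descriptors
#'
#' Pipeline: encode both structures, compute the cosine-similarity matrix of
#' their (row-normalized) residue embeddings, align with [nw_align], and
#' superpose the corresponding C-alpha atoms with [kabsch]. Optionally
#' writes a two-model PDB (MODEL 1 = A, MODEL 2 = superposed B).
#'
#' @param structure_a,structure_b [protein_structure] objects.
#' @param model a fitted [strucr] model (or a `strucr_encoder`).
#' @param out_pdb optional path for the superposed two-model PDB file.
#' @return a `superposition_result` (see [kabsch]).
#' @export
superpose <- function(structure_a, structure_b, model, out_pdb = NULL) {
  if (inherits(model, "strucr")) {
    enc <- predict(model, list(structure_a, structure_b),
                   type = "residue_embeddings")
  } else {
    stopifnot(inherits(model, "strucr_encoder"))
    M <- as.integer(round(log2(model$config$input_dim)))
    graphs <- lapply(list(structure_a, structure_b), featurize, M = M)
    enc <- encode_structures(model, graphs)$residue_embeddings
  }
  C <- cosine_similarity_matrix(enc[[1]], enc[[2]])
  aln <- nw_align(C)
  res <- kabsch(structure_a$ca_coords, structure_b$ca_coords, aln$pairs)
  res$score <- aln$score
  if (!is.null(out_pdb)) {
    b_sup <- sweep(structure_b$ca_coords %*% t(res$rotation), 2,
                   res$translation, `+`)
    write_superposed_pdb(structure_a$ca_coords, b_sup, out_pdb)
  }
  res
}

# Two-model CA-only PDB for visual inspection of a superposition.
write_superposed_pdb <- function(coords_a, coords_b, path) {
  fmt <- function(i, xyz) {
    sprintf("ATOM  %5d  CA  ALA A%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
            i, i, xyz[1], xyz[2], xyz[3])
  }
  lines <- c("MODEL     1",
             vapply(seq_len(nrow(coords_a)),
                    function(i) fmt(i, coords_a[i, ]), character(1)),
             "ENDMDL",
             "MODEL     2",
             vapply(seq_len(nrow(coords_b)),
                    function(i) fmt(i, coords_b[i, ]), character(1)),
             "ENDMDL", "END")
  writeLines(lines, path)
  invisible(path)
}
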
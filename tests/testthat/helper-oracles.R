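# Independent oracles used by the alignment tests.

# Exhaustive enumeration: best score over all monotone global alignments
# with linear gap cost (naive recursion, feasible at <= 6 x 8).
enum_align_score <- function(C, gap) {
  go <- function(i, j) {
    if (i == 0 && j == 0) return(0)
    best <- -Inf
    if (i > 0 && j > 0) best <- max(best, go(i - 1, j - 1) + C[i, j])
    if (i > 0) best <- max(best, go(i - 1, j) - gap)
    if (j > 0) best <- max(best, go(i, j - 1) - gap)
    best
  }
  go(nrow(C), ncol(C))
}

# Quaternion (Horn) superposition: optimal RMSD from the largest eigenvalue
# of the 4x4 key matrix, independent of the SVD route.
horn_rmsd <- function(a, b, pairs) {
  pa <- a[pairs[, 1], , drop = FALSE]; pb <- b[pairs[, 2], , drop = FALSE]
  a0 <- sweep(pa, 2, colMeans(pa)); b0 <- sweep(pb, 2, colMeans(pb))
  S <- crossprod(b0, a0)
  K <- rbind(
    c(S[1,1]+S[2,2]+S[3,3], S[2,3]-S[3,2], S[3,1]-S[1,3], S[1,2]-S[2,1]),
    c(S[2,3]-S[3,2], S[1,1]-S[2,2]-S[3,3], S[1,2]+S[2,1], S[3,1]+S[1,3]),
    c(S[3,1]-S[1,3], S[1,2]+S[2,1], -S[1,1]+S[2,2]-S[3,3], S[2,3]+S[3,2]),
    c(S[1,2]-S[2,1], S[3,1]+S[1,3], S[2,3]+S[3,2], -S[1,1]-S[2,2]+S[3,3]))
  lmax <- max(eigen(K, symmetric = TRUE)$values)
  msd <- (sum(a0^2) + sum(b0^2) - 2 * lmax) / nrow(pa)
  sqrt(max(msd, 0))
}
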
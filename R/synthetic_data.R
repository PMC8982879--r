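# Synthetic C-alpha trace generator and same-length TM-score oracle.
#
# Desk-scale stand-in for a curated fold database: a handful of archetype
# backbones (helix bundles, sheets, mixed topologies, coils) each spawn a
# family of members by graded coordinate perturbation plus a random rigid
# transform, giving a fully known pairwise similarity structure. The oracle
# scores same-length pairs with the TM-score formula under identity
# correspondence and iteratively reweighted optimal superposition;
# cross-length pairs receive a configurable floor constant.

## ---- internal geometry -----------------------------------------------------

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Place the next atom from the last three by internal coordinates
# (bond length d, bond angle theta, dihedral phi), NeRF-style.
place_next <- function(p1, p2, p3, d, theta, phi) {
  bc <- unit_vector(p3 - p2)
  n <- cross3(p2 - p1, bc)
  if (sqrt(sum(n^2)) < 1e-8) n <- cross3(c(1, 0, 0), bc)
  if (sqrt(sum(n^2)) < 1e-8) n <- cross3(c(0, 1, 0), bc)
  n <- unit_vector(n)
  m <- cross3(n, bc)
  d2 <- c(-d * cos(theta), d * sin(theta) * cos(phi), d * sin(theta) * sin(phi))
  p3 + d2[1] * bc + d2[2] * m + d2[3] * n
}

# Canonical ideal alpha-helix C-alpha trace: rise 1.5 A/residue,
# radius 2.3 A, 100 degrees/residue (consecutive spacing ~3.83 A).
canonical_helix <- function(len) {
  k <- 0:(len - 1)
  ang <- k * 100 * pi / 180
  cbind(2.3 * cos(ang), 2.3 * sin(ang), 1.5 * k)
}

# Near-extended strand: 3.3 A axial step with alternating 0.95 A offset
# (consecutive spacing ~3.81 A).
canonical_strand <- function(len) {
  k <- 0:(len - 1)
  cbind(3.3 * k, 0.95 * (-1)^k, rep(0, len))
}

# Append a rigidly re-oriented canonical segment to a growing chain,
# keeping the junction C-alpha distance at 3.8 A.
attach_segment <- function(coords, seg) {
  seg0 <- sweep(seg, 2, seg[1, ])
  R <- random_rotation()
  seg_r <- seg0 %*% t(R)
  n <- nrow(coords)
  if (n == 0) return(seg_r)
  # junction direction: random, biased to continue the chain
  prev_dir <- if (n >= 2) unit_vector(coords[n, ] - coords[n - 1, ]) else c(1, 0, 0)
  repeat {
    dir <- unit_vector(stats::rnorm(3))
    if (sum(dir * prev_dir) > -0.2) break
  }
  anchor <- coords[n, ] + 3.8 * dir
  rbind(coords, sweep(seg_r, 2, anchor, `+`))
}

# Append loop residues one by one with exact 3.8 A bonds and random
# moderate bend angles.
attach_loop <- function(coords, len) {
  for (k in seq_len(len)) {
    n <- nrow(coords)
    if (n == 0) {
      coords <- matrix(c(0, 0, 0), 1, 3)
    } else if (n == 1) {
      coords <- rbind(coords, coords[1, ] + c(3.8, 0, 0))
    } else {
      p1 <- if (n >= 3) coords[n - 2, ] else coords[n - 1, ] + c(0, 1, 0)
      theta <- stats::runif(1, 95, 125) * pi / 180
      phi <- stats::runif(1, -pi, pi)
      coords <- rbind(coords,
                      place_next(p1, coords[n - 1, ], coords[n, ], 3.8, theta, phi))
    }
  }
  coords
}

## ---- generators ------------------------------------------------------------

#' Generate an archetype C-alpha trace
#'
#' Deterministic given `seed`. Secondary-structure segments follow the
#' archetype kind: `helix_bundle` alternates ideal alpha-helices (rise 1.5
#' A/residue, radius 2.3 A, 100 degrees/residue) with short loops; `sheet`
#' alternates near-extended strands with loops; `mixed` interleaves helices
#' and strands; `coil` is a smooth random walk. All consecutive C-alpha
#' distances lie in [3.7, 3.9] A.
#'
#' @param kind one of `"helix_bundle"`, `"sheet"`, `"mixed"`, `"coil"`.
#' @param length chain length in residues (>= 16).
#' @param seed integer RNG seed.
#' @param id structure id (default derived from kind and seed).
#' @return a [protein_structure].
#' @export
generate_archetype <- function(kind = c("helix_bundle", "sheet", "mixed", "coil"),
                               length, seed,
                               id = sprintf("%s_%d", kind, seed)) {
  kind <- match.arg(kind)
  if (length < 16) stop("length must be >= 16")
  set.seed(seed)
  coords <- matrix(numeric(0), 0, 3)
  seg_i <- 0L
  while (nrow(coords) < length) {
    remaining <- length - nrow(coords)
    seg_i <- seg_i + 1L
    seg_kind <- switch(kind,
      helix_bundle = "helix",
      sheet = "strand",
      mixed = if (seg_i %% 2 == 1) "helix" else "strand",
      coil = "loop")
    if (seg_kind == "loop") {
      coords <- attach_loop(coords, remaining)
    } else {
      seg_len <- if (seg_kind == "helix") sample(12:18, 1) else sample(6:10, 1)
      seg_len <- min(seg_len, remaining)
      seg <- if (seg_kind == "helix") canonical_helix(seg_len)
             else canonical_strand(seg_len)
      coords <- attach_segment(coords, seg)
      remaining <- length - nrow(coords)
      if (remaining > 0) {
        coords <- attach_loop(coords, min(sample(3:5, 1), remaining))
      }
    }
  }
  protein_structure(id, coords[seq_len(length), , drop = FALSE],
                    class_label = kind)
}

#' Perturb an archetype into a family member
#'
#' Adds isotropic Gaussian coordinate noise of the given scale, locally
#' smooths the chain until consecutive C-alpha distances return to
#' 3.8 +/- 0.15 A, and applies a random rigid transform (so that invariance
#' is exercised). `scale = 0` applies the rigid transform only.
#'
#' @param parent a [protein_structure].
#' @param scale noise standard deviation in Angstrom (>= 0).
#' @param seed integer RNG seed.
#' @param id member id.
#' @return a [protein_structure] of the same length and class label.
#' @export
perturb_member <- function(parent, scale, seed,
                           id = sprintf("%s_p%g_%d", parent$id, scale, seed)) {
  stopifnot(inherits(parent, "protein_structure"), scale >= 0)
  set.seed(seed)
  coords <- parent$ca_coords
  n <- nrow(coords)
  if (scale > 0) {
    coords <- coords + matrix(stats::rnorm(3 * n, sd = scale), n, 3)
    for (iter in 1:200) {
      b <- coords[-1, , drop = FALSE] - coords[-n, , drop = FALSE]
      l <- sqrt(rowSums(b^2))
      if (max(abs(l - 3.8)) <= 0.15) break
      corr <- (l - 3.8) / pmax(l, 1e-8) / 2
      delta <- b * corr
      coords[-n, ] <- coords[-n, , drop = FALSE] + delta
      coords[-1, ] <- coords[-1, , drop = FALSE] - delta
    }
  }
  coords <- rigid_transform(coords, random_rotation(),
                            stats::runif(3, -30, 30))
  protein_structure(id, coords, class_label = parent$class_label)
}

## ---- TM-score oracle -------------------------------------------------------

# Weighted Kabsch superposition of b onto a; returns per-residue deviations.
weighted_superpose_dev <- function(a, b, w) {
  w <- w / sum(w)
  ca <- colSums(a * w); cb <- colSums(b * w)
  a0 <- sweep(a, 2, ca); b0 <- sweep(b, 2, cb)
  h <- crossprod(b0 * w, a0)
  sv <- svd(h)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  sqrt(rowSums((a0 - b0 %*% t(R))^2))
}

#' TM-score value from per-residue deviations
#'
#' `TM = mean( 1 / (1 + (d_i / d0)^2) )` with
#' `d0 = max(1.24 (L - 15)^(1/3) - 1.8, 0.5)`.
#'
#' @param d vector of per-residue deviations in Angstrom.
#' @param L normalizing chain length (default `length(d)`).
#' @return TM-score in (0, 1].
#' @export
tm_from_deviations <- function(d, L = length(d)) {
  d0 <- max(1.24 * (L - 15)^(1 / 3) - 1.8, 0.5)
  mean(1 / (1 + (d / d0)^2))
}

#' Same-length TM-score oracle
#'
#' Scores two equal-length structures under the identity residue
#' correspondence: the superposition maximizing the TM-sum is approximated
#' by 5 rounds of TM-weighted Kabsch superposition (weights
#' `1/(1 + (d_i/d0)^2)` recomputed each round), then the TM-score formula is
#' evaluated. Rigidly equivalent structures score 1. Cross-length pairs are
#' out of scope by construction and raise an error.
#'
#' @param a,b [protein_structure] objects of equal length.
#' @param rounds reweighting iterations (default 5).
#' @return TM-score in (0, 1].
#' @export
tm_oracle <- function(a, b, rounds = 5) {
  stopifnot(inherits(a, "protein_structure"), inherits(b, "protein_structure"))
  if (a$n_residues != b$n_residues) {
    stop("tm_oracle requires equal-length structures (got ",
         a$n_residues, " and ", b$n_residues, ")")
  }
  L <- a$n_residues
  d0 <- max(1.24 * (L - 15)^(1 / 3) - 1.8, 0.5)
  w <- rep(1, L)
  for (r in seq_len(rounds)) {
    dev <- weighted_superpose_dev(a$ca_coords, b$ca_coords, w)
    w <- 1 / (1 + (dev / d0)^2)
  }
  tm_from_deviations(dev, L)
}

## ---- benchmark assembly ----------------------------------------------------

#' Specification of a synthetic benchmark dataset
#'
#' @param n_archetypes number of fold archetypes (kinds cycle through
#'   helix_bundle, sheet, mixed, coil).
#' @param members_per_archetype family members per archetype.
#' @param length_range inclusive residue-count range; each archetype draws
#'   one length, shared by its members (min >= 16).
#' @param perturbation_scales noise scales in Angstrom, recycled over the
#'   members of each archetype to grade within-family similarity.
#' @param cross_floor ground-truth similarity assigned to cross-length
#'   pairs (default 0.17, the literature's random-pair TM-score expectation).
#' @param seed master RNG seed.
#' @return an object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_archetypes = 6, members_per_archetype = 10,
                           length_range = c(40, 60),
                           perturbation_scales = seq(0.3, 3, length.out =
                                                       members_per_archetype),
                           cross_floor = 0.17, seed = 1) {
  stopifnot(n_archetypes >= 1, members_per_archetype >= 1,
            length_range[1] >= 16, length_range[2] >= length_range[1],
            all(perturbation_scales >= 0))
  structure(
    list(n_archetypes = as.integer(n_archetypes),
         members_per_archetype = as.integer(members_per_archetype),
         length_range = as.integer(length_range),
         perturbation_scales = perturbation_scales,
         cross_floor = cross_floor, seed = as.integer(seed)),
    class = "synthetic_spec"
  )
}

#' Build a synthetic benchmark: structures, similarity table, class labels
#'
#' Generates the archetypes and their perturbed members, computes the full
#' pairwise oracle similarity table (TM oracle within same-length cohorts,
#' the floor constant across lengths), and labels every member with its
#' archetype kind. Optionally persists the structures as PDB files.
#'
#' @param spec a [synthetic_spec].
#' @param dir optional directory; when given, one PDB file per structure
#'   plus `tm.tsv` and `labels.tsv` are written there.
#' @return list with `structures` (named list of [protein_structure]),
#'   `sim_table` (named square matrix), `labels` (named character vector),
#'   `archetype` (named integer vector), `spec`.
#' @export
make_benchmark <- function(spec = synthetic_spec(), dir = NULL) {
  stopifnot(inherits(spec, "synthetic_spec"))
  kinds <- c("helix_bundle", "sheet", "mixed", "coil")
  set.seed(spec$seed)
  arch_seeds <- sample.int(2^30, spec$n_archetypes)
  mem_seeds <- matrix(sample.int(2^30, spec$n_archetypes *
                                   spec$members_per_archetype),
                      spec$n_archetypes)
  lens <- sample(seq(spec$length_range[1], spec$length_range[2]),
                 spec$n_archetypes, replace = TRUE)
  structures <- list()
  labels <- character(0)
  arch_of <- integer(0)
  for (i in seq_len(spec$n_archetypes)) {
    kind <- kinds[(i - 1) %% length(kinds) + 1]
    parent <- generate_archetype(kind, lens[i], seed = arch_seeds[i])
    for (j in seq_len(spec$members_per_archetype)) {
      sc <- spec$perturbation_scales[(j - 1) %% length(spec$perturbation_scales) + 1]
      id <- sprintf("arch%02d_m%02d", i, j)
      structures[[id]] <- perturb_member(parent, sc, seed = mem_seeds[i, j],
                                         id = id)
      labels[id] <- kind
      arch_of[id] <- i
    }
  }
  ids <- names(structures)
  n <- length(ids)
  sim <- matrix(spec$cross_floor, n, n, dimnames = list(ids, ids))
  diag(sim) <- 1
  lens_all <- vapply(structures, function(s) s$n_residues, integer(1))
  for (p in seq_len(n - 1)) {
    for (q in (p + 1):n) {
      if (lens_all[p] == lens_all[q]) {
        tm <- tm_oracle(structures[[p]], structures[[q]])
        sim[p, q] <- tm
        sim[q, p] <- tm
      }
    }
  }
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    for (id in ids) {
      write_structure(structures[[id]], file.path(dir, paste0(id, ".pdb")))
    }
    utils::write.table(sim, file.path(dir, "tm.tsv"), sep = "\t",
                       quote = FALSE, col.names = NA)
    utils::write.table(data.frame(id = ids, label = labels[ids]),
                       file.path(dir, "labels.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  list(structures = structures, sim_table = sim, labels = labels,
       archetype = arch_of, spec = spec)
}
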
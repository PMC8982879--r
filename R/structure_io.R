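# Reading and writing single-chain C-alpha traces.
#
# Only C-alpha atoms are used anywhere in the package: a protein structure is
# its ordered C-alpha trace. Multi-chain PDB files are split into one
# structure per chain; HETATM records and residues without a C-alpha are
# ignored; alternate locations resolve to the first conformer.

#' Construct a protein structure (ordered C-alpha trace)
#'
#' @param id character identifier.
#' @param ca_coords numeric N x 3 matrix of C-alpha coordinates in Angstrom,
#'   in chain order.
#' @param class_label optional fold-class label (any atomic scalar).
#' @return an object of class `protein_structure` with fields `id`,
#'   `n_residues`, `ca_coords`, `class_label`.
#' @export
protein_structure <- function(id, ca_coords, class_label = NULL) {
  ca_coords <- as.matrix(ca_coords)
  if (ncol(ca_coords) != 3) stop("ca_coords must be an N x 3 matrix")
  if (nrow(ca_coords) < 1) stop("structure must contain at least one residue")
  if (!all(is.finite(ca_coords))) stop("all coordinates must be finite")
  storage.mode(ca_coords) <- "double"
  dimnames(ca_coords) <- NULL
  structure(
    list(id = as.character(id), n_residues = nrow(ca_coords),
         ca_coords = ca_coords, class_label = class_label),
    class = "protein_structure"
  )
}

#' @export
print.protein_structure <- function(x, ...) {
  cat(sprintf("<protein_structure> %s: %d residues (C-alpha trace)\n",
              x$id, x$n_residues))
  if (!is.null(x$class_label)) cat("  class:", as.character(x$class_label), "\n")
  invisible(x)
}

#' Load protein structures from a PDB file, one per chain
#'
#' Reads ATOM records with a `bio3d` backend, keeps C-alpha atoms only,
#' resolves alternate locations to the first conformer, and splits the file
#' into one [protein_structure] per chain (in file order). Residues lacking
#' a C-alpha atom are skipped with a warning; chains with no C-alpha at all
#' are omitted with a warning.
#'
#' @param path path to a PDB file.
#' @param format input format; only `"pdb"` is supported.
#' @return list of [protein_structure], one per chain. Structure ids are the
#'   file base name, suffixed with `_<chain>` when the file has > 1 chain.
#' @export
load_structures <- function(path, format = c("pdb")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = FALSE, verbose = FALSE)),
    error = function(e) stop("failed to parse PDB file '", path, "': ",
                             conditionMessage(e))
  )
  atoms <- pdb$atom
  atoms <- atoms[atoms$type == "ATOM", , drop = FALSE]
  if (nrow(atoms) == 0) stop("no ATOM records in ", path)
  atoms$chain[is.na(atoms$chain)] <- " "
  atoms$insert[is.na(atoms$insert)] <- ""
  # first-conformer rule for altlocs: keep the first CA seen per residue key
  base <- tools::file_path_sans_ext(basename(path))
  chains <- unique(atoms$chain)  # unique() preserves file order
  out <- list()
  for (ch in chains) {
    a <- atoms[atoms$chain == ch, , drop = FALSE]
    reskey <- paste(a$resno, a$insert, sep = "|")
    n_res_total <- length(unique(reskey))
    ca <- a[a$elety == "CA", , drop = FALSE]
    ca <- ca[!duplicated(paste(ca$resno, ca$insert, sep = "|")), , drop = FALSE]
    if (nrow(ca) == 0) {
      warning("chain '", ch, "' in ", basename(path),
              " has no C-alpha atoms; omitted")
      next
    }
    if (nrow(ca) < n_res_total) {
      warning(n_res_total - nrow(ca), " residue(s) in chain '", ch, "' of ",
              basename(path), " lack a C-alpha atom; skipped")
    }
    id <- if (length(chains) > 1) paste0(base, "_", ch) else base
    out[[length(out) + 1]] <-
      protein_structure(id, cbind(ca$x, ca$y, ca$z))
  }
  out
}

#' Write a C-alpha trace as a minimal PDB file
#'
#' Emits one `ATOM` record (atom name `CA`, residue `ALA`, chain `A`) per
#' residue with sequential residue numbering from 1, at the PDB fixed-column
#' precision of 0.001 Angstrom.
#'
#' @param s a [protein_structure].
#' @param path output file path.
#' @return invisibly, `path`.
#' @export
write_structure <- function(s, path) {
  stopifnot(inherits(s, "protein_structure"))
  n <- s$n_residues
  suppressWarnings(bio3d::write.pdb(
    file = path,
    xyz = as.vector(t(s$ca_coords)),
    type = rep("ATOM", n),
    resno = seq_len(n),
    resid = rep("ALA", n),
    eleno = seq_len(n),
    elety = rep("CA", n),
    chain = rep("A", n)
  ))
  invisible(path)
}
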
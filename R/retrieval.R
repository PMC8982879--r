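# Descriptor databases and ranking by length-scaling cosine distance.
#
# TM-score is asymmetric in chain length; plain cosine distance is not. The
# length-scaling cosine distance divides the cosine distance by
# 1 + max((l_b - l_a)/l_max, 0), shrinking the distance when the key is the
# longer chain, which mirrors the TM-score's behaviour. It is used only at
# query time; training works on plain cosine similarity.

#' Length-scaling cosine distance between two descriptors
#'
#' `d = (1 - y_a . y_b) / (1 + max((l_b - l_a) / l_max, 0))`. When the key
#' is not longer than the query this is exactly the cosine distance; when it
#' is longer the distance shrinks, so `d(a, b) < d(b, a)` for `l_a < l_b` --
#' the same asymmetry as a TM-score normalized by the query length, where a
#' short query scores higher against a long key than the reverse.
#'
#' @param y_a,y_b unit-norm descriptor vectors (query, key).
#' @param l_a,l_b residue counts of query and key.
#' @param l_max longest chain in the database.
#' @return distance in [0, 2].
#' @export
length_scaling_distance <- function(y_a, y_b, l_a, l_b, l_max) {
  na <- sqrt(sum(y_a^2)); nb <- sqrt(sum(y_b^2))
  if (na == 0 || nb == 0) stop("zero-norm descriptor")
  (1 - sum(y_a * y_b)) / (1 + max((l_b - l_a) / l_max, 0))
}

#' Build a descriptor database from a fitted model
#'
#' Encodes every structure with the model's query encoder (eval mode) and
#' stacks the unit descriptors with their residue counts; `l_max` is frozen
#' at build time. Structures that cannot be featurized (too short for the
#' reference-point hierarchy) are reported and skipped.
#'
#' @param model a fitted [strucr] model.
#' @param structures list of [protein_structure].
#' @return an object of class `descriptor_db` (fields `ids`, `vectors`,
#'   `lengths`, `l_max`). Persist with [saveRDS]; reloading is bit-identical.
#' @export
build_descriptor_db <- function(model, structures) {
  stopifnot(inherits(model, "strucr"))
  graphs <- list()
  for (s in structures) {
    g <- tryCatch(featurize(s, M = model$feature_params$M,
                            omega = model$feature_params$omega,
                            epsilon = model$feature_params$epsilon),
                  error = function(e) {
                    warning("skipping '", s$id, "': ", conditionMessage(e))
                    NULL
                  })
    if (!is.null(g)) graphs[[length(graphs) + 1]] <- g
  }
  if (length(graphs) == 0) stop("no structure could be featurized")
  enc <- encode_structures(model, graphs)
  d <- enc$descriptors
  structure(
    list(ids = d$ids, vectors = d$vectors, lengths = d$lengths,
         l_max = max(d$lengths)),
    class = "descriptor_db"
  )
}

#' @export
print.descriptor_db <- function(x, ...) {
  cat(sprintf("<descriptor_db> %d structures, L = %d, l_max = %d\n",
              length(x$ids), ncol(x$vectors), x$l_max))
  invisible(x)
}

#' Rank a database against a query descriptor
#'
#' Orders all database entries by ascending length-scaling distance to the
#' query; ties break by ascending id and the query itself (matched by id)
#' is excluded.
#'
#' @param query_vector unit-norm query descriptor.
#' @param query_length query residue count.
#' @param db a [build_descriptor_db] result.
#' @param query_id id to exclude from the ranking (optional).
#' @return object of class `ranking_result`: `query_id`, `ordered_ids`,
#'   `distances` (non-decreasing).
#' @export
rank_database <- function(query_vector, query_length, db, query_id = NULL) {
  stopifnot(inherits(db, "descriptor_db"))
  keep <- if (is.null(query_id)) rep(TRUE, length(db$ids)) else db$ids != query_id
  if (!any(keep)) stop("database is empty after self-exclusion")
  ids <- db$ids[keep]
  cosd <- 1 - as.vector(db$vectors[keep, , drop = FALSE] %*% query_vector)
  scale <- 1 + pmax((db$lengths[keep] - query_length) / db$l_max, 0)
  d <- cosd / scale
  ord <- order(d, ids)
  structure(
    list(query_id = query_id %||% NA_character_,
         ordered_ids = ids[ord], distances = d[ord]),
    class = "ranking_result"
  )
}

#' @export
print.ranking_result <- function(x, n = 5, ...) {
  cat(sprintf("<ranking_result> query %s over %d structures\n",
              x$query_id, length(x$ordered_ids)))
  k <- min(n, length(x$ordered_ids))
  for (i in seq_len(k)) {
    cat(sprintf("  %2d. %s  (d = %.4f)\n", i, x$ordered_ids[i], x$distances[i]))
  }
  invisible(x)
}

#' Rank every database entry as query against the database itself
#'
#' @param db a [build_descriptor_db] result.
#' @return named list of `ranking_result`, one per database entry (self
#'   excluded in each).
#' @export
rank_all <- function(db) {
  out <- lapply(seq_along(db$ids), function(i) {
    rank_database(db$vectors[i, ], db$lengths[i], db, query_id = db$ids[i])
  })
  names(out) <- db$ids
  out
}
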
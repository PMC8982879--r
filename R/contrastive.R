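# Momentum-contrast machinery: momentum update of the key encoder, the
# InfoNCE loss, the FIFO negative queue, and the dynamic training-data
# partition that turns a ground-truth similarity table into (positive,
# negative) supervision per query.

#' Momentum update of the key-encoder parameters
#'
#' `theta_k <- m * theta_k + (1 - m) * theta_q`, applied elementwise over
#' structurally identical nested parameter lists. `m = 1` leaves `theta_k`
#' unchanged; the key parameters never receive gradient updates.
#'
#' @param theta_q,theta_k nested lists of numeric arrays with identical
#'   structure.
#' @param m momentum coefficient in (0, 1]; default 0.999.
#' @return the updated `theta_k`.
#' @export
momentum_update <- function(theta_q, theta_k, m = 0.999) {
  stopifnot(m > 0, m <= 1)
  if (!param_same_shape(theta_q, theta_k)) {
    stop("theta_q and theta_k have different parameter structures")
  }
  param_map2(function(k, q) m * k + (1 - m) * q, theta_k, theta_q)
}

#' InfoNCE contrastive loss for one (query, key) pair
#'
#' `-log( exp(q.k/tau) / (exp(q.k/tau) + sum_i exp(q.n_i/tau)) )` with the
#' positive included in the denominator, so the loss is >= 0 and equals
#' `log(n + 1)` when the positive and all `n` negatives have identical
#' similarity to the query. An empty negative set gives 0.
#'
#' @param y_q,y_k unit-norm query/key descriptor vectors.
#' @param negatives matrix of unit-norm negatives (one per row), or NULL.
#' @param tau temperature (> 0); default 0.07.
#' @return scalar loss.
#' @export
info_nce <- function(y_q, y_k, negatives = NULL, tau = 0.07) {
  stopifnot(tau > 0)
  check_unit <- function(v, what) {
    if (abs(sqrt(sum(v^2)) - 1) > 1e-5) stop(what, " is not unit-norm")
  }
  check_unit(y_q, "y_q"); check_unit(y_k, "y_k")
  pos <- sum(y_q * y_k) / tau
  if (is.null(negatives) || NROW(negatives) == 0) return(0)
  negatives <- as.matrix(negatives)
  apply(negatives, 1, function(v) check_unit(v, "negative"))
  logits <- c(pos, as.vector(negatives %*% y_q) / tau)
  mx <- max(logits)
  -(pos - mx - log(sum(exp(logits - mx))))
}

#' Create an empty (randomly initialized) negative queue
#'
#' The queue starts filled with random unit vectors carrying no structure
#' ids, mimicking a randomly initialized negative memory; real keys then
#' displace them FIFO.
#'
#' @param capacity queue length `n` (default 1024).
#' @param dim descriptor length.
#' @return an object of class `moco_queue`.
#' @export
new_queue <- function(capacity = 1024, dim) {
  v <- matrix(stats::rnorm(capacity * dim), capacity, dim)
  v <- row_normalize(v)
  structure(list(vectors = v, ids = rep(NA_character_, capacity),
                 capacity = as.integer(capacity), head = 0L),
            class = "moco_queue")
}

#' Push key descriptors onto the queue (FIFO)
#'
#' The oldest entries are overwritten when the queue is full.
#'
#' @param queue a [new_queue] object.
#' @param vectors matrix of unit-norm key descriptors, one per row.
#' @param ids matching structure ids.
#' @return the updated queue.
#' @export
enqueue <- function(queue, vectors, ids = NULL) {
  stopifnot(inherits(queue, "moco_queue"))
  vectors <- matrix(vectors, ncol = ncol(queue$vectors))
  if (is.null(ids)) ids <- rep(NA_character_, nrow(vectors))
  for (r in seq_len(nrow(vectors))) {
    slot <- (queue$head %% queue$capacity) + 1L
    queue$vectors[slot, ] <- vectors[r, ]
    queue$ids[slot] <- ids[r]
    queue$head <- queue$head + 1L
  }
  queue
}

#' Per-query dynamic partition index
#'
#' For each query, database ids are sorted by descending ground-truth
#' similarity (ties broken by ascending id, self-pair excluded) and the top
#' `ceiling(K% x database size)` form the positive-candidate subset S.
#'
#' @param sim_table square numeric matrix of ground-truth similarities with
#'   identical row/column names (structure ids).
#' @param K_percent size of S as a percentage of the database (default 30).
#' @return named list (one entry per query) with fields `query_id`,
#'   `ranked_ids`, `similarities`, `subset_size`.
#' @export
build_partition_index <- function(sim_table, K_percent = 30) {
  sim_table <- as.matrix(sim_table)
  ids <- rownames(sim_table)
  if (is.null(ids) || nrow(sim_table) == 0) {
    stop("sim_table must be a non-empty matrix with row/column names")
  }
  stopifnot(identical(ids, colnames(sim_table)), K_percent > 0)
  out <- lapply(ids, function(q) {
    others <- setdiff(ids, q)
    s <- sim_table[q, others]
    ord <- order(-s, others)  # descending similarity, then ascending id
    list(query_id = q,
         ranked_ids = others[ord],
         similarities = unname(s[ord]),
         subset_size = max(1L, ceiling(K_percent / 100 * length(others))))
  })
  names(out) <- ids
  out
}

#' Sample a training pair under the dynamic partition
#'
#' The positive is drawn uniformly from the query's subset S; any structure
#' whose similarity to the query is strictly below that of the sampled
#' positive is a valid negative. Queue entries are masked out of the InfoNCE
#' denominator when they violate that predicate; entries with unknown ids
#' (e.g. the random initial fill) count as negatives.
#'
#' @param index one entry of [build_partition_index].
#' @return list with `query_id`, `positive_id`, `positive_sim` and
#'   `negative_predicate` (a function of an id vector returning logicals;
#'   `NA` ids are treated as valid negatives).
#' @export
sample_training_pair <- function(index) {
  k <- index$subset_size
  j <- if (k == 1) 1L else sample.int(k, 1)
  pos_id <- index$ranked_ids[j]
  pos_sim <- index$similarities[j]
  sims <- stats::setNames(index$similarities, index$ranked_ids)
  list(
    query_id = index$query_id,
    positive_id = pos_id,
    positive_sim = pos_sim,
    negative_predicate = function(ids) {
      s <- sims[ids]
      is.na(s) | s < pos_sim
    }
  )
}
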
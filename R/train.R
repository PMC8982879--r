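# Model fitting: momentum-contrast training of the graph encoder.
#
# strucr() is the package's fitting front end. Each iteration samples a
# batch of queries, draws one positive per query under the (dynamic)
# training-data partition, encodes queries with the gradient encoder and
# positives with the momentum encoder, evaluates the masked InfoNCE loss
# against the FIFO negative queue, takes an SGD-with-momentum step on the
# query parameters, momentum-updates the key parameters, and enqueues the
# key descriptors. Validation AUPRC is tracked at a fixed cadence and the
# learning rate is divided by 10 when it plateaus.

#' Training configuration
#'
#' Defaults follow the full-scale recipe: SGD momentum 0.9, batch 64,
#' initial learning rate 0.1 with /10 plateau decay, MoCo momentum 0.999,
#' temperature 0.07, queue 1024, dynamic partition at K = 30%.
#'
#' @param iterations number of training iterations; `NULL` scales with the
#'   dataset (`40 x n_structures`, capped at 240000).
#' @param batch_size queries per iteration.
#' @param lr initial learning rate.
#' @param sgd_momentum SGD momentum coefficient.
#' @param moco_momentum key-encoder momentum `m` in (0, 1].
#' @param tau InfoNCE temperature.
#' @param queue_size negative-queue capacity `n`.
#' @param K_percent dynamic-partition subset size (percent of database).
#' @param dynamic_partition if `FALSE`, positives are drawn from the static
#'   structural-neighbor set (similarity >= `rho` x max) instead.
#' @param rho neighbor threshold used for validation metrics and the static
#'   partition.
#' @param eval_every validation cadence in iterations (0 disables).
#' @param patience plateau patience in validation evaluations.
#' @param min_rel_improve relative AUPRC improvement counted as progress.
#' @param max_lr_decays maximum number of /10 decays.
#' @param bn_chunks chunk count for the key encoder's shuffled batch norm.
#' @param verbose print progress lines.
#' @return an object of class `train_config`.
#' @export
train_config <- function(iterations = NULL, batch_size = 64, lr = 0.1,
                         sgd_momentum = 0.9, moco_momentum = 0.999,
                         tau = 0.07, queue_size = 1024, K_percent = 30,
                         dynamic_partition = TRUE, rho = 0.9,
                         eval_every = 50, patience = 5,
                         min_rel_improve = 1e-3, max_lr_decays = 3,
                         bn_chunks = 4, verbose = FALSE) {
  stopifnot(batch_size >= 1, lr > 0, sgd_momentum >= 0, sgd_momentum < 1,
            moco_momentum > 0, moco_momentum <= 1, tau > 0, queue_size >= 1)
  structure(as.list(environment()), class = "train_config")
}

# Static (DeepFold-style) partition: S = structural neighbors at rho.
static_partition_index <- function(sim_table, rho) {
  idx <- build_partition_index(sim_table, K_percent = 100)
  for (q in names(idx)) {
    s <- idx[[q]]$similarities
    idx[[q]]$subset_size <- max(1L, sum(s >= rho * max(s)))
  }
  idx
}

# Internal: descriptor_db straight from an encoder + graphs (eval mode).
db_from_encoder <- function(enc, graphs) {
  out <- encode_structures(enc, graphs)
  d <- out$descriptors
  structure(list(ids = d$ids, vectors = d$vectors, lengths = d$lengths,
                 l_max = max(d$lengths)),
            class = "descriptor_db")
}

validation_auprc <- function(enc, graphs, sim_table, rho) {
  db <- db_from_encoder(enc, graphs)
  res <- suppressWarnings(evaluate_ranking(db, sim_table, ks = 1, rho = rho))
  res$avg_auprc
}

#' Fit a contrastive structure-retrieval model
#'
#' Trains the graph encoder on a set of structures supervised by a
#' ground-truth pairwise similarity table (TM-scores or the synthetic
#' oracle). Returns a fitted model usable with [predict.strucr],
#' [build_descriptor_db], [superpose] and the evaluation functions.
#'
#' @param structures named list of [protein_structure] (names = ids; when
#'   unnamed, structure ids are used).
#' @param similarities square numeric matrix of ground-truth similarities
#'   in [0, 1], with row/column names covering all structure ids.
#' @param encoder an [encoder_config].
#' @param training a [train_config].
#' @param M reference-point hierarchy depth (raw feature width is `2^M`;
#'   must match `encoder$input_dim`).
#' @param seed master RNG seed; all randomness (initialization, queue,
#'   sampling, dropout, BN shuffling) derives from it.
#' @return an object of class `strucr` with elements `encoder` (query
#'   encoder: params + BN state + config), `key_encoder`, `queue`,
#'   `feature_params`, `training`, `log` (per-iteration loss, learning rate)
#'   and `validation` (cadenced AUPRC trace).
#' @export
strucr <- function(structures, similarities,
                   encoder = encoder_config(), training = train_config(),
                   M = 5, seed = 1) {
  stopifnot(inherits(encoder, "encoder_config"),
            inherits(training, "train_config"))
  if (2^M != encoder$input_dim) {
    stop("encoder$input_dim must equal 2^M (= ", 2^M, ")")
  }
  ids <- names(structures) %||% vapply(structures, `[[`, character(1), "id")
  names(structures) <- ids
  similarities <- as.matrix(similarities)[ids, ids]
  n <- length(structures)
  set.seed(seed)

  graphs <- lapply(structures, featurize, M = M)
  index <- if (training$dynamic_partition) {
    build_partition_index(similarities, training$K_percent)
  } else {
    static_partition_index(similarities, training$rho)
  }

  enc_q <- init_encoder(encoder)
  enc_k <- enc_q
  queue <- new_queue(training$queue_size, encoder$descriptor_dim)
  velocity <- param_map1(function(x) x * 0, enc_q$params)

  iterations <- training$iterations %||% min(240000L, 40L * n)
  lr <- training$lr
  loss_trace <- numeric(iterations)
  val_iter <- integer(0); val_auprc <- numeric(0)
  best_val <- -Inf; since_best <- 0L; decays <- 0L

  batch_size <- min(training$batch_size, n)
  for (it in seq_len(iterations)) {
    qsel <- sample.int(n, batch_size)
    pairs <- lapply(index[ids[qsel]], sample_training_pair)
    pos_ids <- vapply(pairs, `[[`, character(1), "positive_id")

    bq <- build_batch(graphs[qsel])
    fq <- encoder_forward(enc_q, bq, train = TRUE, dropout = TRUE,
                          with_cache = TRUE)
    enc_q$state <- fq$state
    bk <- build_batch(graphs[pos_ids])
    fk <- encoder_forward(enc_k, bk, train = TRUE, dropout = FALSE,
                          bn_chunks = training$bn_chunks)
    enc_k$state <- fk$state
    yq <- fq$desc; yk <- fk$desc

    l_pos <- rowSums(yq * yk) / training$tau
    l_neg <- yq %*% t(queue$vectors) / training$tau
    valid <- t(vapply(pairs, function(p) p$negative_predicate(queue$ids),
                      logical(queue$capacity)))
    l_neg[!valid] <- -Inf
    mx <- pmax(l_pos, apply(l_neg, 1, max))
    e_pos <- exp(l_pos - mx)
    e_neg <- exp(l_neg - mx)
    z <- e_pos + rowSums(e_neg)
    loss <- mean(-(l_pos - mx - log(z)))
    if (!is.finite(loss)) {
      stop("training diverged at iteration ", it, " (loss = ", loss,
           ", lr = ", lr, ")")
    }
    loss_trace[it] <- loss

    p_pos <- e_pos / z
    p_neg <- e_neg / z
    dyq <- ((p_pos - 1) * yk + p_neg %*% queue$vectors) /
      (training$tau * batch_size)
    grads <- encoder_backward(enc_q, fq$cache, dyq)

    velocity <- param_map2(function(v, g) training$sgd_momentum * v - lr * g,
                           velocity, grads)
    enc_q$params <- param_map2(`+`, enc_q$params, velocity)
    enc_k$params <- momentum_update(enc_q$params, enc_k$params,
                                    training$moco_momentum)
    queue <- enqueue(queue, yk, pos_ids)

    if (training$eval_every > 0 && it %% training$eval_every == 0) {
      va <- validation_auprc(enc_q, graphs, similarities, training$rho)
      val_iter <- c(val_iter, it); val_auprc <- c(val_auprc, va)
      if (va > best_val * (1 + training$min_rel_improve)) {
        best_val <- va; since_best <- 0L
      } else {
        since_best <- since_best + 1L
        if (since_best >= training$patience &&
            decays < training$max_lr_decays) {
          lr <- lr / 10
          decays <- decays + 1L
          since_best <- 0L
        }
      }
      if (training$verbose) {
        message(sprintf("iter %d: loss %.4f, val AUPRC %.4f, lr %.4g",
                        it, loss, va, lr))
      }
    }
  }

  structure(
    list(encoder = enc_q, key_encoder = enc_k, queue = queue,
         feature_params = list(M = M, omega = 4, epsilon = 2),
         training = training, seed = seed, ids = ids,
         log = data.frame(iteration = seq_len(iterations), loss = loss_trace),
         validation = data.frame(iteration = val_iter, auprc = val_auprc),
         final_lr = lr, call = match.call()),
    class = "strucr"
  )
}

## ---- methods ---------------------------------------------------------------

#' @export
print.strucr <- function(x, ...) {
  cfg <- x$encoder$config
  cat("Contrastive graph encoder for protein structure retrieval\n")
  cat(sprintf("  %d training structures, %d iterations, seed %d\n",
              length(x$ids), nrow(x$log), x$seed))
  cat(sprintf("  descriptor length %d; %d residual GC block(s); BiLSTM hidden %d\n",
              cfg$descriptor_dim, cfg$n_res_blocks, cfg$lstm_hidden))
  cat(sprintf("  final training loss %.4f", utils::tail(x$log$loss, 1)))
  if (nrow(x$validation) > 0) {
    cat(sprintf("; last validation AUPRC %.4f",
                utils::tail(x$validation$auprc, 1)))
  }
  cat("\n")
  invisible(x)
}

#' @export
summary.strucr <- function(object, ...) {
  out <- list(
    n_structures = length(object$ids),
    iterations = nrow(object$log),
    initial_loss = object$log$loss[1],
    final_loss = mean(utils::tail(object$log$loss, 20)),
    validation = object$validation,
    final_lr = object$final_lr,
    config = object$encoder$config,
    training = object$training
  )
  class(out) <- "summary.strucr"
  out
}

#' @export
print.summary.strucr <- function(x, ...) {
  cat(sprintf("strucr model: %d structures, %d iterations\n",
              x$n_structures, x$iterations))
  cat(sprintf("  loss: %.4f (first) -> %.4f (mean of last 20)\n",
              x$initial_loss, x$final_loss))
  cat(sprintf("  final learning rate: %.4g\n", x$final_lr))
  if (nrow(x$validation) > 0) {
    cat(sprintf("  validation AUPRC: %.4f -> %.4f over %d evaluations\n",
                x$validation$auprc[1], utils::tail(x$validation$auprc, 1),
                nrow(x$validation)))
  }
  invisible(x)
}

#' Encode structures with a fitted model
#'
#' @param object a fitted [strucr] model.
#' @param newdata a [protein_structure] or list of them.
#' @param type `"descriptors"` (a `descriptor_set`) or
#'   `"residue_embeddings"` (list of row-normalized N_r x L matrices).
#' @param ... unused.
#' @export
predict.strucr <- function(object, newdata,
                           type = c("descriptors", "residue_embeddings"),
                           ...) {
  type <- match.arg(type)
  if (inherits(newdata, "protein_structure")) newdata <- list(newdata)
  graphs <- lapply(newdata, featurize, M = object$feature_params$M,
                   omega = object$feature_params$omega,
                   epsilon = object$feature_params$epsilon)
  out <- encode_structures(object, graphs)
  if (type == "descriptors") out$descriptors else out$residue_embeddings
}

#' @export
coef.strucr <- function(object, ...) object$encoder$params

#' Plot training loss and validation AUPRC traces
#'
#' @param x a fitted [strucr] model.
#' @param ... passed to [plot.default].
#' @export
plot.strucr <- function(x, ...) {
  has_val <- nrow(x$validation) > 0
  old <- graphics::par(mfrow = c(1, if (has_val) 2 else 1))
  on.exit(graphics::par(old))
  plot(x$log$iteration, x$log$loss, type = "l", xlab = "iteration",
       ylab = "InfoNCE loss", main = "training loss", ...)
  if (has_val) {
    plot(x$validation$iteration, x$validation$auprc, type = "b",
         xlab = "iteration", ylab = "mean AUPRC", main = "validation", ...)
  }
  invisible(x)
}

#' Save / load a model checkpoint
#'
#' Thin [saveRDS]/[readRDS] wrappers; a reloaded checkpoint reproduces
#' inference bit for bit (config, both parameter sets and the queue are
#' stored).
#'
#' @param model a fitted [strucr] model.
#' @param path file path.
#' @return `load_strucr` returns the model.
#' @export
save_strucr <- function(model, path) {
  stopifnot(inherits(model, "strucr"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_strucr
#' @export
load_strucr <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "strucr")) stop("not a strucr checkpoint: ", path)
  model
}
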
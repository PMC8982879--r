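# MoCo machinery: momentum update, InfoNCE, queue, data partition, training.

test_that("momentum update fixed points and convex combination", {
  set.seed(1)
  q <- list(a = matrix(rnorm(6), 2, 3), b = list(w = rnorm(4)))
  k <- list(a = matrix(rnorm(6), 2, 3), b = list(w = rnorm(4)))
  expect_equal(momentum_update(q, k, m = 1), k)           # m = 1: unchanged
  expect_equal(momentum_update(q, q, m = 0.5), q)         # equal sets: fixed
  expect_equal(momentum_update(list(x = 1), list(x = 0), m = 0.9)$x, 0.1)
  upd <- momentum_update(q, k, m = 0.999)
  expect_equal(upd$a, 0.999 * k$a + 0.001 * q$a)
  expect_error(momentum_update(q, list(a = matrix(0, 3, 2), b = k$b), 0.9),
               "different")
  # drift bound: |k' - k| <= (1 - m) |q - k|
  expect_lte(max(abs(upd$a - k$a)), (1 - 0.999) * max(abs(q$a - k$a)) + 1e-15)
})

test_that("InfoNCE closed forms and monotonicity", {
  L <- 8
  unit <- function(v) v / sqrt(sum(v^2))
  set.seed(2)
  y_q <- unit(rnorm(L))
  # uniform case: positive and n negatives all at equal similarity
  n <- 5
  negs <- matrix(rep(y_q, n), n, byrow = TRUE)
  expect_equal(info_nce(y_q, y_q, negs, tau = 0.07), log(n + 1),
               tolerance = 1e-10)
  # empty queue -> 0
  expect_equal(info_nce(y_q, y_q, NULL), 0)
  # hand computation: perfect positive, orthogonal negatives, tau = 0.07
  y_k <- y_q
  negs <- diag(L)[1:3, , drop = FALSE]
  negs <- t(apply(negs, 1, function(v) v - sum(v * y_q) * y_q))
  negs <- t(apply(negs, 1, unit))
  sims <- as.vector(negs %*% y_q)  # ~0 by construction
  manual <- -log(exp(1 / 0.07) / (exp(1 / 0.07) + sum(exp(sims / 0.07))))
  expect_equal(info_nce(y_q, y_k, negs, tau = 0.07), manual, tolerance = 1e-10)
  # strictly decreasing in the positive similarity, negatives fixed
  set.seed(3)
  other <- unit(rnorm(L))
  mix <- function(t) unit(t * y_q + (1 - t) * other)
  negs <- t(apply(matrix(rnorm(4 * L), 4), 1, unit))
  losses <- vapply(c(0.1, 0.5, 0.9), function(t) {
    info_nce(y_q, mix(t), negs, tau = 0.07)
  }, numeric(1))
  expect_true(all(diff(losses) < 0))
  expect_error(info_nce(2 * y_q, y_q, negs), "unit-norm")
})

test_that("queue has FIFO semantics with unit-norm random initialization", {
  set.seed(4)
  q <- new_queue(capacity = 4, dim = 6)
  expect_equal(sqrt(rowSums(q$vectors^2)), rep(1, 4), tolerance = 1e-12)
  v <- diag(6)[1:5, ]
  q <- enqueue(q, v[1:4, ], ids = paste0("s", 1:4))
  expect_equal(q$ids, paste0("s", 1:4))
  q <- enqueue(q, v[5, , drop = FALSE], ids = "s5")
  expect_false("s1" %in% q$ids)   # earliest sample dequeued
  expect_true("s5" %in% q$ids)
  expect_equal(nrow(q$vectors), 4)
})

test_that("partition index sorts by similarity with id tie-breaks", {
  set.seed(5)
  n <- 10
  ids <- sprintf("s%02d", 1:n)
  sim <- matrix(runif(n * n), n, n, dimnames = list(ids, ids))
  sim <- (sim + t(sim)) / 2; diag(sim) <- 1
  idx <- build_partition_index(sim, K_percent = 30)
  expect_equal(idx[["s01"]]$subset_size, 3)  # ceil(0.3 * 9)
  for (q in ids) {
    others <- setdiff(ids, q)
    s <- sim[q, others]
    ord <- others[order(-s, others)]  # brute-force sort-and-slice oracle
    expect_equal(idx[[q]]$ranked_ids, ord)
    expect_true(all(diff(idx[[q]]$similarities) <= 0))
    expect_false(q %in% idx[[q]]$ranked_ids)
  }
  expect_equal(build_partition_index(sim, 100)[["s01"]]$subset_size, 9)
  # exact ties broken by ascending id
  simt <- matrix(0.5, 3, 3, dimnames = list(c("b", "a", "c"), c("b", "a", "c")))
  diag(simt) <- 1
  expect_equal(build_partition_index(simt, 100)[["b"]]$ranked_ids, c("a", "c"))
})

test_that("positive sampling is uniform over S and the negative mask is sound", {
  idx <- list(query_id = "q", ranked_ids = paste0("s", 1:8),
              similarities = c(0.9, 0.8, 0.7, 0.6, 0.5, 0.4, 0.3, 0.2),
              subset_size = 4L)
  set.seed(6)
  draws <- replicate(1e4, sample_training_pair(idx)$positive_id)
  counts <- table(factor(draws, levels = paste0("s", 1:4)))
  # 3-sigma binomial band around 2500
  sigma <- sqrt(1e4 * 0.25 * 0.75)
  expect_true(all(abs(counts - 2500) < 3 * sigma))
  # negatives: strictly below the sampled positive's similarity; NA ids pass
  p <- sample_training_pair(idx)
  keep <- p$negative_predicate(c(idx$ranked_ids, NA))
  sims <- c(idx$similarities, NA)
  expect_true(all(keep[is.na(sims)]))
  expect_true(all(sims[which(keep & !is.na(sims))] < p$positive_sim))
  expect_false(any(sims[which(!keep)] < p$positive_sim, na.rm = TRUE))
  # singleton subset always yields its only member
  idx1 <- idx; idx1$subset_size <- 1L
  expect_equal(sample_training_pair(idx1)$positive_id, "s1")
})

test_that("training is deterministic under a fixed seed", {
  bench <- make_benchmark(synthetic_spec(n_archetypes = 4,
                                         members_per_archetype = 5,
                                         length_range = c(20, 24),
                                         seed = 3))
  ec <- encoder_config(mlp_dims = c(16, 24), lstm_hidden = 8,
                       n_res_blocks = 1, gc_dim = 32, descriptor_dim = 32)
  tc <- train_config(iterations = 25, batch_size = 8, queue_size = 32,
                     eval_every = 0)
  f1 <- strucr(bench$structures, bench$sim_table, encoder = ec,
               training = tc, seed = 17)
  f2 <- strucr(bench$structures, bench$sim_table, encoder = ec,
               training = tc, seed = 17)
  expect_identical(f1$log$loss, f2$log$loss)
  expect_identical(f1$encoder$params, f2$encoder$params)
  # checkpoints restore bit-compatible inference
  path <- withr::local_tempfile(fileext = ".rds")
  save_strucr(f1, path)
  f3 <- load_strucr(path)
  s <- bench$structures[[1]]
  expect_identical(predict(f1, s)$vectors, predict(f3, s)$vectors)
})

test_that("training reduces the InfoNCE loss on the model's own encodings", {
  fit <- get_trained_model()
  bench <- get_benchmark()
  # like-for-like: each encoder is scored on identical (query, positive)
  # pairs with negatives drawn from its *own* database encodings -- using a
  # foreign queue would reward a collapsed embedding
  untrained <- fixed_untrained_encoder(seed = 5)
  idx <- build_partition_index(bench$sim_table, 30)
  graphs <- lapply(bench$structures, featurize)
  ids <- names(graphs)
  loss_of <- function(enc) {
    d <- encode_structures(enc, graphs)$descriptors
    V <- d$vectors
    rownames(V) <- d$ids
    set.seed(41)
    qids <- sample(ids, 30)
    mean(vapply(qids, function(q) {
      p <- sample_training_pair(idx[[q]])
      keep <- ids[p$negative_predicate(ids) & ids != q]
      info_nce(V[q, ], V[p$positive_id, ], V[keep, , drop = FALSE],
               tau = 0.07)
    }, numeric(1)))
  }
  expect_lt(loss_of(fit$encoder), loss_of(untrained))
})

test_that("plateau scheduler divides the learning rate by 10 at most 3 times", {
  bench <- make_benchmark(synthetic_spec(n_archetypes = 2,
                                         members_per_archetype = 5,
                                         length_range = c(20, 22), seed = 9))
  ec <- encoder_config(mlp_dims = c(8, 12), lstm_hidden = 4,
                       n_res_blocks = 1, gc_dim = 16, descriptor_dim = 16)
  # patience 1 and no improvement threshold large enough that every
  # evaluation counts as a plateau -> one decay per evaluation, capped
  tc <- train_config(iterations = 30, batch_size = 4, queue_size = 16,
                     eval_every = 5, patience = 1, min_rel_improve = 10,
                     max_lr_decays = 3)
  fit <- strucr(bench$structures, bench$sim_table, encoder = ec,
                training = tc, seed = 2)
  expect_equal(fit$final_lr, 0.1 / 1000)
})
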
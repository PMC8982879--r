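# Shared fixtures: the desk-scale synthetic benchmark and a model trained
# on it, built once per test run and memoized.

.fixtures <- new.env(parent = emptyenv())

desk_encoder_config <- function() {
  encoder_config(mlp_dims = c(32, 48), lstm_hidden = 24,
                 n_res_blocks = 1, gc_dim = 64, descriptor_dim = 64)
}

desk_train_config <- function(iterations = 400, ...) {
  train_config(iterations = iterations, batch_size = 32, queue_size = 128,
               eval_every = 50, ...)
}

get_benchmark <- function() {
  if (is.null(.fixtures$bench)) {
    .fixtures$bench <- make_benchmark(synthetic_spec(seed = 11))
  }
  .fixtures$bench
}

get_trained_model <- function() {
  if (is.null(.fixtures$fit)) {
    bench <- get_benchmark()
    .fixtures$fit <- strucr(bench$structures, bench$sim_table,
                            encoder = desk_encoder_config(),
                            training = desk_train_config(), seed = 5)
  }
  .fixtures$fit
}

# Random-ranking AUPRC baseline for a neighbor structure: average of
# `reps` uniformly random rankings (macro over queries).
random_ranking_auprc <- function(ids, neighbors, reps = 20, seed = 123) {
  set.seed(seed)
  mean(replicate(reps, {
    rankings <- lapply(ids, function(q) {
      others <- sample(setdiff(ids, q))
      structure(list(query_id = q, ordered_ids = others,
                     distances = seq_along(others)),
                class = "ranking_result")
    })
    names(rankings) <- ids
    suppressWarnings(per_query_roc_pr(rankings, neighbors)$avg_auprc)
  }))
}

neighbors_from_sim <- function(sim_table, rho = 0.9) {
  ids <- rownames(sim_table)
  out <- lapply(ids, function(q) {
    others <- setdiff(ids, q)
    define_neighbors(sim_table[q, others], rho)$neighbor_ids
  })
  names(out) <- ids
  out
}

# A small untrained encoder with a fixed seed, for structural/invariance
# tests that do not need training.
fixed_untrained_encoder <- function(seed = 7, config = desk_encoder_config()) {
  set.seed(seed)
  init_encoder(config)
}
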
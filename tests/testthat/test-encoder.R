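# Encoder layers, readout, invariances, and gradient correctness.

test_that("graph_conv equals the per-node aggregation sum", {
  set.seed(12)
  X <- matrix(rnorm(20), 4, 5)
  A <- matrix(runif(16), 4, 4); A <- (A + t(A)) / 2
  W <- matrix(rnorm(15), 5, 3)
  out <- graph_conv(X, A, W)
  # brute-force: x_j' = sum_k a_jk x_k . W
  for (j in 1:4) {
    acc <- numeric(5)
    for (k in 1:4) acc <- acc + A[j, k] * X[k, ]
    expect_equal(out[j, ], as.vector(acc %*% W), tolerance = 1e-12)
  }
  # identity A, identity W, identity activation reproduces X
  expect_equal(graph_conv(X, diag(4), diag(5)), X)
  # zero input stays zero under ReLU
  expect_equal(graph_conv(matrix(0, 4, 5), A, W, function(z) pmax(z, 0)),
               matrix(0, 4, 3))
  expect_error(graph_conv(X, A, matrix(0, 4, 2)), "shape")
})

test_that("residual_block composes two graph convolutions plus the skip", {
  set.seed(13)
  X <- matrix(rnorm(18), 6, 3)
  A <- build_adjacency(matrix(rnorm(18, sd = 5), 6, 3))
  Wa <- matrix(rnorm(12), 3, 4); Wb <- matrix(rnorm(16), 4, 4)
  Ws <- matrix(rnorm(12), 3, 4)
  out <- residual_block(X, A, Wa, Wb, Ws)
  # hand-composed oracle from two graph_conv calls
  x1 <- graph_conv(X, A, Wa, function(z) pmax(z, 0))
  manual <- A %*% x1 %*% Wb + X %*% Ws
  manual <- ifelse(manual > 0, manual, 0.01 * manual)
  expect_equal(out, manual, tolerance = 1e-12)
  # zero weights + identity skip = pure skip path
  expect_equal(
    unname(residual_block(X, A, matrix(0, 3, 4), matrix(0, 4, 3), NULL,
                          identity)),
    X)
  # deterministic at dropout 0
  expect_identical(residual_block(X, A, Wa, Wb, Ws),
                   residual_block(X, A, Wa, Wb, Ws))
})

test_that("sequential_context is order-sensitive with fixed output shape", {
  enc <- fixed_untrained_encoder(seed = 3)
  set.seed(5)
  X <- matrix(rnorm(48 * 9), 9, 48)
  out <- sequential_context(X, enc$params$lstm)
  expect_equal(dim(out), c(9, 48))  # 2 * lstm_hidden = 48
  out_rev <- sequential_context(X[9:1, ], enc$params$lstm)
  expect_gt(max(abs(out - out_rev[9:1, ])), 0)  # order matters
  expect_identical(out, sequential_context(X, enc$params$lstm))
  one <- sequential_context(X[1, , drop = FALSE], enc$params$lstm)
  expect_equal(dim(one), c(1, 48))
})

test_that("descriptors are unit-norm, fixed-length, and padding-safe", {
  enc <- fixed_untrained_encoder()
  lens <- c(20, 45, 33)
  graphs <- lapply(seq_along(lens), function(i) {
    featurize(generate_archetype("mixed", lens[i], seed = 40 + i))
  })
  batch_out <- encode_structures(enc, graphs)
  v <- batch_out$descriptors$vectors
  expect_equal(dim(v), c(3, 64))  # length independent of N_r
  expect_equal(sqrt(rowSums(v^2)), rep(1, 3), tolerance = 1e-5)
  # batch vs single: identical in eval mode (padding/mask correctness)
  for (i in seq_along(graphs)) {
    single <- encode_structures(enc, graphs[[i]])$descriptors$vectors
    expect_lt(max(abs(single[1, ] - v[i, ])), 1e-5)
  }
  # residue embeddings: one row-normalized row per residue
  emb <- batch_out$residue_embeddings
  expect_equal(unname(vapply(emb, nrow, integer(1))), lens)
  expect_equal(sqrt(rowSums(emb[[2]]^2)), rep(1, lens[2]), tolerance = 1e-6)
})

test_that("descriptors inherit SE(3) invariance from the features", {
  enc <- fixed_untrained_encoder()
  s <- generate_archetype("helix_bundle", 50, seed = 9)
  d0 <- encode_structures(enc, featurize(s))$descriptors$vectors
  set.seed(31)
  for (k in 1:5) {
    st <- protein_structure("t", rigid_transform(
      s$ca_coords, random_rotation(), runif(3, -40, 40)))
    dt <- encode_structures(enc, featurize(st))$descriptors$vectors
    expect_lt(max(abs(d0 - dt)), 1e-5)
  }
})

test_that("max-pool readout is monotone under residue masking", {
  enc <- fixed_untrained_encoder()
  g <- featurize(generate_archetype("coil", 30, seed = 2))
  ns <- asNamespace("strucr")
  fw <- ns$encoder_forward(enc, ns$build_batch(list(g)))
  node <- fw$node_embed[[1]]
  full_max <- apply(node, 2, max)
  for (drop_row in c(1, 15, 30)) {
    expect_true(all(apply(node[-drop_row, , drop = FALSE], 2, max) <=
                      full_max + 1e-12))
  }
})

test_that("analytic gradients match finite differences", {
  ns <- asNamespace("strucr")
  set.seed(42)
  graphs <- lapply(1:3, function(i) {
    featurize(generate_archetype(c("helix_bundle", "sheet", "coil")[i],
                                 16 + 2 * i, seed = i), M = 4)
  })
  cfg <- encoder_config(input_dim = 16, mlp_dims = c(8, 10), lstm_hidden = 5,
                        n_res_blocks = 2, gc_dim = 9, descriptor_dim = 7,
                        dropout_rate = 0)
  enc <- init_encoder(cfg)
  batch <- ns$build_batch(graphs)
  G <- matrix(rnorm(21), 3, 7)
  lossfn <- function(e) {
    sum(ns$encoder_forward(e, batch, train = TRUE)$desc * G)
  }
  fw <- ns$encoder_forward(enc, batch, train = TRUE, with_cache = TRUE)
  ana <- unlist(ns$encoder_backward(enc, fw$cache, G))
  v <- unlist(enc$params)
  expect_length(ana, length(v))
  set.seed(99)
  ks <- sample(length(v), 40)
  h <- 1e-5
  num <- vapply(ks, function(k) {
    vp <- v; vp[k] <- vp[k] + h
    vm <- v; vm[k] <- vm[k] - h
    ep <- enc; ep$params <- utils::relist(vp, enc$params)
    em <- enc; em$params <- utils::relist(vm, enc$params)
    (lossfn(ep) - lossfn(em)) / (2 * h)
  }, numeric(1))
  expect_lt(max(abs(num - ana[ks]) / pmax(abs(num) + abs(ana[ks]), 1e-4)),
            1e-5)
})
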
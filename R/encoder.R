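# GNN-based structure encoder.
#
# Architecture (sequence module -> graph module -> readout):
#   raw node features (N x d)
#     -> MLP (linear + BN + leaky ReLU per layer)
#     -> BiLSTM over the residue order, hidden states of both directions
#        concatenated per position, + BN
#     -> stacked residual graph-convolution blocks; each block is
#        X1 = dropout(ReLU(BN(A X Wa)));  X2 = lrelu(A X1 Wb + X Ws)
#        with Ws the identity when dimensions already match
#     -> global max-pool over (real) residues -> L2 normalization
#        => unit descriptor of fixed length L.
# The final block's node matrix doubles as residue-level embeddings.
#
# The adjacency A is the normalized complete-graph matrix of
# build_adjacency(); it already carries self-loops and normalization, so the
# graph convolution is plain sigma(A X W).
#
# All forward and backward passes are written directly in base R matrix
# algebra (no autodiff framework); gradients are verified against finite
# differences in the test suite.

#' Encoder hyperparameter configuration
#'
#' @param input_dim raw node-feature width `d` (2^M; 32 at M = 5).
#' @param mlp_dims widths of the MLP layers applied per residue before the
#'   BiLSTM.
#' @param lstm_hidden hidden size of each LSTM direction (concatenated
#'   output width is `2 * lstm_hidden`).
#' @param n_res_blocks number of residual graph-convolution blocks.
#' @param gc_dim width of the residual blocks before the last.
#' @param descriptor_dim descriptor length `L`; also the width of the final
#'   residual block, whose node matrix is max-pooled into the descriptor.
#' @param dropout_rate dropout probability after the first GC layer of each
#'   residual block (training only).
#' @param leaky_slope negative slope of the leaky ReLU used outside the
#'   ReLU-carrying GC layer.
#' @return an object of class `encoder_config`.
#' @export
encoder_config <- function(input_dim = 32, mlp_dims = c(64, 128),
                           lstm_hidden = 64, n_res_blocks = 3,
                           gc_dim = 256, descriptor_dim = 512,
                           dropout_rate = 0.1, leaky_slope = 0.01) {
  stopifnot(input_dim > 0, all(mlp_dims > 0), lstm_hidden > 0,
            n_res_blocks >= 1, gc_dim > 0, descriptor_dim > 0,
            dropout_rate >= 0, dropout_rate < 1)
  structure(
    list(input_dim = as.integer(input_dim), mlp_dims = as.integer(mlp_dims),
         lstm_hidden = as.integer(lstm_hidden),
         n_res_blocks = as.integer(n_res_blocks),
         gc_dim = as.integer(gc_dim),
         descriptor_dim = as.integer(descriptor_dim),
         dropout_rate = dropout_rate, leaky_slope = leaky_slope),
    class = "encoder_config"
  )
}

## ---- activations -----------------------------------------------------------

lrelu <- function(x, slope) ifelse(x > 0, x, slope * x)
lrelu_grad <- function(x, slope) ifelse(x > 0, 1, slope)

sigmoid <- function(x) 1 / (1 + exp(-x))

## ---- batch normalization ---------------------------------------------------

# Mask-aware BN over the rows of a flat (total-residues x d) matrix.
# `chunks` (a list of row-index vectors) computes statistics per chunk,
# which is how shuffled BN is emulated for the key encoder on one device.
bn_forward <- function(x, gamma, beta, run_mean, run_var,
                       train, chunks = NULL, eps = 1e-5, momentum = 0.1) {
  if (!train) {
    inv <- 1 / sqrt(run_var + eps)
    xhat <- sweep(sweep(x, 2, run_mean), 2, inv, `*`)
    out <- sweep(sweep(xhat, 2, gamma, `*`), 2, beta, `+`)
    return(list(out = out, cache = NULL, run_mean = run_mean, run_var = run_var))
  }
  if (is.null(chunks)) chunks <- list(seq_len(nrow(x)))
  out <- x
  xhat <- x
  inv_all <- vector("list", length(chunks))
  for (ci in seq_along(chunks)) {
    rows <- chunks[[ci]]
    xc <- x[rows, , drop = FALSE]
    mu <- colMeans(xc)
    v <- colMeans(sweep(xc, 2, mu)^2)
    inv <- 1 / sqrt(v + eps)
    xh <- sweep(sweep(xc, 2, mu), 2, inv, `*`)
    xhat[rows, ] <- xh
    out[rows, ] <- sweep(sweep(xh, 2, gamma, `*`), 2, beta, `+`)
    inv_all[[ci]] <- inv
    run_mean <- (1 - momentum) * run_mean + momentum * mu
    run_var <- (1 - momentum) * run_var + momentum * v
  }
  list(out = out,
       cache = list(xhat = xhat, inv = inv_all, chunks = chunks, gamma = gamma),
       run_mean = run_mean, run_var = run_var)
}

# Backward for the single-chunk (query-encoder) case.
bn_backward <- function(dy, cache) {
  stopifnot(length(cache$chunks) == 1)
  xhat <- cache$xhat
  inv <- cache$inv[[1]]
  n <- nrow(xhat)
  dgamma <- colSums(dy * xhat)
  dbeta <- colSums(dy)
  dxhat <- sweep(dy, 2, cache$gamma, `*`)
  t1 <- sweep(dxhat, 2, colMeans(dxhat))
  t2 <- sweep(xhat, 2, colSums(dxhat * xhat) / n, `*`)
  dx <- sweep(t1 - t2, 2, inv, `*`)
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

## ---- parameter initialization ---------------------------------------------

glorot <- function(nin, nout) {
  matrix(stats::rnorm(nin * nout, sd = sqrt(2 / (nin + nout))), nin, nout)
}

#' Initialize an encoder (parameters + BN running state)
#'
#' Weights are Glorot-initialized from the current RNG state; LSTM forget
#' gates get a +1 bias. Returns an object of class `strucr_encoder` holding
#' `params` (trainable), `state` (BN running statistics) and `config`.
#'
#' @param config an [encoder_config].
#' @return a `strucr_encoder` object.
#' @export
init_encoder <- function(config = encoder_config()) {
  stopifnot(inherits(config, "encoder_config"))
  H <- config$lstm_hidden
  dims <- c(config$input_dim, config$mlp_dims)
  mlp <- list()
  for (j in seq_along(config$mlp_dims)) {
    mlp[[j]] <- list(W = glorot(dims[j], dims[j + 1]),
                     b = numeric(dims[j + 1]),
                     gamma = rep(1, dims[j + 1]), beta = numeric(dims[j + 1]))
  }
  d_mlp <- dims[length(dims)]
  lstm_dir <- function() {
    b <- numeric(4 * H)
    b[(H + 1):(2 * H)] <- 1  # forget-gate bias
    list(Wx = glorot(d_mlp, 4 * H), Wh = glorot(H, 4 * H), b = b)
  }
  lstm <- list(fwd = lstm_dir(), rev = lstm_dir(),
               gamma = rep(1, 2 * H), beta = numeric(2 * H))
  block_dims <- c(2 * H,
                  if (config$n_res_blocks > 1)
                    rep(config$gc_dim, config$n_res_blocks - 1),
                  config$descriptor_dim)
  blocks <- list()
  for (i in seq_len(config$n_res_blocks)) {
    d_in <- block_dims[i]; d_out <- block_dims[i + 1]
    blocks[[i]] <- list(
      Wa = glorot(d_in, d_out),
      gamma = rep(1, d_out), beta = numeric(d_out),
      Wb = glorot(d_out, d_out),
      Ws = if (d_in != d_out) glorot(d_in, d_out) else NULL
    )
  }
  params <- list(mlp = mlp, lstm = lstm, blocks = blocks)
  state <- list(
    mlp = lapply(config$mlp_dims, function(d) list(mean = numeric(d),
                                                   var = rep(1, d))),
    lstm = list(mean = numeric(2 * H), var = rep(1, 2 * H)),
    blocks = lapply(seq_len(config$n_res_blocks), function(i) {
      d <- block_dims[i + 1]
      list(mean = numeric(d), var = rep(1, d))
    })
  )
  structure(list(params = params, state = state, config = config),
            class = "strucr_encoder")
}

## ---- batching --------------------------------------------------------------

# Stack a list of structure_graphs into a flat representation:
# flat node features (sum N_r x d), per-structure row indices, lengths and
# adjacency matrices. No padding is needed outside the BiLSTM.
build_batch <- function(graphs) {
  stopifnot(length(graphs) > 0)
  lens <- vapply(graphs, function(g) g$n_residues, integer(1))
  offs <- cumsum(c(0L, lens[-length(lens)]))
  idx <- lapply(seq_along(graphs), function(b) offs[b] + seq_len(lens[b]))
  list(x = do.call(rbind, lapply(graphs, function(g) g$node_features)),
       idx = idx, lens = lens,
       A = lapply(graphs, function(g) g$adjacency),
       ids = vapply(graphs, function(g) g$structure_id, character(1)))
}

## ---- BiLSTM ----------------------------------------------------------------

# One LSTM direction over a padded (B x T x D) array; mask handled by zero
# gradient injection at padded steps (padding always sits at the tail).
lstm_forward_dir <- function(xpad, lens, p) {
  B <- dim(xpad)[1]; T <- dim(xpad)[2]
  H <- nrow(p$Wh)
  n_gates <- 4 * H
  h <- matrix(0, B, H); c_ <- matrix(0, B, H)
  cache <- vector("list", T)
  hs <- array(0, c(B, T, H))
  for (t in seq_len(T)) {
    xt <- matrix(xpad[, t, ], B)
    z <- xt %*% p$Wx + h %*% p$Wh
    z <- sweep(z, 2, p$b, `+`)
    i <- sigmoid(z[, 1:H, drop = FALSE])
    f <- sigmoid(z[, (H + 1):(2 * H), drop = FALSE])
    g <- tanh(z[, (2 * H + 1):(3 * H), drop = FALSE])
    o <- sigmoid(z[, (3 * H + 1):n_gates, drop = FALSE])
    c_new <- f * c_ + i * g
    tc <- tanh(c_new)
    h_new <- o * tc
    cache[[t]] <- list(xt = xt, h_prev = h, c_prev = c_,
                       i = i, f = f, g = g, o = o, tc = tc)
    h <- h_new; c_ <- c_new
    hs[, t, ] <- h
  }
  list(hs = hs, cache = cache)
}

lstm_backward_dir <- function(dhs, cache, p) {
  T <- length(cache)
  H <- nrow(p$Wh)
  B <- nrow(cache[[1]]$h_prev)
  dWx <- matrix(0, nrow(p$Wx), ncol(p$Wx))
  dWh <- matrix(0, nrow(p$Wh), ncol(p$Wh))
  db <- numeric(length(p$b))
  dx <- array(0, c(B, T, nrow(p$Wx)))
  dh_next <- matrix(0, B, H); dc_next <- matrix(0, B, H)
  for (t in rev(seq_len(T))) {
    cc <- cache[[t]]
    dh <- matrix(dhs[, t, ], B) + dh_next
    do_ <- dh * cc$tc
    dct <- dc_next + dh * cc$o * (1 - cc$tc^2)
    di <- dct * cc$g
    df <- dct * cc$c_prev
    dg <- dct * cc$i
    dz <- cbind(di * cc$i * (1 - cc$i),
                df * cc$f * (1 - cc$f),
                dg * (1 - cc$g^2),
                do_ * cc$o * (1 - cc$o))
    dWx <- dWx + crossprod(cc$xt, dz)
    dWh <- dWh + crossprod(cc$h_prev, dz)
    db <- db + colSums(dz)
    dx[, t, ] <- dz %*% t(p$Wx)
    dh_next <- dz %*% t(p$Wh)
    dc_next <- dct * cc$f
  }
  list(dWx = dWx, dWh = dWh, db = db, dx = dx)
}

# flat (R_total x D) -> padded (B x T x D), with optional per-sequence
# reversal (for the reverse LSTM direction).
flat_to_pad <- function(flat, idx, lens, reverse = FALSE) {
  B <- length(idx); T <- max(lens); D <- ncol(flat)
  xpad <- array(0, c(B, T, D))
  for (b in seq_len(B)) {
    rows <- idx[[b]]
    if (reverse) rows <- rev(rows)
    xpad[b, seq_len(lens[b]), ] <- flat[rows, ]
  }
  xpad
}

pad_to_flat <- function(xpad, idx, lens, reverse = FALSE) {
  D <- dim(xpad)[3]
  flat <- matrix(0, sum(lens), D)
  for (b in seq_along(idx)) {
    rows <- idx[[b]]
    if (reverse) rows <- rev(rows)
    flat[rows, ] <- matrix(xpad[b, seq_len(lens[b]), ], lens[b])
  }
  flat
}

## ---- full forward pass -----------------------------------------------------

# enc: strucr_encoder; batch: build_batch() output.
# train: batch-stat BN (+ dropout when `dropout = TRUE`), cache kept for
#   backward when `with_cache = TRUE`.
# bn_chunks > 1 emulates shuffled BN (key encoder): rows are grouped by a
#   random permutation of the batch members and BN statistics are computed
#   per chunk.
# Returns descriptors (B x L, unit rows), per-structure node embeddings,
# updated BN state, and the backward cache.
encoder_forward <- function(enc, batch, train = FALSE, dropout = FALSE,
                            bn_chunks = 1, with_cache = FALSE) {
  p <- enc$params; st <- enc$state; cfg <- enc$config
  slope <- cfg$leaky_slope
  chunks <- NULL
  if (train && bn_chunks > 1 && length(batch$idx) >= 2 * bn_chunks) {
    perm <- sample(length(batch$idx))
    grp <- split(perm, cut(seq_along(perm), bn_chunks, labels = FALSE))
    chunks <- lapply(grp, function(bs) unlist(batch$idx[bs], use.names = FALSE))
  }
  cache <- if (with_cache) list() else NULL
  x <- batch$x

  # MLP
  mlp_cache <- vector("list", length(p$mlp))
  for (j in seq_along(p$mlp)) {
    pj <- p$mlp[[j]]
    z <- sweep(x %*% pj$W, 2, pj$b, `+`)
    bn <- bn_forward(z, pj$gamma, pj$beta,
                     st$mlp[[j]]$mean, st$mlp[[j]]$var,
                     train = train, chunks = chunks)
    st$mlp[[j]]$mean <- bn$run_mean; st$mlp[[j]]$var <- bn$run_var
    a <- lrelu(bn$out, slope)
    if (with_cache) mlp_cache[[j]] <- list(x_in = x, bn = bn$cache, pre_act = bn$out)
    x <- a
  }

  # BiLSTM
  xpad_f <- flat_to_pad(x, batch$idx, batch$lens, reverse = FALSE)
  xpad_r <- flat_to_pad(x, batch$idx, batch$lens, reverse = TRUE)
  lf <- lstm_forward_dir(xpad_f, batch$lens, p$lstm$fwd)
  lr <- lstm_forward_dir(xpad_r, batch$lens, p$lstm$rev)
  hf <- pad_to_flat(lf$hs, batch$idx, batch$lens, reverse = FALSE)
  hr <- pad_to_flat(lr$hs, batch$idx, batch$lens, reverse = TRUE)
  hcat <- cbind(hf, hr)
  bnl <- bn_forward(hcat, p$lstm$gamma, p$lstm$beta,
                    st$lstm$mean, st$lstm$var, train = train, chunks = chunks)
  st$lstm$mean <- bnl$run_mean; st$lstm$var <- bnl$run_var
  x <- bnl$out
  lstm_cache <- if (with_cache) {
    list(x_in_pad_f = xpad_f, x_in_pad_r = xpad_r,
         cache_f = lf$cache, cache_r = lr$cache, bn = bnl$cache)
  }

  # residual GC blocks
  B <- length(batch$idx)
  block_cache <- vector("list", length(p$blocks))
  for (i in seq_along(p$blocks)) {
    pb <- p$blocks[[i]]
    ax <- matrix(0, nrow(x), ncol(x))
    for (b in seq_len(B)) {
      rows <- batch$idx[[b]]
      ax[rows, ] <- batch$A[[b]] %*% x[rows, , drop = FALSE]
    }
    z1 <- ax %*% pb$Wa
    bn1 <- bn_forward(z1, pb$gamma, pb$beta,
                      st$blocks[[i]]$mean, st$blocks[[i]]$var,
                      train = train, chunks = chunks)
    st$blocks[[i]]$mean <- bn1$run_mean; st$blocks[[i]]$var <- bn1$run_var
    r1 <- pmax(bn1$out, 0)  # ReLU after the first GC layer
    if (train && dropout && cfg$dropout_rate > 0) {
      mask <- matrix(stats::runif(length(r1)) >= cfg$dropout_rate,
                     nrow(r1), ncol(r1)) / (1 - cfg$dropout_rate)
      d1 <- r1 * mask
    } else {
      mask <- NULL
      d1 <- r1
    }
    ad1 <- matrix(0, nrow(d1), ncol(d1))
    for (b in seq_len(B)) {
      rows <- batch$idx[[b]]
      ad1[rows, ] <- batch$A[[b]] %*% d1[rows, , drop = FALSE]
    }
    skip <- if (is.null(pb$Ws)) x else x %*% pb$Ws
    z2 <- ad1 %*% pb$Wb + skip
    out <- lrelu(z2, slope)
    if (with_cache) {
      block_cache[[i]] <- list(x_in = x, ax = ax, bn = bn1$cache,
                               pre_relu = bn1$out, r1 = r1, mask = mask,
                               d1 = d1, ad1 = ad1, z2 = z2)
    }
    x <- out
  }

  # readout: per-structure column-wise max over real residues, L2-normalize
  L <- ncol(x)
  z <- matrix(0, B, L)
  amax <- matrix(0L, B, L)
  for (b in seq_len(B)) {
    rows <- batch$idx[[b]]
    xb <- x[rows, , drop = FALSE]
    am <- max.col(t(xb), ties.method = "first")
    amax[b, ] <- rows[am]
    z[b, ] <- xb[cbind(am, seq_len(L))]
  }
  znorm <- sqrt(rowSums(z^2))
  znorm[znorm == 0] <- 1
  desc <- z / znorm

  node_embed <- lapply(seq_len(B), function(b) x[batch$idx[[b]], , drop = FALSE])
  names(node_embed) <- batch$ids
  if (with_cache) {
    cache <- list(batch = batch, mlp = mlp_cache, lstm = lstm_cache,
                  blocks = block_cache, amax = amax, z = z, znorm = znorm,
                  desc = desc, n_rows = nrow(x))
  }
  list(desc = desc, node_embed = node_embed, state = st, cache = cache)
}

## ---- full backward pass ----------------------------------------------------

# ddesc: gradient of the loss w.r.t. the (normalized) descriptors, B x L.
# Returns gradients with the same nesting as enc$params.
encoder_backward <- function(enc, cache, ddesc) {
  p <- enc$params; cfg <- enc$config
  slope <- cfg$leaky_slope
  batch <- cache$batch
  B <- length(batch$idx)
  L <- ncol(ddesc)

  # through L2 normalization: dz = (ddesc - desc * rowSums(desc*ddesc)) / ||z||
  dz <- (ddesc - cache$desc * rowSums(cache$desc * ddesc)) / cache$znorm

  # through max-pool: route each column's gradient to its argmax row
  dx <- matrix(0, cache$n_rows, L)
  for (b in seq_len(B)) {
    tgt <- cbind(cache$amax[b, ], seq_len(L))
    dx[tgt] <- dx[tgt] + dz[b, ]
  }

  grads <- list(mlp = vector("list", length(p$mlp)),
                lstm = NULL,
                blocks = vector("list", length(p$blocks)))

  # residual blocks, last to first
  for (i in rev(seq_along(p$blocks))) {
    pb <- p$blocks[[i]]
    bc <- cache$blocks[[i]]
    dz2 <- dx * lrelu_grad(bc$z2, slope)
    dWb <- crossprod(bc$ad1, dz2)
    dad1 <- dz2 %*% t(pb$Wb)
    if (is.null(pb$Ws)) {
      dx_in_skip <- dz2
      dWs <- NULL
    } else {
      dWs <- crossprod(bc$x_in, dz2)
      dx_in_skip <- dz2 %*% t(pb$Ws)
    }
    dd1 <- matrix(0, nrow(dad1), ncol(dad1))
    for (b in seq_len(B)) {
      rows <- batch$idx[[b]]
      dd1[rows, ] <- batch$A[[b]] %*% dad1[rows, , drop = FALSE]  # A symmetric
    }
    dr1 <- if (is.null(bc$mask)) dd1 else dd1 * bc$mask
    dbn1 <- dr1 * (bc$pre_relu > 0)
    bnb <- bn_backward(dbn1, bc$bn)
    dz1 <- bnb$dx
    dWa <- crossprod(bc$ax, dz1)
    dax <- dz1 %*% t(pb$Wa)
    dx_in_gc <- matrix(0, nrow(dax), ncol(dax))
    for (b in seq_len(B)) {
      rows <- batch$idx[[b]]
      dx_in_gc[rows, ] <- batch$A[[b]] %*% dax[rows, , drop = FALSE]
    }
    dx <- dx_in_gc + dx_in_skip
    grads$blocks[[i]] <- list(Wa = dWa, gamma = bnb$dgamma, beta = bnb$dbeta,
                              Wb = dWb, Ws = dWs)
  }

  # BiLSTM (+ its BN)
  lc <- cache$lstm
  bnb <- bn_backward(dx, lc$bn)
  H <- cfg$lstm_hidden
  dh_f <- flat_to_pad(bnb$dx[, 1:H, drop = FALSE], batch$idx, batch$lens,
                      reverse = FALSE)
  dh_r <- flat_to_pad(bnb$dx[, (H + 1):(2 * H), drop = FALSE], batch$idx,
                      batch$lens, reverse = TRUE)
  lbf <- lstm_backward_dir(dh_f, lc$cache_f, p$lstm$fwd)
  lbr <- lstm_backward_dir(dh_r, lc$cache_r, p$lstm$rev)
  dx <- pad_to_flat(lbf$dx, batch$idx, batch$lens, reverse = FALSE) +
        pad_to_flat(lbr$dx, batch$idx, batch$lens, reverse = TRUE)
  grads$lstm <- list(fwd = list(Wx = lbf$dWx, Wh = lbf$dWh, b = lbf$db),
                     rev = list(Wx = lbr$dWx, Wh = lbr$dWh, b = lbr$db),
                     gamma = bnb$dgamma, beta = bnb$dbeta)

  # MLP, last to first
  for (j in rev(seq_along(p$mlp))) {
    mc <- cache$mlp[[j]]
    dbn <- dx * lrelu_grad(mc$pre_act, slope)
    bnb <- bn_backward(dbn, mc$bn)
    dzj <- bnb$dx
    grads$mlp[[j]] <- list(W = crossprod(mc$x_in, dzj), b = colSums(dzj),
                           gamma = bnb$dgamma, beta = bnb$dbeta)
    dx <- dzj %*% t(p$mlp[[j]]$W)
  }
  grads
}

## ---- standalone layer operations ------------------------------------------

#' Graph convolution sigma(A X W)
#'
#' Single graph-convolution layer: the adjacency matrix itself acts as the
#' aggregation weight matrix (it is already normalized and carries
#' self-loops), so the layer is the activated product `A X W`.
#'
#' @param X node matrix (N x d_in).
#' @param A N x N adjacency matrix.
#' @param W d_in x d_out weight matrix.
#' @param activation activation function (default identity).
#' @return N x d_out node matrix.
#' @export
graph_conv <- function(X, A, W, activation = identity) {
  X <- as.matrix(X); A <- as.matrix(A); W <- as.matrix(W)
  if (ncol(A) != nrow(X) || ncol(X) != nrow(W)) stop("shape mismatch")
  activation(A %*% X %*% W)
}

#' Residual graph-convolution block
#'
#' `X2 = sigma(A X1 Wb + X Ws)` with `X1 = dropout(relu(A X Wa))`; `Ws` is
#' the identity map when input and output widths agree. This is the
#' batch-norm-free form of the block used inside the encoder, exposed for
#' composition and testing.
#'
#' @param X node matrix; @param A adjacency; @param Wa,Wb GC weights.
#' @param Ws optional skip-projection weights (NULL = identity skip).
#' @param activation output activation (default leaky ReLU, slope 0.01).
#' @param dropout_rate dropout after the first GC layer (0 = deterministic).
#' @return node matrix with `ncol(Wb)` columns.
#' @export
residual_block <- function(X, A, Wa, Wb, Ws = NULL,
                           activation = function(z) lrelu(z, 0.01),
                           dropout_rate = 0) {
  x1 <- graph_conv(X, A, Wa, function(z) pmax(z, 0))
  if (dropout_rate > 0) {
    x1 <- x1 * (matrix(stats::runif(length(x1)) >= dropout_rate,
                       nrow(x1), ncol(x1)) / (1 - dropout_rate))
  }
  skip <- if (is.null(Ws)) X else X %*% Ws
  if (!identical(dim(skip), c(nrow(x1), ncol(Wb)))) {
    if (ncol(skip) != ncol(Wb)) stop("skip dimension mismatch; supply Ws")
  }
  activation(A %*% x1 %*% Wb + skip)
}

#' BiLSTM sequential context over one residue sequence
#'
#' Runs the two LSTM directions over the rows of `X` (residue order) and
#' concatenates their hidden states per position, the order-sensitive
#' initial node embedding the graph convolutions build on.
#'
#' @param X node matrix (N x d), rows in residue order.
#' @param lstm_params list with `fwd` and `rev` sublists (`Wx`, `Wh`, `b`),
#'   e.g. `init_encoder(cfg)$params$lstm`.
#' @return N x (2 * lstm_hidden) matrix.
#' @export
sequential_context <- function(X, lstm_params) {
  X <- as.matrix(X)
  if (nrow(X) == 0) stop("empty input")
  n <- nrow(X)
  xpad <- array(X, c(1, n, ncol(X)) )
  xpad[1, , ] <- X
  xrev <- xpad
  xrev[1, , ] <- X[n:1, , drop = FALSE]
  hf <- lstm_forward_dir(xpad, n, lstm_params$fwd)$hs
  hr <- lstm_forward_dir(xrev, n, lstm_params$rev)$hs
  H <- nrow(lstm_params$fwd$Wh)
  out <- cbind(matrix(hf[1, , ], n, H), matrix(hr[1, n:1, ], n, H))
  out
}

## ---- public encoding -------------------------------------------------------

#' Encode structure graphs into descriptors and residue embeddings
#'
#' Runs the encoder forward pass. In `"eval"` mode batch normalization uses
#' running statistics and dropout is off, so results are deterministic and
#' independent of batch composition.
#'
#' @param enc a `strucr_encoder` (see [init_encoder]) or a fitted [strucr]
#'   model (its query encoder is used).
#' @param graphs a `structure_graph` or list of them (see [featurize]).
#' @param mode `"eval"` (default) or `"train"`.
#' @return list with `descriptors` (a `descriptor_set`: ids, unit-row matrix
#'   `vectors`, residue counts `lengths`) and `residue_embeddings` (list of
#'   N_r x L matrices, rows L2-normalized).
#' @export
encode_structures <- function(enc, graphs, mode = c("eval", "train")) {
  mode <- match.arg(mode)
  if (inherits(enc, "strucr")) enc <- enc$encoder
  stopifnot(inherits(enc, "strucr_encoder"))
  if (inherits(graphs, "structure_graph")) graphs <- list(graphs)
  batch <- build_batch(graphs)
  fw <- encoder_forward(enc, batch, train = (mode == "train"),
                        dropout = (mode == "train"))
  desc <- structure(
    list(ids = batch$ids, vectors = fw$desc, lengths = batch$lens),
    class = "descriptor_set"
  )
  list(descriptors = desc,
       residue_embeddings = lapply(fw$node_embed, row_normalize))
}

#' @export
print.descriptor_set <- function(x, ...) {
  cat(sprintf("<descriptor_set> %d structures, descriptor length %d\n",
              length(x$ids), ncol(x$vectors)))
  invisible(x)
}
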
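#' Model configuration for the five-block Chebyshev GCN
#'
#' The network stacks `n_blocks` graph-convolutional blocks. Block `b` maps
#' `dims[b]` input channels to `dims[b+1]` output channels with a Chebyshev
#' spectral convolution of order `cheb_orders[b]`, followed by batch
#' normalization, Leaky ReLU and (when `double_batchnorm`) a second batch
#' normalization. After the last block a dropout layer (training only) and a
#' per-node softmax produce 2-class probabilities.
#'
#' @param n_blocks number of graph-convolutional blocks.
#' @param dims channel sizes, length `n_blocks + 1`; the final dimension
#'   must be 2 (lesion / non-lesion).
#' @param cheb_orders Chebyshev order per block (scalar recycled). The
#'   per-layer order is a free architectural choice; 3 gives 2-hop filters.
#' @param leaky_relu_slope negative-side slope of the Leaky ReLU.
#' @param dropout_rate dropout probability applied after the last block.
#' @param double_batchnorm add the second batch normalization per block.
#' @return an object of class `model_config`.
#' @export
model_config <- function(n_blocks = 5L,
                         dims = c(16L, 16L, 16L, 16L, 16L, 2L),
                         cheb_orders = 3L,
                         leaky_relu_slope = 0.01,
                         dropout_rate = 0.3,
                         double_batchnorm = TRUE) {
  if (length(dims) != n_blocks + 1)
    stop_input("dims must have length n_blocks + 1")
  if (dims[length(dims)] != 2)
    stop_input("final dimension must be 2 (lesion / non-lesion)")
  cheb_orders <- as.integer(rep_len(cheb_orders, n_blocks))
  if (any(cheb_orders < 1)) stop_input("Chebyshev orders must be >= 1")
  if (dropout_rate < 0 || dropout_rate >= 1) stop_input("dropout_rate must be in [0, 1)")
  structure(list(n_blocks = as.integer(n_blocks), dims = as.integer(dims),
                 cheb_orders = cheb_orders,
                 leaky_relu_slope = leaky_relu_slope,
                 dropout_rate = dropout_rate,
                 double_batchnorm = isTRUE(double_batchnorm)),
            class = "model_config")
}

#' Training configuration
#'
#' Defaults follow the hyperparameter study backing this architecture:
#' Adadelta optimization of a per-node cross-entropy loss, weight decay
#' `6e-4` on the Chebyshev coefficient tensors, dropout handled by the
#' model config, 150 epochs. `learning_rate` is the Adadelta step
#' multiplier; the default 1.0 is the method's original parameter-free
#' form (see the methods vignette for why a small multiplier freezes
#' Adadelta at its \eqn{\sqrt{\epsilon}} step anchor).
#'
#' @param optimizer only `"adadelta"` is implemented.
#' @param loss only `"cross_entropy"` is implemented.
#' @param learning_rate Adadelta step multiplier.
#' @param rho Adadelta decay of the squared-gradient / squared-step
#'   accumulators.
#' @param eps Adadelta numerical floor.
#' @param weight_decay L2 coefficient applied to convolution weights.
#' @param epochs training epochs (one pass over all graphs, one
#'   optimization step per graph).
#' @param class_weights use inverse-frequency class weights in the loss.
#' @param shuffle reshuffle graph order each epoch (seeded).
#' @param bn_momentum momentum of the batch-normalization running statistics.
#' @param seed integer seed driving parameter initialization, shuffling and
#'   dropout.
#' @return an object of class `train_config`.
#' @export
train_config <- function(optimizer = "adadelta",
                         loss = "cross_entropy",
                         learning_rate = 1.0,
                         rho = 0.9,
                         eps = 1e-6,
                         weight_decay = 6e-4,
                         epochs = 150L,
                         class_weights = FALSE,
                         shuffle = TRUE,
                         bn_momentum = 0.1,
                         seed = 1L) {
  optimizer <- match.arg(optimizer, "adadelta")
  loss <- match.arg(loss, "cross_entropy")
  if (learning_rate < 0) stop_input("learning_rate must be nonnegative")
  if (epochs < 1) stop_input("epochs must be >= 1")
  structure(list(optimizer = optimizer, loss = loss,
                 learning_rate = learning_rate, rho = rho, eps = eps,
                 weight_decay = weight_decay, epochs = as.integer(epochs),
                 class_weights = isTRUE(class_weights),
                 shuffle = isTRUE(shuffle), bn_momentum = bn_momentum,
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Total trainable parameter count of a model configuration
#'
#' Each convolution contributes `order * in * out` coefficients plus `out`
#' biases (e.g. `256 * O + 16` for a 16-to-16 layer, `32 * O + 2` for the
#' final 16-to-2 layer); each batch normalization contributes a scale and a
#' shift per channel.
#'
#' @param cfg a [model_config()].
#' @return integer parameter count.
#' @export
parameter_count <- function(cfg) {
  total <- 0L
  for (b in seq_len(cfg$n_blocks)) {
    din <- cfg$dims[b]; dout <- cfg$dims[b + 1]
    total <- total + cfg$cheb_orders[b] * din * dout + dout
    n_bn <- if (cfg$double_batchnorm) 2L else 1L
    total <- total + n_bn * 2L * dout
  }
  as.integer(total)
}

# ---- parameter initialization -------------------------------------------

# Glorot-uniform Chebyshev coefficient tensors theta[[k]] (in x out),
# zero biases, unit-scale batchnorms. Must be called inside a seeded RNG
# context.
init_params <- function(cfg) {
  params <- vector("list", cfg$n_blocks)
  for (b in seq_len(cfg$n_blocks)) {
    din <- cfg$dims[b]; dout <- cfg$dims[b + 1]; O <- cfg$cheb_orders[b]
    lim <- sqrt(6 / (din * O + dout))
    theta <- lapply(seq_len(O), function(k)
      matrix(runif(din * dout, -lim, lim), din, dout))
    bn <- function() list(gamma = rep(1, dout), beta = rep(0, dout),
                          run_mean = rep(0, dout), run_var = rep(1, dout))
    params[[b]] <- list(theta = theta, bias = rep(0, dout),
                        bn1 = bn(),
                        bn2 = if (cfg$double_batchnorm) bn() else NULL,
                        order = O, din = din, dout = dout)
  }
  params
}

# enumerate all trainable tensors of an instantiated parameter set
count_instantiated_params <- function(params) {
  n <- 0L
  for (p in params) {
    n <- n + sum(vapply(p$theta, length, integer(1))) + length(p$bias)
    n <- n + length(p$bn1$gamma) + length(p$bn1$beta)
    if (!is.null(p$bn2)) n <- n + length(p$bn2$gamma) + length(p$bn2$beta)
  }
  n
}

# ---- layer forward / backward -------------------------------------------
#
# Internals run in channel-major layout (features are C x N matrices,
# channels down the rows, nodes across the columns): per-channel
# broadcasts then reduce to native column-major recycling, and the
# Chebyshev recurrence applies Lt on the right (Lt is symmetric, so
# (Lt t(X))' = X Lt). The public surface stays node-major (N x F).

BN_EPS <- 1e-5

# Chebyshev convolution: out = sum_k t(theta_k) %*% (X T_k(Lt)) + bias.
# Returns output and the basis signals S_k needed for gradients.
chebconv_forward <- function(Lt, X, theta, bias) {
  O <- length(theta)
  S <- vector("list", O)
  S[[1]] <- X
  if (O >= 2) S[[2]] <- X %*% Lt
  if (O >= 3) for (k in 3:O) S[[k]] <- 2 * (S[[k - 1]] %*% Lt) - S[[k - 2]]
  out <- crossprod(theta[[1]], S[[1]])
  if (O > 1) for (k in 2:O) out <- out + crossprod(theta[[k]], S[[k]])
  list(out = out + bias, S = S)
}

# Gradients of the Chebyshev convolution. T_k(Lt) is symmetric, so the
# input gradient reuses the same recurrence on theta_k %*% dOut.
chebconv_backward <- function(Lt, cache, theta, dOut) {
  O <- length(theta)
  dtheta <- vector("list", O)
  for (k in seq_len(O)) dtheta[[k]] <- tcrossprod(cache$S[[k]], dOut)
  dbias <- rowSums(dOut)
  dX <- theta[[1]] %*% dOut
  if (O >= 2) dX <- dX + (theta[[2]] %*% dOut) %*% Lt
  if (O >= 3) {
    for (k in 3:O) {
      V <- theta[[k]] %*% dOut
      t0 <- V; t1 <- V %*% Lt
      for (j in 3:k) { t2 <- 2 * (t1 %*% Lt) - t0; t0 <- t1; t1 <- t2 }
      dX <- dX + t1
    }
  }
  list(dtheta = dtheta, dbias = dbias, dX = dX)
}

# Batch normalization over the node axis of a single graph (channels are
# rows). Train mode uses batch statistics (biased variance) and updates
# running statistics; eval mode uses the running statistics. Single-node
# graphs fall back to the identity in train mode (no statistics to
# normalize by).
# mode "train": batch statistics + running-stat update; "batch": batch
# statistics without updating (inference on one graph); "running": the
# accumulated running statistics.
batchnorm_forward <- function(X, bn, mode, momentum = 0.1) {
  n <- ncol(X)
  if (mode %in% c("train", "batch")) {
    if (n < 2) {
      return(list(out = X, bn = bn, cache = list(identity = TRUE)))
    }
    mu <- rowMeans(X)
    xc <- X - mu
    v <- rowMeans(xc^2)
    istd <- 1 / sqrt(v + BN_EPS)
    xhat <- xc * istd
    out <- xhat * bn$gamma + bn$beta
    if (mode == "train") {
      bn$run_mean <- (1 - momentum) * bn$run_mean + momentum * mu
      bn$run_var <- (1 - momentum) * bn$run_var + momentum * v * n / max(n - 1, 1)
    }
    list(out = out, bn = bn,
         cache = list(identity = FALSE, xhat = xhat, istd = istd, n = n))
  } else {
    istd <- 1 / sqrt(bn$run_var + BN_EPS)
    xhat <- (X - bn$run_mean) * istd
    list(out = xhat * bn$gamma + bn$beta, bn = bn, cache = NULL)
  }
}

batchnorm_backward <- function(dOut, bn, cache) {
  if (isTRUE(cache$identity)) {
    return(list(dgamma = rep(0, length(bn$gamma)),
                dbeta = rep(0, length(bn$beta)), dX = dOut))
  }
  dgamma <- rowSums(dOut * cache$xhat)
  dbeta <- rowSums(dOut)
  dxhat <- dOut * bn$gamma
  # standard batchnorm gradient through mean and variance
  term <- dxhat - rowMeans(dxhat) - cache$xhat * rowMeans(dxhat * cache$xhat)
  list(dgamma = dgamma, dbeta = dbeta, dX = term * cache$istd)
}

leaky_relu <- function(X, slope) pmax(X, 0) + slope * pmin(X, 0)
leaky_relu_grad <- function(X, slope) (X >= 0) + slope * (X < 0)

# softmax down the rows of a 2 x N logit matrix
softmax_cols2 <- function(Z) {
  m <- pmax(Z[1, ], Z[2, ])
  e1 <- exp(Z[1, ] - m); e2 <- exp(Z[2, ] - m)
  s <- e1 + e2
  rbind(e1 / s, e2 / s)
}

# ---- full model forward (and cache for backward) ------------------------

# Xt is the channel-major (C x N) feature matrix of one graph; Lt its
# precomputed rescaled Laplacian.
model_forward_internal <- function(Lt, Xt, params, cfg, mode, collect_cache = FALSE,
                                   momentum = 0.1, bn_stats = "batch") {
  caches <- if (collect_cache) vector("list", cfg$n_blocks) else NULL
  bn_mode <- if (mode == "train") "train" else bn_stats
  H <- Xt
  for (b in seq_len(cfg$n_blocks)) {
    p <- params[[b]]
    conv <- chebconv_forward(Lt, H, p$theta, p$bias)
    bn1 <- batchnorm_forward(conv$out, p$bn1, bn_mode, momentum)
    params[[b]]$bn1 <- bn1$bn
    act <- leaky_relu(bn1$out, cfg$leaky_relu_slope)
    if (cfg$double_batchnorm) {
      bn2 <- batchnorm_forward(act, p$bn2, bn_mode, momentum)
      params[[b]]$bn2 <- bn2$bn
      H_out <- bn2$out
    } else {
      bn2 <- NULL
      H_out <- act
    }
    if (collect_cache)
      caches[[b]] <- list(conv = conv, bn1_cache = bn1$cache,
                          pre_act = bn1$out,
                          bn2_cache = if (is.null(bn2)) NULL else bn2$cache)
    H <- H_out
  }
  drop_mask <- NULL
  if (mode == "train" && cfg$dropout_rate > 0) {
    keep <- 1 - cfg$dropout_rate
    drop_mask <- matrix((runif(length(H)) < keep) / keep, nrow(H), ncol(H))
    H <- H * drop_mask
  }
  probs <- softmax_cols2(H)
  list(probs = probs, logits = H, params = params, caches = caches,
       drop_mask = drop_mask)
}

#' Forward pass of the Chebyshev GCN on one region graph
#'
#' Runs the five-block network on a graph and returns per-node class
#' probabilities (each row sums to 1). In `"eval"` mode batch
#' normalization uses running statistics and dropout is disabled, so the
#' pass is deterministic; `"train"` mode uses batch statistics and applies
#' dropout (RNG state dependent).
#'
#' @param graph a `region_graph` (or a list with fields `A` and `X`).
#' @param params parameter set (e.g. `coef()` of a fitted [cheb_gcn()]).
#' @param cfg the [model_config()] the parameters were built for.
#' @param mode `"eval"` or `"train"`.
#' @param normalization Laplacian variant, see [scaled_laplacian()].
#' @param bn_stats statistics used by batch normalization in `"eval"` mode:
#'   `"batch"` (default) standardizes each channel over the nodes of the
#'   graph being scored -- the same per-graph normalization used in
#'   training, insensitive to global intensity shifts of the slice --
#'   while `"running"` applies the running statistics accumulated during
#'   training. Both are deterministic.
#' @return `n x 2` matrix of class probabilities (column 2 = lesion).
#' @export
model_forward <- function(graph, params, cfg, mode = c("eval", "train"),
                          normalization = "sym",
                          bn_stats = c("batch", "running")) {
  mode <- match.arg(mode)
  bn_stats <- match.arg(bn_stats)
  if (ncol(graph$X) != cfg$dims[1])
    stop_input("graph features have ", ncol(graph$X), " columns; model expects ",
               cfg$dims[1])
  Lt <- scaled_laplacian(graph$A, normalization)$Lt
  t(model_forward_internal(Lt, t(graph$X), params, cfg, mode,
                           bn_stats = bn_stats)$probs)
}
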
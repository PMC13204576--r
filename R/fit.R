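#' Fit a Chebyshev graph convolutional network to labelled region graphs
#'
#' The central model fitter. Trains the five-block spectral GCN (Chebyshev
#' polynomial filters on the rescaled graph Laplacian, batch normalization,
#' Leaky ReLU, dropout, per-node softmax) to classify superpixel nodes as
#' lesion vs. non-lesion, minimizing mean per-node cross-entropy with
#' Adadelta. Graphs are visited one per optimization step, in an order
#' reshuffled every epoch; batch normalization operates over the node axis
#' of the current graph. The whole run is a deterministic function of
#' `train_cfg$seed`.
#'
#' @param graphs list of `region_graph` objects with non-`NULL` `labels`.
#' @param model_cfg a [model_config()].
#' @param train_cfg a [train_config()].
#' @param normalization Laplacian variant, see [scaled_laplacian()].
#' @param engine `"cpp"` (compiled training loop, the default) or `"r"`
#'   (pure-R reference implementation of the identical computation; slow,
#'   used for cross-checking).
#' @param verbose print the loss every 10 epochs.
#' @return an object of class `cheb_gcn` with components `params`,
#'   `model_cfg`, `train_cfg`, `normalization`, `loss_history` (mean
#'   per-node cross-entropy per epoch), `n_graphs`, `n_nodes` and `call`.
#' @seealso [predict.cheb_gcn()], [parameter_count()]
#' @examples
#' \donttest{
#' cohort <- generate_cohort(phantom_spec(seed = 3, n_patients = 2,
#'                                        image_size = c(64, 64),
#'                                        slices_per_patient = c(2, 3),
#'                                        lesion_radius = c(5, 9)))
#' graphs <- lapply(cohort, graphify_sample, graph_cfg = graph_config(n_zones = 30))
#' fit <- cheb_gcn(graphs, train_cfg = train_config(epochs = 20, seed = 1))
#' print(fit)
#' }
#' @export
cheb_gcn <- function(graphs, model_cfg = model_config(),
                     train_cfg = train_config(),
                     normalization = "sym",
                     engine = c("cpp", "r"), verbose = FALSE) {
  engine <- match.arg(engine)
  if (length(graphs) == 0) stop_input("empty training set")
  for (g in graphs) {
    if (is.null(g$labels)) stop_input("every training graph needs node labels")
    if (ncol(g$X) != model_cfg$dims[1])
      stop_input("graph features have ", ncol(g$X), " columns; model expects ",
                 model_cfg$dims[1])
  }
  all_y <- unlist(lapply(graphs, `[[`, "labels"))
  if (length(unique(all_y)) < 2)
    warning("training labels contain a single class; training proceeds", call. = FALSE)

  # class weights (inverse frequency), if requested
  cw <- c(1, 1)
  if (train_cfg$class_weights) {
    freq <- c(mean(all_y == 0), mean(all_y == 1))
    freq[freq == 0] <- 1
    cw <- (1 / freq) / sum(1 / freq) * 2
  }

  # precompute rescaled Laplacians once per graph
  prep <- lapply(graphs, function(g) {
    list(Lt = scaled_laplacian(g$A, normalization)$Lt,
         Xt = t(g$X), y = as.integer(g$labels))
  })

  fit <- with_local_seed(train_cfg$seed, {
    params <- init_params(model_cfg)
    ng <- length(prep)
    orders <- matrix(0L, train_cfg$epochs, ng)
    for (ep in seq_len(train_cfg$epochs))
      orders[ep, ] <- if (train_cfg$shuffle) sample.int(ng) else seq_len(ng)
    if (engine == "cpp") {
      res <- train_gcn_cpp(lapply(prep, `[[`, "Lt"),
                           lapply(prep, `[[`, "Xt"),
                           lapply(prep, `[[`, "y"),
                           params, orders,
                           model_cfg$leaky_relu_slope, model_cfg$dropout_rate,
                           train_cfg$learning_rate, train_cfg$rho, train_cfg$eps,
                           train_cfg$weight_decay, train_cfg$bn_momentum, cw)
      if (verbose) message(sprintf("final loss %.5f", tail(res$loss_history, 1)))
      list(params = res$params, loss_history = as.numeric(res$loss_history))
    } else {
      state <- adadelta_init(params)
      loss_hist <- numeric(train_cfg$epochs)
      for (ep in seq_len(train_cfg$epochs)) {
        ord <- orders[ep, ]
        ep_loss <- 0
        for (gi in ord) {
          d <- prep[[gi]]
          fw <- model_forward_internal(d$Lt, d$Xt, params, model_cfg, "train",
                                       collect_cache = TRUE,
                                       momentum = train_cfg$bn_momentum)
          params <- fw$params            # batchnorm running stats updated
          lw <- ce_loss_grad(fw$probs, d$y, cw)
          ep_loss <- ep_loss + lw$loss
          grads <- model_backward(d$Lt, fw, lw$dlogits, params, model_cfg)
          upd <- adadelta_step(params, grads, state, train_cfg)
          params <- upd$params
          state <- upd$state
        }
        loss_hist[ep] <- ep_loss / ng
        if (verbose && (ep %% 10 == 0 || ep == 1))
          message(sprintf("epoch %3d  loss %.5f", ep, loss_hist[ep]))
      }
      list(params = params, loss_history = loss_hist)
    }
  })

  structure(list(params = fit$params, model_cfg = model_cfg,
                 train_cfg = train_cfg, normalization = normalization,
                 loss_history = fit$loss_history,
                 n_graphs = length(graphs), n_nodes = length(all_y),
                 class_weights = cw, call = match.call()),
            class = "cheb_gcn")
}

# weighted cross-entropy loss and gradient w.r.t. logits.
# probs: 2 x n channel-major softmax output; y: 0/1 labels; cw: class weights.
ce_loss_grad <- function(probs, y, cw = c(1, 1)) {
  n <- length(y)
  w <- cw[y + 1L]
  sw <- sum(w)
  is1 <- y == 1L
  py <- probs[1, ]
  py[is1] <- probs[2, is1]
  loss <- -sum(w * log(pmax(py, 1e-12))) / sw
  onehot <- rbind(1 - y, y)
  dlogits <- (probs - onehot) * rep(w / sw, each = 2)
  list(loss = loss, dlogits = dlogits)
}

# backpropagate through dropout, the blocks (bn2 <- leaky <- bn1 <- conv)
model_backward <- function(Lt, fw, dlogits, params, cfg) {
  dH <- dlogits
  if (!is.null(fw$drop_mask)) dH <- dH * fw$drop_mask
  grads <- vector("list", cfg$n_blocks)
  for (b in rev(seq_len(cfg$n_blocks))) {
    p <- params[[b]]
    cache <- fw$caches[[b]]
    if (cfg$double_batchnorm) {
      bb2 <- batchnorm_backward(dH, p$bn2, cache$bn2_cache)
      dH <- bb2$dX
    } else {
      bb2 <- NULL
    }
    dH <- dH * leaky_relu_grad(cache$pre_act, cfg$leaky_relu_slope)
    bb1 <- batchnorm_backward(dH, p$bn1, cache$bn1_cache)
    cb <- chebconv_backward(Lt, cache$conv, p$theta, bb1$dX)
    grads[[b]] <- list(dtheta = cb$dtheta, dbias = cb$dbias,
                       dbn1 = list(dgamma = bb1$dgamma, dbeta = bb1$dbeta),
                       dbn2 = if (is.null(bb2)) NULL else
                         list(dgamma = bb2$dgamma, dbeta = bb2$dbeta))
    dH <- cb$dX
  }
  grads
}

# ---- Adadelta -----------------------------------------------------------

# Accumulator state mirroring the parameter structure.
adadelta_init <- function(params) {
  zero_like <- function(x) {
    z <- x; z[] <- 0; z
  }
  lapply(params, function(p) list(
    theta = lapply(p$theta, function(th) list(Eg2 = zero_like(th), Edx = zero_like(th))),
    bias = list(Eg2 = zero_like(p$bias), Edx = zero_like(p$bias)),
    bn1 = list(gamma = list(Eg2 = zero_like(p$bn1$gamma), Edx = zero_like(p$bn1$gamma)),
               beta = list(Eg2 = zero_like(p$bn1$beta), Edx = zero_like(p$bn1$beta))),
    bn2 = if (is.null(p$bn2)) NULL else
      list(gamma = list(Eg2 = zero_like(p$bn2$gamma), Edx = zero_like(p$bn2$gamma)),
           beta = list(Eg2 = zero_like(p$bn2$beta), Edx = zero_like(p$bn2$beta)))
  ))
}

# One Adadelta update:
#   Eg2  <- rho Eg2 + (1-rho) g^2
#   dx   <- sqrt(Edx + eps) / sqrt(Eg2 + eps) * g
#   Edx  <- rho Edx + (1-rho) dx^2
#   par  <- par - lr * dx
# The accumulated step dx is the *unscaled* Adadelta step; `lr` only
# multiplies the applied update, so lr = 1 is the method's original form.
adadelta_one <- function(par, g, st, tc) {
  st$Eg2 <- tc$rho * st$Eg2 + (1 - tc$rho) * g * g
  dx <- sqrt((st$Edx + tc$eps) / (st$Eg2 + tc$eps)) * g
  st$Edx <- tc$rho * st$Edx + (1 - tc$rho) * dx * dx
  list(par = par - tc$learning_rate * dx, st = st)
}

adadelta_step <- function(params, grads, state, tc) {
  for (b in seq_along(params)) {
    p <- params[[b]]; g <- grads[[b]]; s <- state[[b]]
    for (k in seq_along(p$theta)) {
      gk <- g$dtheta[[k]] + tc$weight_decay * p$theta[[k]]  # decay conv weights only
      u <- adadelta_one(p$theta[[k]], gk, s$theta[[k]], tc)
      p$theta[[k]] <- u$par; s$theta[[k]] <- u$st
    }
    u <- adadelta_one(p$bias, g$dbias, s$bias, tc)
    p$bias <- u$par; s$bias <- u$st
    u <- adadelta_one(p$bn1$gamma, g$dbn1$dgamma, s$bn1$gamma, tc)
    p$bn1$gamma <- u$par; s$bn1$gamma <- u$st
    u <- adadelta_one(p$bn1$beta, g$dbn1$dbeta, s$bn1$beta, tc)
    p$bn1$beta <- u$par; s$bn1$beta <- u$st
    if (!is.null(p$bn2)) {
      u <- adadelta_one(p$bn2$gamma, g$dbn2$dgamma, s$bn2$gamma, tc)
      p$bn2$gamma <- u$par; s$bn2$gamma <- u$st
      u <- adadelta_one(p$bn2$beta, g$dbn2$dbeta, s$bn2$beta, tc)
      p$bn2$beta <- u$par; s$bn2$beta <- u$st
    }
    params[[b]] <- p; state[[b]] <- s
  }
  list(params = params, state = state)
}

# ---- S3 methods ---------------------------------------------------------

#' @export
print.cheb_gcn <- function(x, ...) {
  cat("Chebyshev spectral GCN (", x$model_cfg$n_blocks, " blocks, dims ",
      paste(x$model_cfg$dims, collapse = "-"), ", orders ",
      paste(x$model_cfg$cheb_orders, collapse = ","), ")\n", sep = "")
  cat(sprintf("  %d parameters; trained on %d graphs / %d nodes; final loss %.5f\n",
              parameter_count(x$model_cfg), x$n_graphs, x$n_nodes,
              tail(x$loss_history, 1)))
  invisible(x)
}

#' @export
summary.cheb_gcn <- function(object, ...) {
  cfg <- object$model_cfg
  rows <- data.frame(
    block = seq_len(cfg$n_blocks),
    order = cfg$cheb_orders,
    in_dim = cfg$dims[-length(cfg$dims)],
    out_dim = cfg$dims[-1]
  )
  rows$conv_params <- rows$order * rows$in_dim * rows$out_dim + rows$out_dim
  rows$bn_params <- (if (cfg$double_batchnorm) 4L else 2L) * rows$out_dim
  structure(list(layers = rows, total = parameter_count(cfg),
                 loss_history = object$loss_history,
                 n_graphs = object$n_graphs),
            class = "summary.cheb_gcn")
}

#' @export
print.summary.cheb_gcn <- function(x, ...) {
  print(x$layers, row.names = FALSE)
  cat("total trainable parameters:", x$total, "\n")
  cat(sprintf("loss: first %.5f -> last %.5f over %d epochs\n",
              x$loss_history[1], tail(x$loss_history, 1), length(x$loss_history)))
  invisible(x)
}

#' @export
coef.cheb_gcn <- function(object, ...) object$params

#' Predict lesion probabilities, node classes or a pixel mask
#'
#' @param object a fitted [cheb_gcn()].
#' @param graph a `region_graph` (features must match the model input
#'   width).
#' @param type `"prob"` returns the `n x 2` class-probability matrix,
#'   `"class"` the 0/1 node vector (lesion iff `P(lesion) >= 0.5`),
#'   `"mask"` the pixel mask via [nodes_to_mask()] (requires the graph to
#'   carry its superpixel map).
#' @param bn_stats see [model_forward()].
#' @param ... unused.
#' @return see `type`.
#' @export
predict.cheb_gcn <- function(object, graph, type = c("prob", "class", "mask"),
                             bn_stats = c("batch", "running"), ...) {
  type <- match.arg(type)
  probs <- model_forward(graph, object$params, object$model_cfg, mode = "eval",
                         normalization = object$normalization,
                         bn_stats = match.arg(bn_stats))
  if (type == "prob") return(probs)
  cls <- as.integer(probs[, 2] >= 0.5)
  if (type == "class") return(cls)
  if (is.null(graph$spmap))
    stop_input("graph carries no superpixel map; cannot build a pixel mask")
  nodes_to_mask(graph$spmap, cls)
}

#' Plot the training loss history
#'
#' @param x a fitted [cheb_gcn()].
#' @param ... passed to [graphics::plot()].
#' @export
plot.cheb_gcn <- function(x, ...) {
  plot(seq_along(x$loss_history), x$loss_history, type = "l",
       xlab = "epoch", ylab = "mean per-node cross-entropy", ...)
  invisible(x)
}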
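# small labelled graphs for model tests
toy_graphs <- function(n_graphs = 2, seed = 21, n_zones = 40) {
  cohort <- generate_cohort(phantom_spec(seed = seed, n_patients = n_graphs,
                                         image_size = c(96L, 96L),
                                         slices_per_patient = c(2L, 2L),
                                         lesion_radius = c(6, 12)))
  graphs <- lapply(cohort, graphify_sample,
                   pre_cfg = preprocess_config(target_size = c(96L, 96L)),
                   graph_cfg = graph_config(n_zones = n_zones))
  graphs[vapply(graphs, function(g) sum(g$labels) > 0, logical(1))]
}

test_that("the Chebyshev convolution implements sum_k T_k(Lt) X theta_k + b", {
  set.seed(31)
  n <- 6
  A <- random_adjacency(n)
  Lt <- scaled_laplacian(A)$Lt
  Xt <- matrix(rnorm(3 * n), 3, n)                     # channel-major internals
  # zero coefficients: output is the broadcast bias
  th0 <- lapply(1:3, function(k) matrix(0, 3, 4))
  out0 <- strokegraph:::chebconv_forward(Lt, Xt, th0, c(1, 2, 3, 4))$out
  expect_equal(out0, matrix(rep(c(1, 2, 3, 4), n), 4, n))
  # order-1 identity filter passes features through
  thI <- list(diag(1, 3))
  expect_equal(strokegraph:::chebconv_forward(Lt, Xt, thI, rep(0, 3))$out, Xt)
  # dense spectral construction oracle
  th <- lapply(1:3, function(k) matrix(rnorm(12), 3, 4))
  out <- strokegraph:::chebconv_forward(Lt, Xt, th, rep(0, 4))$out
  oracle <- matrix(0, 4, n)
  for (k in 0:2) {
    Tk <- spectral_filter_oracle(Lt, diag(1, n), k)    # dense T_k(Lt)
    oracle <- oracle + t(th[[k + 1]]) %*% (Xt %*% t(Tk))
  }
  expect_equal(out, oracle, tolerance = 1e-10)
  # linearity in the input signal
  X2 <- matrix(rnorm(3 * n), 3, n)
  f <- function(X) strokegraph:::chebconv_forward(Lt, X, th, rep(0, 4))$out
  expect_equal(f(2 * Xt - 5 * X2), 2 * f(Xt) - 5 * f(X2), tolerance = 1e-10)
})

test_that("batch normalization standardizes channels in train mode", {
  set.seed(32)
  X <- matrix(rnorm(16 * 50, mean = 3, sd = 2), 16, 50)
  bn <- list(gamma = rep(1, 16), beta = rep(0, 16),
             run_mean = rep(0, 16), run_var = rep(1, 16))
  fw <- strokegraph:::batchnorm_forward(X, bn, "train")
  expect_equal(rowMeans(fw$out), rep(0, 16), tolerance = 1e-12)
  expect_equal(apply(fw$out, 1, var) * 49 / 50, rep(1, 16), tolerance = 1e-3)
  # leaky ReLU definition
  expect_equal(strokegraph:::leaky_relu(matrix(c(-1, 2), 1), 0.01),
               matrix(c(-0.01, 2), 1))
  # single-node fallback is the identity
  one <- matrix(rnorm(16), 16, 1)
  expect_equal(strokegraph:::batchnorm_forward(one, bn, "train")$out, one)
})

test_that("analytic gradients match finite differences", {
  set.seed(33)
  n <- 7
  A <- random_adjacency(n)
  g <- list(A = A, X = matrix(rnorm(n * 4), n, 4), labels = rbinom(n, 1, 0.5),
            n = n)
  mc <- model_config(n_blocks = 2, dims = c(4L, 3L, 2L), cheb_orders = 3L,
                     dropout_rate = 0)
  params <- strokegraph:::with_local_seed(1, strokegraph:::init_params(mc))
  Lt <- scaled_laplacian(A)$Lt
  Xt <- t(g$X)
  y <- g$labels
  loss_at <- function(p) {
    fw <- strokegraph:::model_forward_internal(Lt, Xt, p, mc, "train",
                                               collect_cache = TRUE)
    strokegraph:::ce_loss_grad(fw$probs, y)$loss
  }
  fw <- strokegraph:::model_forward_internal(Lt, Xt, params, mc, "train",
                                             collect_cache = TRUE)
  lw <- strokegraph:::ce_loss_grad(fw$probs, y)
  grads <- strokegraph:::model_backward(Lt, fw, lw$dlogits, fw$params, mc)
  eps <- 1e-6
  central_diff <- function(set_fn) {
    (loss_at(set_fn(params, eps)) - loss_at(set_fn(params, -eps))) / (2 * eps)
  }
  check <- function(analytic, numeric_g)
    expect_lt(abs(analytic - numeric_g) / max(abs(analytic), 1e-3), 1e-4)
  for (b in 1:2) {
    for (k in c(1L, 3L)) {
      for (trial in 1:3) {
        i <- sample(length(params[[b]]$theta[[k]]), 1)
        num <- central_diff(function(p, e) {
          p[[b]]$theta[[k]][i] <- p[[b]]$theta[[k]][i] + e; p
        })
        check(grads[[b]]$dtheta[[k]][i], num)
      }
    }
    i <- sample(length(params[[b]]$bias), 1)
    num <- central_diff(function(p, e) { p[[b]]$bias[i] <- p[[b]]$bias[i] + e; p })
    check(grads[[b]]$dbias[i], num)
    # batchnorm scale/shift
    i <- sample(length(params[[b]]$bn1$gamma), 1)
    num <- central_diff(function(p, e) {
      p[[b]]$bn1$gamma[i] <- p[[b]]$bn1$gamma[i] + e; p
    })
    check(grads[[b]]$dbn1$dgamma[i], num)
  }
})

test_that("model output is a per-node probability distribution and eval is deterministic", {
  gs <- toy_graphs()
  mc <- model_config()
  params <- strokegraph:::with_local_seed(2, strokegraph:::init_params(mc))
  p1 <- model_forward(gs[[1]], params, mc, mode = "eval")
  expect_identical(dim(p1), c(gs[[1]]$n, 2L))
  expect_equal(rowSums(p1), rep(1, gs[[1]]$n), tolerance = 1e-6)
  expect_identical(model_forward(gs[[1]], params, mc, mode = "eval"), p1)
  expect_error(model_forward(list(A = gs[[1]]$A, X = gs[[1]]$X[, 1:3]),
                             params, mc), "expects")
})

test_that("eval-mode predictions are equivariant under node permutations", {
  set.seed(34)
  n <- 7
  A <- random_adjacency(n)
  g <- list(A = A, X = matrix(rnorm(n * 16), n, 16), n = n)
  mc <- model_config()
  params <- strokegraph:::with_local_seed(3, strokegraph:::init_params(mc))
  p <- model_forward(g, params, mc)
  for (i in 1:5) {
    perm <- sample(n)
    gp <- list(A = A[perm, perm], X = g$X[perm, , drop = FALSE], n = n)
    pp <- model_forward(gp, params, mc)
    expect_lt(max(abs(p[perm, ] - pp)), 1e-6)
  }
})

test_that("parameter accounting matches the per-layer closed forms exactly", {
  # 16->16 layer at order 3 contributes 256*3+16 conv parameters,
  # the final 16->2 layer 32*3+2
  mc <- model_config()
  conv <- sum(3 * 16 * 16 + 16, 3 * 16 * 16 + 16, 3 * 16 * 16 + 16,
              3 * 16 * 16 + 16, 3 * 16 * 2 + 2)
  expect_equal(3 * 16 * 16 + 16, 784)
  expect_equal(3 * 16 * 2 + 2, 98)
  bn <- 2 * 2 * (16 * 4 + 2)
  expect_equal(parameter_count(mc), conv + bn)
  # introspection oracle over random configurations
  set.seed(35)
  for (i in 1:5) {
    nb <- sample(2:4, 1)
    dims <- c(sample(3:8, nb), 2L)
    cfg <- model_config(n_blocks = nb, dims = dims,
                        cheb_orders = sample(1:4, nb, replace = TRUE),
                        double_batchnorm = sample(c(TRUE, FALSE), 1))
    params <- strokegraph:::with_local_seed(i, strokegraph:::init_params(cfg))
    expect_identical(parameter_count(cfg),
                     as.integer(strokegraph:::count_instantiated_params(params)))
  }
})

test_that("training separates lesion from tissue nodes on a phantom toy problem", {
  gs <- toy_graphs(3, seed = 21)
  gs <- gs[seq_len(min(2, length(gs)))]
  fit <- cheb_gcn(gs, train_cfg = train_config(epochs = 150, seed = 7))
  acc <- vapply(gs, function(g) mean(predict(fit, g, type = "class") == g$labels),
                numeric(1))
  expect_true(all(acc > 0.95))
  # loss decreases in trailing moving average
  ma <- stats::filter(fit$loss_history, rep(1 / 10, 10), sides = 1)
  ma <- ma[!is.na(ma)]
  expect_lt(ma[length(ma)], ma[1])
})

test_that("training is reproducible and a zero step size freezes parameters", {
  gs <- toy_graphs(2, seed = 22)
  t5 <- train_config(epochs = 5, seed = 5)
  f1 <- cheb_gcn(gs, train_cfg = t5)
  f2 <- cheb_gcn(gs, train_cfg = t5)
  expect_identical(f1$loss_history, f2$loss_history)
  expect_identical(f1$params, f2$params)
  init <- strokegraph:::with_local_seed(5, strokegraph:::init_params(model_config()))
  f0 <- cheb_gcn(gs, train_cfg = train_config(epochs = 3, learning_rate = 0,
                                              seed = 5))
  expect_identical(f0$params[[1]]$theta, init[[1]]$theta)
  expect_error(cheb_gcn(list()), "empty")
  g1 <- gs[[1]]; g1$labels <- rep(0L, g1$n)
  expect_warning(cheb_gcn(list(g1), train_cfg = train_config(epochs = 1)),
                 "single class")
})

test_that("the compiled and reference training engines agree to machine precision", {
  gs <- toy_graphs(2, seed = 23)
  mc <- model_config(dropout_rate = 0)
  tc <- train_config(epochs = 3, shuffle = FALSE, seed = 9)
  fc <- cheb_gcn(gs, mc, tc, engine = "cpp")
  fr <- cheb_gcn(gs, mc, tc, engine = "r")
  flat <- function(f) unname(unlist(lapply(f$params, function(p)
    c(unlist(p$theta), p$bias, unlist(p$bn1), unlist(p$bn2)))))
  expect_equal(flat(fc), flat(fr), tolerance = 1e-12)
  expect_equal(fc$loss_history, fr$loss_history, tolerance = 1e-12)
})
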
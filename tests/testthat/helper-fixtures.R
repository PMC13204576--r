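# Shared fixtures and independent oracles for the test suite.

# small, fast phantom spec (64x64 slices, few patients)
small_spec <- function(seed = 1L, n_patients = 3L, ...) {
  phantom_spec(seed = seed, n_patients = n_patients,
               image_size = c(64L, 64L), slices_per_patient = c(2L, 4L),
               lesion_radius = c(4, 9), ...)
}

small_pre_cfg <- function() preprocess_config(target_size = c(64L, 64L))
small_graph_cfg <- function(n_zones = 30L) graph_config(n_zones = n_zones)

small_graphify <- function(sample, n_zones = 30L) {
  graphify_sample(sample, pre_cfg = small_pre_cfg(),
                  graph_cfg = small_graph_cfg(n_zones))
}

# random symmetric nonnegative adjacency with zero diagonal
random_adjacency <- function(n, density = 0.5) {
  A <- matrix(runif(n * n), n, n)
  A[A > density] <- 0
  A <- (A + t(A)) / 2
  diag(A) <- 0
  A
}

# dense spectral-domain Chebyshev filter: U T_k(Lambda) U' x, the
# eigendecomposition oracle against which the recurrence is checked
cheb_scalar <- function(lambda, k) {
  t0 <- rep(1, length(lambda))
  if (k == 0) return(t0)
  t1 <- lambda
  if (k == 1) return(t1)
  for (i in 2:k) { t2 <- 2 * lambda * t1 - t0; t0 <- t1; t1 <- t2 }
  t1
}

spectral_filter_oracle <- function(Lt, x, k) {
  e <- eigen(Lt, symmetric = TRUE)
  e$vectors %*% (cheb_scalar(e$values, k) * crossprod(e$vectors, x))
}

# brute-force per-pixel confusion counts
confusion_loop_oracle <- function(pred, truth) {
  tp <- fp <- fn <- tn <- 0L
  for (i in seq_along(pred)) {
    if (pred[i] == 1 && truth[i] == 1) tp <- tp + 1L
    else if (pred[i] == 1 && truth[i] == 0) fp <- fp + 1L
    else if (pred[i] == 0 && truth[i] == 1) fn <- fn + 1L
    else tn <- tn + 1L
  }
  c(TP = tp, FP = fp, FN = fn, TN = tn)
}

# flood-fill connectivity check: is every region of the label matrix a
# single 4-connected component?
regions_connected <- function(labels) {
  for (id in unique(as.vector(labels))) {
    px <- which(labels == id, arr.ind = TRUE)
    seen <- rep(FALSE, nrow(px))
    key <- paste(px[, 1], px[, 2])
    idx <- stats::setNames(seq_len(nrow(px)), key)
    queue <- 1L
    seen[1] <- TRUE
    while (length(queue)) {
      cur <- queue[1]; queue <- queue[-1]
      r <- px[cur, 1]; c <- px[cur, 2]
      for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
        k <- paste(r + d[1], c + d[2])
        j <- idx[k]
        if (!is.na(j) && !seen[j]) { seen[j] <- TRUE; queue <- c(queue, j) }
      }
    }
    if (!all(seen)) return(FALSE)
  }
  TRUE
}

# 2x2 checkerboard-quadrant superpixel map over an s x s image
quadrant_spmap <- function(s = 8L, image = matrix(0.5, s, s)) {
  h <- s / 2
  labels <- matrix(1L, s, s)
  labels[(h + 1):s, 1:h] <- 2L
  labels[1:h, (h + 1):s] <- 3L
  labels[(h + 1):s, (h + 1):s] <- 4L
  superpixel_map_from_labels(labels, image)
}
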
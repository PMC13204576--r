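rand_mask <- function(n = 16, p = 0.3) matrix(rbinom(n * n, 1, p), n, n)

test_that("confusion counts match a per-pixel loop on random mask pairs", {
  set.seed(41)
  for (i in 1:10) {
    a <- rand_mask(); b <- rand_mask()
    cc <- confusion_counts(a, b)
    expect_identical(cc, confusion_loop_oracle(a, b))
    expect_equal(sum(cc), length(a))
  }
  m <- rand_mask()
  expect_equal(unname(confusion_counts(m, m)[c("FP", "FN")]), c(0L, 0L))
  z <- matrix(0L, 4, 4)
  expect_equal(unname(confusion_counts(z, z)), c(0L, 0L, 0L, 16L))
  expect_error(confusion_counts(matrix(0, 2, 2), matrix(0, 3, 3)), "differ")
  expect_error(confusion_counts(matrix(2, 2, 2), matrix(0, 2, 2)), "binary")
})

test_that("overlap metrics match counting oracles and their closed forms", {
  n <- 8
  left <- matrix(0L, n, n); left[, 1:(n / 2)] <- 1L   # prediction: left half
  top <- matrix(0L, n, n); top[1:(n / 2), ] <- 1L     # truth: top half
  # TP = n^2/4, FP = FN = n^2/4
  expect_equal(dsc(left, top), 0.5)
  expect_equal(jaccard(left, top), 1 / 3)
  expect_equal(sensitivity(left, top), 0.5)
  expect_equal(precision(left, top), 0.5)
  expect_equal(pixel_accuracy(left, top), 0.5)
  m <- rand_mask()
  expect_equal(dsc(m, m), 1)
  expect_equal(jaccard(m, m), 1)
  disj <- matrix(0L, 16, 16); disj[1, 1] <- 1L
  disj2 <- matrix(0L, 16, 16); disj2[2, 2] <- 1L
  expect_equal(dsc(disj, disj2), 0)
  # empty-reference conventions
  z <- matrix(0L, 16, 16)
  expect_equal(dsc(z, z), 1)
  expect_equal(jaccard(z, z), 1)
  expect_equal(sensitivity(m, z), 1)   # empty truth
  expect_equal(precision(z, m), 1)     # empty prediction
  # bounds and the Dice--Jaccard identity on random pairs
  set.seed(42)
  for (i in 1:20) {
    a <- rand_mask(p = runif(1, 0.05, 0.6)); b <- rand_mask(p = runif(1, 0.05, 0.6))
    d <- dsc(a, b); j <- jaccard(a, b)
    for (v in c(d, j, sensitivity(a, b), precision(a, b), pixel_accuracy(a, b))) {
      expect_gte(v, 0); expect_lte(v, 1)
    }
    expect_equal(j, d / (2 - d))
  }
})

test_that("metric aggregation pools counts globally or averages per slice", {
  set.seed(43)
  preds <- lapply(1:4, function(i) rand_mask())
  truths <- lapply(1:4, function(i) rand_mask())
  gl <- metrics_report(preds, truths, "global-pooled")
  cc <- Reduce(`+`, Map(confusion_loop_oracle, preds, truths))
  expect_equal(gl$dsc, 2 * cc["TP"] / (2 * cc["TP"] + cc["FP"] + cc["FN"]),
               ignore_attr = TRUE)
  expect_equal(gl$jaccard, gl$dsc / (2 - gl$dsc))   # identity exact when pooled
  ps <- metrics_report(preds, truths, "per-slice-mean")
  expect_equal(ps$dsc, mean(mapply(dsc, preds, truths)))
  expect_equal(gl$n_slices, 4L)
})

test_that("the ROC sweep yields calibrated AUC values", {
  set.seed(44)
  labels <- rep(c(0L, 1L), each = 50)
  sep <- c(runif(50, 0, 0.4), runif(50, 0.6, 1))
  r <- roc_curve(sep, labels)
  expect_equal(r$auc, 1)
  expect_true(all(r$fpr >= 0 & r$fpr <= 1) && all(r$tpr >= 0 & r$tpr <= 1))
  # permuted labels: chance performance
  aucs <- replicate(20, roc_curve(sep, sample(labels))$auc)
  expect_lt(abs(mean(aucs) - 0.5), 0.1)
  # AUC equals the Mann-Whitney U statistic / (n1 n0)
  probs <- runif(100)
  r2 <- roc_curve(probs, labels)
  U <- unname(wilcox.test(probs[labels == 1], probs[labels == 0],
                          exact = FALSE)$statistic)
  expect_equal(r2$auc, U / (50 * 50))
  # AUC invariant under strictly monotone transforms
  expect_equal(roc_curve(plogis(5 * probs - 2), labels)$auc, r2$auc)
  expect_error(roc_curve(runif(5), rep(1L, 5)), "class 0")
  expect_error(roc_curve(runif(5), rep(0L, 5)), "class 1")
})

test_that("paired fold tests flag degenerate inputs and match stats oracles", {
  a <- c(0.71, 0.74, 0.69, 0.80, 0.77, 0.72, 0.75, 0.78, 0.70, 0.73)
  b <- a - c(0.02, 0.01, 0.03, 0.015, 0.02, 0.01, 0.025, 0.02, 0.01, 0.03)
  fs <- fold_significance(a, b)
  expect_equal(fs$degenerate, "none")
  expect_equal(fs$t_p, t.test(a, b, paired = TRUE)$p.value)
  expect_equal(fs$wilcoxon_p,
               suppressWarnings(wilcox.test(a, b, paired = TRUE,
                                            exact = FALSE)$p.value))
  expect_lt(fs$t_p, 0.05)
  ident <- fold_significance(a, a)
  expect_equal(ident$t_p, 1)
  expect_equal(ident$wilcoxon_p, 1)
  expect_equal(ident$degenerate, "identical")
  shift <- fold_significance(a, a - 0.05)
  expect_true(is.na(shift$t_p))
  expect_equal(shift$degenerate, "zero-variance")
  expect_error(fold_significance(a[1:3], b[1:3]), "at least 5")
})
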
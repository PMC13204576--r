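test_that("patient-level folds partition patients with near-equal sizes", {
  ids10 <- sprintf("P%02d", 1:10)
  f <- patient_kfold(ids10, k = 10, seed = 1)
  expect_equal(sort(unname(f)), 1:10)                 # one patient per fold
  expect_identical(patient_kfold(ids10, 10, seed = 1), f)
  expect_false(identical(unname(patient_kfold(ids10, 10, seed = 2)), unname(f)))
  # 23 patients over 10 folds: sizes are three 3s and seven 2s
  f23 <- patient_kfold(sprintf("P%02d", 1:23), k = 10, seed = 3)
  expect_equal(sort(tabulate(f23, 10)), c(rep(2, 7), rep(3, 3)))
  # no patient in two folds, ever
  expect_equal(anyDuplicated(names(f23)), 0)
  expect_error(patient_kfold(ids10, k = 11), "exceeds")
})

test_that("fold assignment never leaks a patient across train/test", {
  set.seed(51)
  for (i in 1:50) {
    n_pat <- sample(10:40, 1)
    ids <- sprintf("P%03d", seq_len(n_pat))
    slices <- sample(ids, n_pat * 4, replace = TRUE)
    k <- sample(c(2, 5, 10), 1)
    f <- patient_kfold(slices, k = k, seed = i)
    for (fold in seq_len(k)) {
      test_pat <- names(f)[f == fold]
      train_pat <- names(f)[f != fold]
      expect_length(intersect(test_pat, train_pat), 0)
    }
    expect_setequal(names(f), unique(slices))
  }
})

test_that("additive noise realizes the requested SNR", {
  s <- generate_cohort(phantom_spec(seed = 52, n_patients = 1,
                                    slices_per_patient = c(2L, 2L)))[[1]]
  for (snr in c(-4, 0, 5)) {
    noisy <- add_awgn(s$image, snr, seed = 7)
    p_sig <- mean(s$image^2)
    p_noise <- mean((noisy - s$image)^2)
    realized <- 10 * log10(p_sig / p_noise)
    expect_lt(abs(realized - snr), 0.2)
  }
  # SNR 0: noise power equals signal power within sampling tolerance
  n0 <- add_awgn(s$image, 0, seed = 8) - s$image
  expect_lt(abs(mean(n0^2) / mean(s$image^2) - 1), 0.05)
  # determinism under seed; fresh draws otherwise
  expect_identical(add_awgn(s$image, 3, seed = 9), add_awgn(s$image, 3, seed = 9))
  expect_error(add_awgn(matrix(0, 8, 8), 0), "all-zero")
  # very high SNR approaches the clean image
  expect_lt(max(abs(add_awgn(s$image, 100, seed = 1) - s$image)), 1)
})

test_that("noise power can be referenced to a brain mask", {
  s <- generate_cohort(phantom_spec(seed = 53, n_patients = 1,
                                    slices_per_patient = c(2L, 2L)))[[1]]
  masked <- add_awgn(s$image, 0, seed = 1, signal_mask = s$brain)
  whole <- add_awgn(s$image, 0, seed = 1)
  # brain-only signal power is larger, so masked noise is stronger
  expect_gt(mean((masked - s$image)^2), mean((whole - s$image)^2))
})
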
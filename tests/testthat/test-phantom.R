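test_that("cohort generation is a pure, deterministic function of seed and spec", {
  spec <- small_spec(seed = 9)
  a <- generate_cohort(spec)
  b <- generate_cohort(spec)
  expect_identical(a, b)
  c <- generate_cohort(small_spec(seed = 10))
  expect_false(identical(a[[1]]$image, c[[1]]$image))
})

test_that("generated masks respect the brain ellipse and lesion-count settings", {
  cohort <- generate_cohort(small_spec(seed = 4, n_patients = 4))
  for (s in cohort) {
    expect_identical(dim(s$image), dim(s$mask))
    expect_true(all(s$mask %in% c(0L, 1L)))
    expect_true(all(s$brain[s$mask == 1L]))          # lesions inside the brain
    lf_brain <- sum(s$mask) / sum(s$brain)
    expect_lte(lf_brain, 0.25)                       # imbalance cap
  }
  # at least one lesion-free slice per cohort
  expect_true(any(vapply(cohort, function(s) sum(s$mask) == 0, logical(1))))
  # lesion_count (0,0) forces all-empty masks
  empty <- generate_cohort(small_spec(seed = 4, lesion_count = c(0L, 0L)))
  expect_true(all(vapply(empty, function(s) sum(s$mask) == 0, logical(1))))
})

test_that("slice counts stay within the configured per-patient range", {
  cohort <- generate_cohort(phantom_spec(seed = 1, n_patients = 5,
                                         image_size = c(32L, 32L)))
  pids <- vapply(cohort, function(s) s$patient_id, character(1))
  expect_length(unique(pids), 5)
  counts <- table(pids)
  expect_true(all(counts >= 2 & counts <= 22))
  # 5 patients x (2..22) slices: total in [10, 110]
  expect_gte(length(cohort), 10)
  expect_lte(length(cohort), 110)
})

test_that("lesion_fraction counts mask pixels exactly", {
  s <- generate_cohort(small_spec(seed = 2, n_patients = 1))[[2]]
  expect_equal(lesion_fraction(s), sum(s$mask == 1) / prod(dim(s$mask)))
  z <- s; z$mask[] <- 0L
  expect_equal(lesion_fraction(z), 0)
  o <- s; o$mask[] <- 1L
  expect_equal(lesion_fraction(o), 1)
  # a 256x256 mask carrying 655 lesion pixels
  m <- s
  m$mask <- matrix(0L, 256, 256)
  m$mask[seq_len(655)] <- 1L
  expect_equal(lesion_fraction(m), 655 / 65536)
})

test_that("a default-sized cohort covers the empty-to-5%% lesion-fraction range", {
  cohort <- generate_cohort(phantom_spec(seed = 11, n_patients = 20))
  lf <- vapply(cohort, lesion_fraction, numeric(1))
  expect_equal(min(lf), 0)
  expect_gte(max(lf), 0.05)
})

test_that("invalid specs are rejected", {
  expect_error(phantom_spec(slices_per_patient = c(5L, 2L)), "ordered")
  expect_error(phantom_spec(brain_intensity = c(-10, 90)), "within")
  expect_error(phantom_spec(out_of_range_fraction = 2), "0, 1")
  expect_error(generate_cohort(list()), "phantom_spec")
})
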
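test_that("Hounsfield clipping replaces out-of-window pixels with zero", {
  cfg <- preprocess_config()
  m <- matrix(c(200, -5, 75, 150, 0, 149.5), 2, 3)
  out <- clip_hounsfield(m, cfg)
  expect_equal(out, matrix(c(0, 0, 75, 150, 0, 149.5), 2, 3))
  # identity on in-window input, idempotent in general
  inw <- matrix(runif(64, 0, 150), 8, 8)
  expect_equal(clip_hounsfield(inw, cfg), inw)
  set.seed(1)
  r <- matrix(runif(400, -100, 300), 20, 20)
  cl <- clip_hounsfield(r, cfg)
  expect_true(max(cl) <= 150 && min(cl) >= 0)
  expect_equal(clip_hounsfield(cl, cfg), cl)
  # brute-force per-pixel oracle
  expect_equal(as.vector(cl),
               vapply(as.vector(r), function(p) if (p > 150 || p < 0) 0 else p,
                      numeric(1)))
  expect_error(clip_hounsfield(matrix(c(1, NA), 1, 2), cfg), "non-finite")
})

test_that("normalization maps the window into [0,1] and preserves order", {
  cfg <- preprocess_config()
  expect_equal(normalize_intensity(matrix(0, 2, 2), cfg), matrix(0, 2, 2))
  expect_equal(normalize_intensity(matrix(150, 1, 1), cfg), matrix(1, 1, 1))
  set.seed(2)
  img <- clip_hounsfield(matrix(runif(256, -50, 200), 16, 16), cfg)
  z <- normalize_intensity(img, cfg)
  expect_true(min(z) >= 0 && max(z) <= 1)
  # pairwise order preservation
  i <- sample(256, 50); j <- sample(256, 50)
  expect_equal(sign(z[i] - z[j]), sign(img[i] - img[j]))
  expect_error(normalize_intensity(img, preprocess_config(bit_depth = 0)),
               "positive")
})

test_that("size standardization center-crops and zero-pads with bottom/right bias", {
  big <- matrix(seq_len(300 * 300), 300, 300)
  out <- standardize_size(big, target_size = c(256L, 256L))$image
  expect_identical(dim(out), c(256L, 256L))
  expect_equal(out, big[23:278, 23:278])   # floor((300-256)/2) = 22 offset
  sm <- matrix(1, 200, 256)
  pad <- standardize_size(sm, target_size = c(256L, 256L))$image
  expect_equal(which(rowSums(pad) > 0), 29:228)  # 28 top, 28 bottom
  odd <- matrix(1, 201, 256)
  pado <- standardize_size(odd, target_size = c(256L, 256L))$image
  expect_equal(which(rowSums(pado) > 0), 28:228) # 27 top, 28 bottom (extra at bottom)
  # identity at target size; masks stay binary
  img <- matrix(runif(64^2), 64, 64)
  msk <- matrix(rbinom(64^2, 1, 0.2), 64, 64)
  std <- standardize_size(img, msk, c(64L, 64L))
  expect_identical(std$image, img)
  expect_true(all(std$mask %in% c(0L, 1L)))
  expect_error(standardize_size(matrix(1, 2, 2), matrix(1, 3, 3)), "differ")
})

test_that("augmentation applies one transform to image and mask jointly", {
  cohort <- generate_cohort(small_spec(seed = 6))
  s <- cohort[[which(vapply(cohort, function(x) sum(x$mask) > 40, logical(1)))[1]]]
  cfg <- small_pre_cfg()
  a <- augment_sample(s, cfg, seed = 3)
  expect_identical(a$patient_id, s$patient_id)
  expect_identical(a$slice_index, s$slice_index)
  expect_true(all(a$mask %in% c(0L, 1L)))
  expect_identical(augment_sample(s, cfg, seed = 3), a)  # seeded determinism
  # zero rotation range and no flip: identity
  id_cfg <- preprocess_config(target_size = c(64L, 64L),
                              rotation_range = c(0, 0), hflip = FALSE)
  expect_equal(augment_sample(s, id_cfg, seed = 1)$image, s$image)
  # horizontal flip is an involution
  flipped <- s
  flipped$image <- s$image[, ncol(s$image):1]
  expect_equal(flipped$image[, ncol(s$image):1], s$image)
  # area of a centered disc is approximately rotation invariant
  disc <- s
  rr <- row(disc$mask) - 32.5; cc <- col(disc$mask) - 32.5
  disc$mask <- matrix(as.integer(rr^2 + cc^2 <= 15^2), 64, 64)
  rot <- rotate_matrix(disc$mask, 17, "nearest")
  expect_lt(abs(sum(rot >= 0.5) - sum(disc$mask)) / sum(disc$mask), 0.05)
  # augmentation is train-only
  s$role <- "test"
  expect_error(augment_sample(s, cfg), "training")
})

test_that("rotation by zero is exact identity and interpolation stays in range", {
  m <- matrix(runif(400), 20, 20)
  expect_identical(rotate_matrix(m, 0), m)
  r <- rotate_matrix(m, 33, "bilinear")
  expect_true(min(r) >= 0 && max(r) <= max(m) + 1e-12)
})
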
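test_that("SLIC partitions the image into connected regions near the target count", {
  img <- matrix(0.5, 64, 64)
  sp4 <- slic_superpixels(img, n_zones = 4)
  expect_equal(sp4$n_regions, 4)
  expect_true(max(sp4$region_size) / min(sp4$region_size) < 1.3)
  expect_equal(sp4$region_mean_intensity, rep(0.5, 4))
  # every pixel belongs to exactly one region; ids contiguous
  expect_setequal(unique(as.vector(sp4$labels)), seq_len(sp4$n_regions))
  expect_equal(sum(sp4$region_size), length(img))
  # phantom slice at the default zone count
  s <- generate_cohort(phantom_spec(seed = 8, n_patients = 1,
                                    slices_per_patient = c(2L, 2L)))[[1]]
  img <- normalize_intensity(clip_hounsfield(s$image))
  sp <- slic_superpixels(img, n_zones = 100)
  expect_gte(sp$n_regions, 50)
  expect_lte(sp$n_regions, 150)
  expect_true(regions_connected(sp$labels))
  expect_error(slic_superpixels(img, n_zones = 1), "n_zones")
  expect_error(slic_superpixels(img, n_zones = length(img) + 1), "n_zones")
})

test_that("region features reproduce per-region statistics", {
  set.seed(3)
  img <- matrix(runif(32 * 32), 32, 32)
  sp <- slic_superpixels(img, n_zones = 12)
  H <- region_features(sp, img, mode = "hist16")
  expect_identical(dim(H), c(sp$n_regions, 16L))
  expect_equal(rowSums(H), rep(1, sp$n_regions))       # normalized histograms
  M <- region_features(sp, img, mode = "mean")
  # brute-force pixel-loop oracle for the mean
  for (r in seq_len(sp$n_regions)) {
    px <- img[sp$labels == r]
    expect_equal(M[r, 1], mean(px))
  }
  # constant region: all histogram mass in the bin containing the value
  cimg <- matrix(0.5, 16, 16)
  csp <- quadrant_spmap(16, cimg)
  ch <- region_features(csp, cimg, mode = "hist16")
  expect_equal(ch[, 9], rep(1, 4))                      # 0.5 falls in bin 9
  expect_equal(region_features(csp, cimg, "mean")[, 1], rep(0.5, 4))
  expect_identical(dim(region_features(csp, cimg, "mean16")), c(4L, 16L))
})

test_that("Gaussian edge weights follow exp(-d^2/(2 sigma^2))", {
  expect_equal(gaussian_edge_weight(0, 2), 1)
  expect_equal(gaussian_edge_weight(3, 3), exp(-0.5))
  d <- sort(runif(20, 0, 10))
  w <- gaussian_edge_weight(d, 2.5)
  expect_true(all(diff(w) < 0))                         # strictly decreasing
  expect_true(all(w > 0 & w <= 1))
  expect_error(gaussian_edge_weight(1, 0), "sigma")
  expect_error(gaussian_edge_weight(-1, 1), "nonnegative")
})

test_that("region graphs connect exactly the spatially adjacent regions", {
  sp <- quadrant_spmap(8)
  g <- build_region_graph(sp, matrix(0.5, 8, 8), sigma = 4)
  # each quadrant touches exactly 2 others (no diagonal adjacency)
  expect_equal(sum(g$A > 0), 8)
  expect_equal(colSums(g$A > 0), c(2, 2, 2, 2))
  expect_equal(g$A, t(g$A))
  expect_equal(diag(g$A), rep(0, 4))
  # weights obey the Gaussian law on centroid distances
  d12 <- sqrt(sum((sp$centroids[1, ] - sp$centroids[2, ])^2))
  expect_equal(g$A[1, 2], gaussian_edge_weight(d12, 4))
})

test_that("node labels follow the lesion-fraction threshold monotonically", {
  sp <- quadrant_spmap(8)
  mask <- matrix(0L, 8, 8)
  mask[1:4, 1:4] <- 1L                                  # region 1 fully lesion
  mask[5:8, 1:2] <- 1L                                  # region 2 half lesion
  expect_equal(node_labels_from_mask(sp, mask, 0.5), c(1L, 1L, 0L, 0L))
  expect_equal(node_labels_from_mask(sp, mask, 0.75), c(1L, 0L, 0L, 0L))
  expect_equal(node_labels_from_mask(sp, mask * 0L, 0.5), rep(0L, 4))
  # monotone: raising the threshold never adds lesion nodes
  ths <- seq(0.05, 1, by = 0.05)
  n_lesion <- vapply(ths, function(t) sum(node_labels_from_mask(sp, mask, t)),
                     integer(1))
  expect_true(all(diff(n_lesion) <= 0))
})

test_that("graph invariants hold on random phantom slices", {
  cohort <- generate_cohort(small_spec(seed = 12, n_patients = 2))
  for (s in cohort[1:4]) {
    g <- small_graphify(s)
    expect_equal(g$A, t(g$A))
    expect_equal(diag(g$A), rep(0, g$n))
    expect_true(all(g$A >= 0 & g$A <= 1))
    # region-adjacency graph of an image partition is connected:
    # reachability via repeated neighbor expansion
    reach <- c(1L)
    repeat {
      nxt <- unique(c(reach, which(colSums(g$A[reach, , drop = FALSE] > 0) > 0)))
      if (length(nxt) == length(reach)) break
      reach <- nxt
    }
    expect_length(reach, g$n)
  }
})

test_that("mask projection inverts region labelling on region-aligned masks", {
  sp <- quadrant_spmap(8)
  expect_equal(nodes_to_mask(sp, c(0, 0, 0, 0)), matrix(0L, 8, 8))
  m1 <- nodes_to_mask(sp, c(0, 1, 0, 0))
  expect_equal(which(m1 == 1L), which(sp$labels == 2L))
  # round trip on a mask that is a union of whole regions
  aligned <- nodes_to_mask(sp, c(1, 0, 1, 0))
  expect_identical(nodes_to_mask(sp, node_labels_from_mask(sp, aligned)), aligned)
  # and on a SLIC map of a real slice
  s <- generate_cohort(small_spec(seed = 13))[[1]]
  g <- small_graphify(s)
  aligned2 <- nodes_to_mask(g$spmap, as.integer(seq_len(g$n) %% 3 == 0))
  expect_identical(nodes_to_mask(g$spmap, node_labels_from_mask(g$spmap, aligned2)),
                   aligned2)
  expect_error(nodes_to_mask(sp, c(1, 0)), "length")
  expect_error(nodes_to_mask(sp, c(1, 0, 2, 0)), "binary")
})

test_that("region graphs serialize to text and round-trip bit-exactly", {
  s <- generate_cohort(small_spec(seed = 14))[[2]]
  g <- small_graphify(s)
  prefix <- file.path(tempdir(), "g1")
  write_region_graph(g, prefix)
  g2 <- read_region_graph(prefix)
  expect_identical(g2$A, g$A)
  expect_identical(g2$X, g$X)
  expect_identical(g2$labels, g$labels)
  expect_identical(g2$sigma, g$sigma)
  expect_identical(g2$patient_id, g$patient_id)
  expect_identical(g2$slice_index, g$slice_index)
})
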
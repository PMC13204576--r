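#' Specification for a synthetic CT-perfusion phantom cohort
#'
#' Describes a cohort of synthetic axial "brain" slices used to exercise the
#' whole segmentation pipeline without access to clinical data. Each slice is
#' an elliptical brain region of textured intensity on a Hounsfield-like
#' scale, carrying 0-3 irregular lesion blobs whose intensity is offset from
#' the surrounding tissue. Slices are grouped into patients so that
#' patient-level cross-validation is meaningful.
#'
#' @param seed integer seed; the cohort is a pure function of `(seed, spec)`.
#' @param n_patients number of patients in the cohort.
#' @param slices_per_patient integer `(min, max)`; each patient draws a slice
#'   count uniformly from this range. The default `(2, 22)` mirrors the
#'   slice-count variability of clinical CTP stacks.
#' @param image_size `(rows, cols)` of every slice.
#' @param lesion_count integer `(min, max)` lesions per slice.
#' @param lesion_radius `(min, max)` mean lesion radius in pixels.
#' @param brain_intensity `(low, high)` HU-like range from which each
#'   patient's baseline tissue intensity is drawn; must lie within
#'   `[0, 150]` so lesion tissue survives the Hounsfield window.
#' @param lesion_contrast signed HU offset added inside lesions. The default
#'   is negative: ischemic tissue is hypoattenuating on CT.
#' @param background_noise_sd per-pixel Gaussian noise, HU units.
#' @param out_of_range_fraction fraction of pixels forced outside `[0, 150]`
#'   so that the Hounsfield clipping stage is observable on phantom data.
#' @return an object of class `phantom_spec`.
#' @seealso [generate_cohort()]
#' @export
phantom_spec <- function(seed = 1L,
                         n_patients = 10L,
                         slices_per_patient = c(2L, 22L),
                         image_size = c(256L, 256L),
                         lesion_count = c(0L, 3L),
                         lesion_radius = c(10, 28),
                         brain_intensity = c(60, 90),
                         lesion_contrast = -35,
                         background_noise_sd = 6,
                         out_of_range_fraction = 0.002) {
  chk_range <- function(x, nm, int = FALSE) {
    if (length(x) != 2 || any(!is.finite(x)) || x[1] > x[2])
      stop_input("invalid ", nm, ": must be an ordered (min, max) pair")
    if (int && any(x != round(x))) stop_input(nm, " must be integer-valued")
  }
  chk_range(slices_per_patient, "slices_per_patient", int = TRUE)
  chk_range(image_size, "image_size", int = TRUE)
  chk_range(lesion_count, "lesion_count", int = TRUE)
  chk_range(lesion_radius, "lesion_radius")
  chk_range(brain_intensity, "brain_intensity")
  if (slices_per_patient[1] < 1) stop_input("slices_per_patient must be >= 1")
  if (n_patients < 1) stop_input("n_patients must be >= 1")
  if (brain_intensity[1] < 0 || brain_intensity[2] > 150)
    stop_input("brain_intensity must lie within [0, 150]")
  if (out_of_range_fraction < 0 || out_of_range_fraction > 1)
    stop_input("out_of_range_fraction must be in [0, 1]")
  structure(list(
    seed = as.integer(seed), n_patients = as.integer(n_patients),
    slices_per_patient = as.integer(slices_per_patient),
    image_size = as.integer(image_size),
    lesion_count = as.integer(lesion_count),
    lesion_radius = as.numeric(lesion_radius),
    brain_intensity = as.numeric(brain_intensity),
    lesion_contrast = as.numeric(lesion_contrast),
    background_noise_sd = as.numeric(background_noise_sd),
    out_of_range_fraction = as.numeric(out_of_range_fraction)
  ), class = "phantom_spec")
}

# Smooth pseudo-texture: a sum of random low-frequency cosine waves,
# rescaled to the requested standard deviation.
smooth_field <- function(nr, nc, sd_target, n_waves = 6L) {
  rr <- matrix(seq_len(nr), nr, nc)
  cc <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  f <- matrix(0, nr, nc)
  for (w in seq_len(n_waves)) {
    period <- runif(1, 40, 120)
    theta <- runif(1, 0, 2 * pi)
    phase <- runif(1, 0, 2 * pi)
    amp <- runif(1, 0.5, 1)
    f <- f + amp * cos(2 * pi * (rr * cos(theta) + cc * sin(theta)) / period + phase)
  }
  s <- stats::sd(as.vector(f))
  if (s > 0) f <- f * (sd_target / s)
  f
}

# Fill an irregular (Fourier-perturbed ellipse) blob centred at (r0, c0)
# with mean radius rad; returns a logical matrix.
lesion_blob <- function(nr, nc, r0, c0, rad) {
  harm <- 2:5
  amps <- rnorm(length(harm), 0, 0.08)
  phs <- runif(length(harm), 0, 2 * pi)
  stretch <- runif(1, 0.7, 1.3)  # anisotropy
  half <- ceiling(rad * 1.6)
  rows <- max(1, floor(r0 - half)):min(nr, ceiling(r0 + half))
  cols <- max(1, floor(c0 - half)):min(nc, ceiling(c0 + half))
  dr <- matrix(rows - r0, length(rows), length(cols))
  dc <- matrix((cols - c0) * stretch, length(rows), length(cols), byrow = TRUE)
  dist <- sqrt(dr^2 + dc^2)
  phi <- atan2(dc, dr)
  rphi <- rad * (1 + Reduce(`+`, Map(function(h, a, p) a * cos(h * phi + p),
                                     harm, amps, phs)))
  blob <- matrix(FALSE, nr, nc)
  blob[rows, cols] <- dist <= pmax(rphi, 1)
  blob
}

#' Generate a synthetic phantom cohort
#'
#' Deterministically generates `spec$n_patients` stacks of slices with paired
#' binary lesion masks. Each patient has a fixed brain ellipse and baseline
#' intensity; each slice adds smooth texture, per-pixel noise, 0-3 irregular
#' lesion blobs (intensity offset by `spec$lesion_contrast`), and a small
#' fraction of out-of-range pixels. The first slice of the first patient
#' always carries zero lesions so that empty-mask edge cases are represented
#' in every cohort; total lesion area per slice is capped at 25% of the brain
#' area, reflecting the strong class imbalance of lesion segmentation.
#'
#' @param spec a [phantom_spec()].
#' @return an object of class `slice_cohort`: a list of `slice_sample`
#'   objects, each with fields `image` (HU-like matrix), `mask` (0/1 integer
#'   matrix), `brain` (logical brain-ellipse matrix), `patient_id`,
#'   `slice_index` and `role` (initially `"train"`).
#' @examples
#' cohort <- generate_cohort(phantom_spec(seed = 7, n_patients = 2,
#'                                        image_size = c(64, 64),
#'                                        slices_per_patient = c(2, 4),
#'                                        lesion_radius = c(4, 8)))
#' sapply(cohort, lesion_fraction)
#' @export
generate_cohort <- function(spec) {
  if (!inherits(spec, "phantom_spec")) stop_input("spec must be a phantom_spec")
  nr <- spec$image_size[1]; nc <- spec$image_size[2]
  with_local_seed(spec$seed, {
    cohort <- list()
    for (p in seq_len(spec$n_patients)) {
      pid <- sprintf("P%03d", p)
      n_slices <- sample(spec$slices_per_patient[1]:spec$slices_per_patient[2], 1)
      base <- runif(1, spec$brain_intensity[1], spec$brain_intensity[2])
      ctr <- c(nr / 2 + runif(1, -8, 8), nc / 2 + runif(1, -8, 8))
      ax <- c(0.42 * nr * runif(1, 0.95, 1.05), 0.36 * nc * runif(1, 0.95, 1.05))
      rr <- matrix(seq_len(nr), nr, nc)
      cc <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
      brain <- ((rr - ctr[1]) / ax[1])^2 + ((cc - ctr[2]) / ax[2])^2 <= 1
      brain_area <- sum(brain)
      for (s in seq_len(n_slices)) {
        img <- matrix(0, nr, nc)
        tex <- smooth_field(nr, nc, sd_target = 8)
        img[brain] <- base + tex[brain]
        n_lesions <- sample(spec$lesion_count[1]:spec$lesion_count[2], 1)
        if (p == 1L && s == 1L) n_lesions <- 0L  # guaranteed lesion-free slice
        mask <- matrix(FALSE, nr, nc)
        if (n_lesions > 0) {
          for (l in seq_len(n_lesions)) {
            ang <- runif(1, 0, 2 * pi); rad_f <- sqrt(runif(1))
            l_r <- ctr[1] + 0.7 * ax[1] * rad_f * cos(ang)
            l_c <- ctr[2] + 0.7 * ax[2] * rad_f * sin(ang)
            rad <- runif(1, spec$lesion_radius[1], spec$lesion_radius[2])
            cand <- mask | (lesion_blob(nr, nc, l_r, l_c, rad) & brain)
            if (sum(cand) <= 0.25 * brain_area) mask <- cand
          }
        }
        img[mask] <- img[mask] + spec$lesion_contrast
        img[brain] <- img[brain] + rnorm(brain_area, 0, spec$background_noise_sd)
        n_oor <- round(spec$out_of_range_fraction * nr * nc)
        if (n_oor > 0) {
          idx <- sample.int(nr * nc, n_oor)
          hi <- idx[seq_len(ceiling(n_oor / 2))]
          lo <- setdiff(idx, hi)
          img[hi] <- runif(length(hi), 160, 250)
          if (length(lo)) img[lo] <- runif(length(lo), -50, -5)
        }
        cohort[[length(cohort) + 1L]] <- structure(list(
          image = img,
          mask = matrix(as.integer(mask), nr, nc),
          brain = brain,
          patient_id = pid,
          slice_index = s,
          role = "train"
        ), class = "slice_sample")
      }
    }
    structure(cohort, class = "slice_cohort", spec = spec)
  })
}

#' Fraction of lesion pixels in a slice
#'
#' @param sample a `slice_sample`.
#' @return `sum(mask == 1) / (rows * cols)`, in `[0, 1]`.
#' @export
lesion_fraction <- function(sample) {
  if (!inherits(sample, "slice_sample")) stop_input("sample must be a slice_sample")
  mean(sample$mask == 1L)
}

#' @export
print.slice_cohort <- function(x, ...) {
  pids <- vapply(x, function(s) s$patient_id, character(1))
  cat("slice_cohort:", length(x), "slices,", length(unique(pids)), "patients\n")
  cat("  image size:", paste(dim(x[[1]]$image), collapse = " x "),
      " lesion fraction range:",
      paste(signif(range(vapply(x, lesion_fraction, numeric(1))), 3), collapse = " - "),
      "\n")
  invisible(x)
}

#' @export
print.slice_sample <- function(x, ...) {
  cat("slice_sample", x$patient_id, "slice", x$slice_index,
      sprintf("(%d x %d, lesion fraction %.4f, role %s)\n",
              nrow(x$image), ncol(x$image), lesion_fraction(x), x$role))
  invisible(x)
}
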
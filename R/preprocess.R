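#' Preprocessing configuration
#'
#' Settings for the Hounsfield-window clipping, intensity normalization,
#' size standardization and training-set augmentation stages.
#'
#' @param hu_low,hu_high Hounsfield window; pixels outside `(hu_low, hu_high)`
#'   are *replaced by zero* (not saturated) by [clip_hounsfield()].
#' @param target_size `(rows, cols)` that [standardize_size()] crops/pads to.
#' @param bit_depth bits per channel `B` used by [normalize_intensity()]:
#'   the window is affinely mapped onto `[0, 2^B - 1]` and divided by
#'   `2^B - 1`, landing in `[0, 1]`.
#' @param rotation_range `(min, max)` augmentation rotation in degrees.
#' @param hflip allow horizontal flipping during augmentation.
#' @return an object of class `preprocess_config`.
#' @export
preprocess_config <- function(hu_low = 0, hu_high = 150,
                              target_size = c(256L, 256L),
                              bit_depth = 8L,
                              rotation_range = c(-20, 20),
                              hflip = TRUE) {
  if (hu_low >= hu_high) stop_input("hu_low must be < hu_high")
  if (length(rotation_range) != 2 || rotation_range[1] > rotation_range[2])
    stop_input("rotation_range must be an ordered (min, max) pair")
  structure(list(hu_low = hu_low, hu_high = hu_high,
                 target_size = as.integer(target_size),
                 bit_depth = as.integer(bit_depth),
                 rotation_range = as.numeric(rotation_range),
                 hflip = isTRUE(hflip)),
            class = "preprocess_config")
}

#' Hounsfield-window clipping
#'
#' Replaces every pixel whose intensity lies above `hu_high` or below
#' `hu_low` with zero, leaving in-window pixels untouched. Replacement (not
#' saturation) matches how out-of-window CT intensities are eliminated in
#' this pipeline; the operation is idempotent.
#'
#' @param image numeric matrix of HU-like intensities.
#' @param cfg a [preprocess_config()].
#' @return matrix of the same shape.
#' @export
clip_hounsfield <- function(image, cfg = preprocess_config()) {
  if (!is.matrix(image) || !is.numeric(image)) stop_input("image must be a numeric matrix")
  if (any(!is.finite(image))) stop_input("image contains non-finite pixels")
  image[image > cfg$hu_high | image < cfg$hu_low] <- 0
  image
}

#' Intensity normalization to \[0, 1\]
#'
#' Affinely maps the Hounsfield window onto `[0, 2^B - 1]` and divides by
#' the bit-depth scale `2^B - 1`, so a pixel at `hu_high` maps to 1. The
#' map is monotone and order-preserving.
#'
#' @inheritParams clip_hounsfield
#' @return matrix with values in `[0, 1]` for clipped input.
#' @export
normalize_intensity <- function(image, cfg = preprocess_config()) {
  if (cfg$bit_depth <= 0) stop_input("bit_depth must be positive")
  scale <- 2^cfg$bit_depth - 1
  scaled <- (image - cfg$hu_low) / (cfg$hu_high - cfg$hu_low) * scale
  scaled / scale
}

#' Standardize a slice (and its mask) to a target size
#'
#' Center-crops dimensions that are too large and zero-pads dimensions that
#' are too small. On an odd crop/pad remainder the extra row/column goes to
#' the bottom/right. The mask receives the identical treatment and stays
#' binary (padding value 0 = background).
#'
#' @param image numeric matrix.
#' @param mask optional binary matrix of the same shape.
#' @param target_size `(rows, cols)`.
#' @return `list(image, mask)` at `target_size` (mask `NULL` if not given).
#' @export
standardize_size <- function(image, mask = NULL, target_size = c(256L, 256L)) {
  if (!is.matrix(image) || length(image) == 0) stop_input("image must be a non-empty matrix")
  if (!is.null(mask) && !all(dim(mask) == dim(image)))
    stop_input("image and mask shapes differ")
  fit1 <- function(m, tgt, d) {
    n <- dim(m)[d]
    if (n > tgt) {                       # center crop, floor offset at top/left
      off <- (n - tgt) %/% 2
      idx <- (off + 1):(off + tgt)
      if (d == 1) m[idx, , drop = FALSE] else m[, idx, drop = FALSE]
    } else if (n < tgt) {                # zero pad, extra at bottom/right
      pad1 <- (tgt - n) %/% 2
      pad2 <- tgt - n - pad1
      if (d == 1) {
        rbind(matrix(0, pad1, ncol(m)), m, matrix(0, pad2, ncol(m)))
      } else {
        cbind(matrix(0, nrow(m), pad1), m, matrix(0, nrow(m), pad2))
      }
    } else m
  }
  std <- function(m) fit1(fit1(m, target_size[1], 1), target_size[2], 2)
  out_mask <- if (is.null(mask)) NULL else {
    mm <- std(mask)
    matrix(as.integer(mm != 0), nrow(mm), ncol(mm))
  }
  list(image = std(image), mask = out_mask)
}

#' Rotate a matrix about its center
#'
#' Inverse-mapping rotation with bilinear (images) or nearest-neighbour
#' (masks) interpolation; pixels sampled outside the source are 0.
#'
#' @param m numeric matrix.
#' @param angle rotation angle in degrees (counter-clockwise in row/col space).
#' @param interp `"bilinear"` or `"nearest"`.
#' @return rotated matrix, same shape.
#' @export
rotate_matrix <- function(m, angle, interp = c("bilinear", "nearest")) {
  interp <- match.arg(interp)
  if (angle == 0) return(m)
  nr <- nrow(m); nc <- ncol(m)
  cr <- (nr + 1) / 2; cc <- (nc + 1) / 2
  th <- angle * pi / 180
  r <- matrix(seq_len(nr), nr, nc) - cr
  c <- matrix(seq_len(nc), nr, nc, byrow = TRUE) - cc
  # inverse rotation: source coordinates
  sr <- cos(th) * r + sin(th) * c + cr
  sc <- -sin(th) * r + cos(th) * c + cc
  gather <- function(ri, ci) {
    ok <- ri >= 1 & ri <= nr & ci >= 1 & ci <= nc
    v <- numeric(length(ri))
    v[ok] <- m[cbind(ri[ok], ci[ok])]
    v
  }
  if (interp == "nearest") {
    out <- gather(round(sr), round(sc))
  } else {
    r0 <- floor(sr); c0 <- floor(sc)
    fr <- sr - r0; fc <- sc - c0
    out <- (1 - fr) * (1 - fc) * gather(r0, c0) +
      (1 - fr) * fc * gather(r0, c0 + 1) +
      fr * (1 - fc) * gather(r0 + 1, c0) +
      fr * fc * gather(r0 + 1, c0 + 1)
  }
  matrix(out, nr, nc)
}

#' Augment a training slice
#'
#' Applies one random spatial transform -- a rotation drawn uniformly from
#' `cfg$rotation_range` and (optionally) a horizontal flip -- identically to
#' the image and its mask. The image is interpolated bilinearly; the mask is
#' transformed with nearest-neighbour interpolation and re-binarized at 0.5,
#' so it stays strictly 0/1. Augmentation is a training-set-only operation:
#' calling it on a sample whose `role` is `"test"` or `"validation"` is a
#' contract error.
#'
#' @param sample a `slice_sample`.
#' @param cfg a [preprocess_config()].
#' @param seed integer seed for the transform draw.
#' @return the augmented `slice_sample` (attribute `augmented = TRUE`).
#' @export
augment_sample <- function(sample, cfg = preprocess_config(), seed = 1L) {
  if (!inherits(sample, "slice_sample")) stop_input("sample must be a slice_sample")
  if (sample$role %in% c("test", "validation"))
    stop_input("augmentation is restricted to training samples; got role '",
               sample$role, "'")
  with_local_seed(seed, {
    angle <- runif(1, cfg$rotation_range[1], cfg$rotation_range[2])
    flip <- cfg$hflip && runif(1) < 0.5
    img <- sample$image; msk <- sample$mask
    if (flip) { img <- img[, ncol(img):1]; msk <- msk[, ncol(msk):1] }
    img <- rotate_matrix(img, angle, "bilinear")
    msk <- rotate_matrix(msk, angle, "nearest")
    msk <- matrix(as.integer(msk >= 0.5), nrow(msk), ncol(msk))
    out <- sample
    out$image <- img
    out$mask <- msk
    attr(out, "augmented") <- TRUE
    out
  })
}
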
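#' Add white Gaussian noise at a target SNR
#'
#' Adds zero-mean Gaussian noise whose variance is set from the slice's
#' signal power: `sigma_n^2 = P_signal / 10^(snr_db / 10)` with
#' `P_signal = mean(image^2)` over the whole slice (or over a supplied
#' mask). Noise is injected on the raw HU-scale image, before clipping and
#' normalization, mirroring acquisition/motion degradation.
#'
#' @param image finite numeric matrix; must not be identically zero
#'   (signal power would be undefined).
#' @param snr_db target signal-to-noise ratio in decibels.
#' @param seed optional integer seed (local RNG stream).
#' @param signal_mask optional logical matrix restricting the signal-power
#'   estimate (e.g. brain-only power); noise is still added everywhere.
#' @return the noisy image.
#' @export
add_awgn <- function(image, snr_db, seed = NULL, signal_mask = NULL) {
  if (!is.matrix(image) || any(!is.finite(image))) stop_input("image must be a finite matrix")
  v <- if (is.null(signal_mask)) as.vector(image) else image[signal_mask]
  p_sig <- mean(v^2)
  if (p_sig == 0) stop_input("signal power is zero; SNR undefined for an all-zero image")
  sd_n <- sqrt(p_sig / 10^(snr_db / 10))
  draw <- function() image + matrix(rnorm(length(image), 0, sd_n),
                                    nrow(image), ncol(image))
  if (is.null(seed)) draw() else with_local_seed(seed, draw())
}
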
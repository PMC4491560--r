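#' Two-dimensional Fourier spectrum of a grayscale image
#'
#' Computes the unnormalized forward 2-D DFT and returns its magnitude
#' sqrt(Re^2 + Im^2) and phase, the four-quadrant arctangent of
#' (Im, Re) with range (-pi, pi]. The phase is defined as 0 wherever the
#' magnitude vanishes; in floating point this is applied where the
#' magnitude falls below 1e-12 times its maximum, which zeroes the
#' round-off residue the DFT leaves in analytically-zero bins.
#'
#' @param image Numeric matrix (grayscale pixels).
#' Real and imaginary parts below 1e-12 times the peak magnitude are
#' treated as exact zeros before the arctangent, so bins whose transform
#' is analytically real land on phase 0 or +pi (not -pi) regardless of
#' the sign of their floating-point residue, keeping the phase inside
#' (-pi, pi].
#'
#' @return An object of class `spectrum_field`: a list with `magnitude`
#'   and `phase` matrices of the same shape as `image`.
#' @export
compute_spectrum <- function(image) {
  stopifnot(is.matrix(image), length(image) > 0)
  F <- stats::fft(image)
  magnitude <- Mod(F)
  mmax <- max(magnitude)
  re <- Re(F); im <- Im(F)
  thr <- 1e-12 * mmax
  re[abs(re) <= thr] <- 0
  im[abs(im) <= thr] <- 0
  phase <- atan2(im, re)
  phase[magnitude <= thr] <- 0
  structure(list(magnitude = magnitude, phase = phase),
            class = "spectrum_field")
}

#' Global frequency features of a grayscale image
#'
#' Three scalar summaries of the full 2-D spectrum, used to place objects
#' on the artificial-to-natural axis:
#' \describe{
#'   \item{f1}{sum of spectral magnitudes over all frequency bins}
#'   \item{f2}{sum of log(1 + magnitude) (natural logarithm)}
#'   \item{f3}{sum of spectral phases}
#' }
#'
#' @param image Numeric matrix (grayscale pixels).
#' @return A named numeric vector `c(f1, f2, f3)`.
#' @export
frequency_features <- function(image) {
  sp <- compute_spectrum(image)
  c(f1 = sum(sp$magnitude),
    f2 = sum(log1p(sp$magnitude)),
    f3 = sum(sp$phase))
}

#' Frequency-feature table for a set of labeled images
#'
#' @param images A list of `labeled_image` objects (grayscale pixels).
#' @return A data.frame with columns `id`, `f1`, `f2`, `f3`,
#'   `superordinate`.
#' @export
frequency_feature_table <- function(images) {
  stopifnot(length(images) > 0)
  feats <- t(vapply(images, function(im) frequency_features(im$pixels),
                    numeric(3)))
  data.frame(id = vapply(images, function(im) im$id, character(1)),
             f1 = feats[, 1], f2 = feats[, 2], f3 = feats[, 3],
             superordinate = vapply(images, function(im)
               unname(im$label[1]), character(1)),
             stringsAsFactors = FALSE)
}
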
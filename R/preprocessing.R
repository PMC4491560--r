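#' Convert a raster image to grayscale luminance in [0, 1]
#'
#' Multi-channel (RGB or RGBA) input is reduced with ITU-R BT.601 luma
#' weights (0.299, 0.587, 0.114); an alpha channel, if present, is ignored.
#' Single-channel input is passed through. Inputs on an 8-bit scale
#' (any value > 1) are rescaled by 1/255 first.
#'
#' @param image A numeric matrix (single channel) or a height x width x
#'   channels array.
#' @return A numeric matrix with values in \[0, 1\].
#' @export
to_grayscale <- function(image) {
  if (is.null(image) || length(image) == 0) {
    stop("empty image", call. = FALSE)
  }
  if (!is.numeric(image)) stop("image must be numeric", call. = FALSE)
  if (max(image) > 1) image <- image / 255
  image <- pmin(pmax(image, 0), 1)
  if (is.matrix(image)) return(image)
  if (length(dim(image)) == 3L) {
    nc <- dim(image)[3L]
    if (nc == 1L) return(image[, , 1L])
    # BT.601 luma; alpha (4th channel) dropped
    w <- c(0.299, 0.587, 0.114)
    g <- w[1] * image[, , 1L] + w[2] * image[, , 2L] + w[3] * image[, , 3L]
    return(pmin(pmax(g, 0), 1))
  }
  stop("image must be a matrix or a 3-d array", call. = FALSE)
}

#' Crop an image and its mask to the mask's foreground bounding box
#'
#' The tight bounding box of the foreground (mask == 1) is expanded by
#' `margin` pixels on every side, clipped to the image bounds, and applied
#' to both the image and the mask.
#'
#' @param image Numeric matrix, same shape as `mask`.
#' @param mask Binary matrix in \{0, 1\} with nonempty foreground.
#' @param margin Nonnegative integer margin in pixels.
#' @return A list with elements `image` and `mask`, both cropped.
#' @export
crop_to_foreground <- function(image, mask, margin = 0L) {
  stopifnot(is.matrix(image), is.matrix(mask),
            all(dim(image) == dim(mask)), margin >= 0)
  idx <- which(mask == 1, arr.ind = TRUE)
  if (nrow(idx) == 0L) stop("mask has empty foreground", call. = FALSE)
  r0 <- max(1L, min(idx[, 1L]) - margin)
  r1 <- min(nrow(mask), max(idx[, 1L]) + margin)
  c0 <- max(1L, min(idx[, 2L]) - margin)
  c1 <- min(ncol(mask), max(idx[, 2L]) + margin)
  list(image = image[r0:r1, c0:c1, drop = FALSE],
       mask  = mask[r0:r1, c0:c1, drop = FALSE])
}

#' Binarize a grayscale image into an object mask
#'
#' Global Otsu thresholding followed by a polarity decision: the 1-pixel
#' border ring is taken as a background sample, and the foreground is the
#' side of the threshold whose mean intensity differs more from the border
#' mean. This makes both bright-on-dark and dark-on-bright objects come
#' out as foreground. The returned foreground is guaranteed nonempty.
#'
#' @param image Numeric matrix in \[0, 1\] with at least two distinct
#'   gray levels.
#' @return A binary matrix (0 = background, 1 = foreground).
#' @export
binarize <- function(image) {
  stopifnot(is.matrix(image))
  if (length(unique(as.vector(image))) < 2L) {
    stop("constant image cannot be binarized", call. = FALSE)
  }
  th <- EBImage::otsu(image, range = c(0, 1), levels = 256)
  hi <- image > th
  if (all(hi) || !any(hi)) hi <- image > mean(range(image))
  border <- c(image[1, ], image[nrow(image), ],
              image[, 1], image[, ncol(image)])
  bmean <- mean(border)
  d_hi <- abs(mean(image[hi]) - bmean)
  d_lo <- abs(mean(image[!hi]) - bmean)
  fg <- if (d_hi >= d_lo) hi else !hi
  if (!any(fg)) fg <- hi
  mask <- matrix(0, nrow(image), ncol(image))
  mask[fg] <- 1
  mask
}

#' Resize a grayscale image by bilinear interpolation
#'
#' Corner-aligned bilinear resampling to a square `side` x `side` output:
#' output pixel i (0-based) samples the input at i * (n - 1) / (side - 1).
#' Output values are clipped to \[0, 1\].
#'
#' @param image Numeric matrix in \[0, 1\].
#' @param side Output side length in pixels (>= 1).
#' @return A `side` x `side` numeric matrix.
#' @export
resize_image <- function(image, side) {
  stopifnot(is.matrix(image), side >= 1)
  side <- as.integer(side)
  out <- .bilinear_weights(nrow(image), side) %*% image %*%
    t(.bilinear_weights(ncol(image), side))
  pmin(pmax(out, 0), 1)
}

# side x n row-interpolation weight matrix for corner-aligned bilinear
# resampling (each row has at most two nonzero entries summing to 1)
.bilinear_weights <- function(n, side) {
  W <- matrix(0, side, n)
  pos <- if (side == 1L) rep((n - 1) / 2, 1L) else (0:(side - 1)) * (n - 1) / (side - 1)
  lo <- pmin(floor(pos), n - 1)
  frac <- pos - lo
  for (i in seq_len(side)) {
    j <- lo[i] + 1
    if (frac[i] < .Machine$double.eps || j >= n) {
      W[i, min(j, n)] <- 1
    } else {
      W[i, j] <- 1 - frac[i]
      W[i, j + 1] <- frac[i]
    }
  }
  W
}
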
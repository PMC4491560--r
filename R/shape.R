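#' Standardized moments of a binary silhouette
#'
#' The foreground pixels are treated as a uniform distribution over their
#' (x, y) coordinates, each axis normalized to \[0, 1\] by (width - 1)
#' and (height - 1). Per axis, order 1 is the raw mean (center of mass),
#' order 2 the variance, and orders 3-8 are standardized central moments
#' (central moment over sd^k); odd orders (3, 5, 7) are returned in
#' absolute value so left- and right-skewed silhouettes are treated
#' alike. The x (column) and y (row) values are interleaved per order.
#'
#' @param mask Binary matrix with nonempty foreground; orders >= 2
#'   require at least two distinct foreground coordinates on each axis.
#' @return A named numeric vector of length 16
#'   (`mu_1x`, `mu_1y`, ..., `mu_8x`, `mu_8y`).
#' @export
standardized_moments <- function(mask) {
  idx <- .foreground_coords(mask)
  x <- if (ncol(mask) > 1) (idx[, 2L] - 1) / (ncol(mask) - 1) else rep(0, nrow(idx))
  y <- if (nrow(mask) > 1) (idx[, 1L] - 1) / (nrow(mask) - 1) else rep(0, nrow(idx))
  out <- numeric(16)
  names(out) <- paste0("mu_", rep(1:8, each = 2), rep(c("x", "y"), 8))
  for (axis in 1:2) {
    v <- if (axis == 1) x else y
    m1 <- mean(v)
    s2 <- mean((v - m1)^2)
    if (s2 == 0) {
      stop("degenerate foreground: no spread along ",
           c("x", "y")[axis], " axis", call. = FALSE)
    }
    s <- sqrt(s2)
    vals <- c(m1, s2, vapply(3:8, function(k) {
      mk <- mean((v - m1)^k) / s^k
      if (k %% 2 == 1) abs(mk) else mk
    }, numeric(1)))
    out[seq(axis, 16, by = 2)] <- vals
  }
  out
}

#' Zernike moment magnitudes of a binary silhouette
#'
#' The foreground is mapped onto the unit disk centered at its centroid,
#' with radius equal to the largest centroid-to-foreground-pixel
#' distance. The moment of order n with repetition m is
#' A_nm = (n + 1) / N * sum over foreground pixels of
#' R_nm(rho) exp(-i m theta), where N is the foreground pixel count
#' (the per-pixel area element pi / N absorbs the conventional 1/pi).
#' Magnitudes |A_nm| are rotation-invariant. All (n, m) with
#' 0 <= n <= `max_order`, 0 <= m <= n and n - m even are returned in
#' ascending (n, m) order: 16 values at the default order 6.
#'
#' Radial polynomials are evaluated with the Kintner three-term
#' recurrence in n, which is numerically stable at these orders.
#'
#' @param mask Binary matrix with at least two foreground pixels.
#' @param max_order Maximum polynomial order n (default 6).
#' @return A named numeric vector of magnitudes (`z_00`, `z_11`, ...).
#' @export
zernike_magnitudes <- function(mask, max_order = 6L) {
  idx <- .foreground_coords(mask)
  x <- idx[, 2L]; y <- idx[, 1L]
  cx <- mean(x); cy <- mean(y)
  d <- sqrt((x - cx)^2 + (y - cy)^2)
  R <- max(d)
  if (R == 0) stop("single-pixel foreground: zero disk radius", call. = FALSE)
  rho <- d / R
  theta <- atan2(y - cy, x - cx)
  nm <- zernike_index_table(max_order)
  nf <- length(x)
  out <- numeric(nrow(nm))
  names(out) <- paste0("z_", nm[, 1L], nm[, 2L])
  for (i in seq_len(nrow(nm))) {
    n <- nm[i, 1L]; m <- nm[i, 2L]
    A <- (n + 1) / nf * sum(zernike_radial(n, m, rho) * exp(-1i * m * theta))
    out[i] <- Mod(A)
  }
  out
}

#' Index table of Zernike (order, repetition) pairs
#'
#' @param max_order Maximum order n.
#' @return A two-column integer matrix of all (n, m) with n <= max_order,
#'   0 <= m <= n, n - m even, sorted by (n, m).
#' @export
zernike_index_table <- function(max_order = 6L) {
  nm <- do.call(rbind, lapply(0:max_order, function(n)
    cbind(n, seq(n %% 2, n, by = 2))))
  colnames(nm) <- c("n", "m")
  nm
}

#' Zernike radial polynomial R_nm
#'
#' Evaluated via the Kintner recurrence: R_mm = rho^m,
#' R_(m+2)m = ((m + 2) rho^2 - (m + 1)) rho^m, and for n >= m + 4 a
#' three-term recurrence in n at fixed m.
#'
#' @param n Order (nonnegative integer).
#' @param m Repetition (0 <= m <= n, n - m even).
#' @param rho Numeric vector of radii in \[0, 1\].
#' @return Numeric vector R_nm(rho).
#' @export
zernike_radial <- function(n, m, rho) {
  stopifnot(n >= 0, m >= 0, m <= n, (n - m) %% 2 == 0)
  if (n == m) return(rho^n)
  if (n == m + 2) return(((m + 2) * rho^2 - (m + 1)) * rho^m)
  k1 <- (n + m) * (n - m) * (n - 2) / 2
  k2 <- 2 * n * (n - 1) * (n - 2)
  k3 <- -m^2 * (n - 1) - n * (n - 1) * (n - 2)
  k4 <- -n * (n + m - 2) * (n - m - 2) / 2
  ((k2 * rho^2 + k3) * zernike_radial(n - 2, m, rho) +
      k4 * zernike_radial(n - 4, m, rho)) / k1
}

#' Combined 32-dimensional shape descriptor
#'
#' Concatenation of the 16 standardized-moment values and the 16 Zernike
#' magnitudes of a binary silhouette.
#'
#' @param mask Binary matrix with nonempty, non-degenerate foreground.
#' @return A named numeric vector of length 32.
#' @export
shape_descriptor <- function(mask) {
  c(standardized_moments(mask), zernike_magnitudes(mask))
}

#' Shape-descriptor table for a set of labeled silhouettes
#'
#' @param images A list of `labeled_image` objects whose pixels are
#'   binary masks (grayscale images are binarized first).
#' @return A data.frame with columns `id`, the 32 descriptor entries and
#'   `basic`.
#' @export
shape_descriptor_table <- function(images) {
  stopifnot(length(images) > 0)
  feats <- t(vapply(images, function(im) {
    px <- im$pixels
    if (!all(px %in% c(0, 1))) px <- binarize(px)
    shape_descriptor(px)
  }, numeric(32)))
  out <- data.frame(id = vapply(images, function(im) im$id, character(1)),
                    feats,
                    basic = vapply(images, function(im)
                      unname(im$label[2]), character(1)),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Histogram-of-oriented-gradients baseline descriptor
#'
#' Basic HOG over a 4 x 4 grid of nonoverlapping blocks with 8
#' orientation bins per block. Gradients are central differences
#' (one-sided at the borders); orientation is unsigned, in \[0, 180)
#' degrees, quantized into 8 equal bins with votes weighted by gradient
#' magnitude. Each block histogram is L2-normalized independently and
#' the 16 histograms are concatenated (blocks in row-major order),
#' giving 128 values.
#'
#' @param image Numeric matrix with height and width >= 4.
#' @return A numeric vector of length 128, all entries >= 0.
#' @export
hog_baseline <- function(image) {
  stopifnot(is.matrix(image))
  h <- nrow(image); w <- ncol(image)
  if (h < 4 || w < 4) stop("image must be at least 4 x 4", call. = FALSE)
  gx <- matrix(0, h, w); gy <- matrix(0, h, w)
  gx[, 2:(w - 1)] <- (image[, 3:w] - image[, 1:(w - 2)]) / 2
  gx[, 1] <- image[, 2] - image[, 1]
  gx[, w] <- image[, w] - image[, w - 1]
  gy[2:(h - 1), ] <- (image[3:h, ] - image[1:(h - 2), ]) / 2
  gy[1, ] <- image[2, ] - image[1, ]
  gy[h, ] <- image[h, ] - image[h - 1, ]
  mag <- sqrt(gx^2 + gy^2)
  ang <- atan2(gy, gx) %% pi                     # unsigned, [0, pi)
  bin <- pmin(floor(ang / (pi / 8)) + 1, 8)
  rsplit <- .block_index(h, 4L)
  csplit <- .block_index(w, 4L)
  out <- numeric(0)
  for (br in 1:4) {
    for (bc in 1:4) {
      sel_m <- mag[rsplit == br, csplit == bc]
      sel_b <- bin[rsplit == br, csplit == bc]
      hist8 <- vapply(1:8, function(b) sum(sel_m[sel_b == b]), numeric(1))
      nrm <- sqrt(sum(hist8^2))
      if (nrm > 0) hist8 <- hist8 / nrm
      out <- c(out, hist8)
    }
  }
  out
}

# assign 1..nblocks to positions 1..n in contiguous near-equal chunks
.block_index <- function(n, nblocks) {
  as.integer(cut(seq_len(n), breaks = nblocks, labels = FALSE))
}

.foreground_coords <- function(mask) {
  stopifnot(is.matrix(mask))
  if (!all(mask %in% c(0, 1))) stop("mask must be binary", call. = FALSE)
  idx <- which(mask == 1, arr.ind = TRUE)
  if (nrow(idx) == 0L) stop("mask has empty foreground", call. = FALSE)
  idx
}
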
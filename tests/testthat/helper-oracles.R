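# Independent reference implementations used as test oracles. These
# deliberately take the slow, literal route (double sums, factorials,
# dense eigendecompositions) so they share no code with the package.

# O(N^4) double-sum 2-D DFT
naive_dft <- function(img) {
  M <- nrow(img); N <- ncol(img)
  out <- matrix(0i, M, N)
  for (u in 0:(M - 1)) {
    for (v in 0:(N - 1)) {
      acc <- 0i
      for (x in 0:(M - 1)) {
        for (y in 0:(N - 1)) {
          acc <- acc + img[x + 1, y + 1] *
            exp(-2i * pi * (u * x / M + v * y / N))
        }
      }
      out[u + 1, v + 1] <- acc
    }
  }
  out
}

# Zernike radial polynomial from the explicit factorial sum
radial_factorial <- function(n, m, rho) {
  out <- numeric(length(rho))
  for (s in 0:((n - m) / 2)) {
    out <- out + (-1)^s * factorial(n - s) /
      (factorial(s) * factorial((n + m) / 2 - s) *
         factorial((n - m) / 2 - s)) * rho^(n - 2 * s)
  }
  out
}

# Zernike magnitudes recomputed with the factorial-sum polynomials,
# per-pixel, same disk mapping convention as the package
zernike_oracle <- function(mask, max_order = 6L) {
  idx <- which(mask == 1, arr.ind = TRUE)
  x <- idx[, 2]; y <- idx[, 1]
  cx <- mean(x); cy <- mean(y)
  d <- sqrt((x - cx)^2 + (y - cy)^2)
  rho <- d / max(d)
  theta <- atan2(y - cy, x - cx)
  out <- numeric(0)
  for (n in 0:max_order) {
    for (m in seq(n %% 2, n, by = 2)) {
      A <- 0i
      for (p in seq_along(rho)) {
        A <- A + radial_factorial(n, m, rho[p]) * exp(-1i * m * theta[p])
      }
      out <- c(out, Mod((n + 1) / length(rho) * A))
    }
  }
  out
}

# phase of a DFT field under the package's zero-residue convention:
# |Re| or |Im| below 1e-12 of the peak magnitude count as exact zeros
phase_of <- function(F) {
  mag <- Mod(F)
  thr <- 1e-12 * max(mag)
  re <- Re(F); im <- Im(F)
  re[abs(re) <= thr] <- 0
  im[abs(im) <= thr] <- 0
  ph <- atan2(im, re)
  ph[mag <= thr] <- 0
  ph
}

# exhaustive between-class-variance search over 256 quantized levels
otsu_bruteforce <- function(img, levels = 256) {
  cand <- seq(0, 1, length.out = levels + 1)[2:levels]
  best <- -Inf; best_t <- cand[1]
  for (t in cand) {
    hi <- img > t
    n1 <- sum(hi); n0 <- sum(!hi)
    if (n1 == 0 || n0 == 0) next
    bcv <- n0 * n1 * (mean(img[hi]) - mean(img[!hi]))^2
    if (bcv > best) { best <- bcv; best_t <- t }
  }
  best_t
}

# corner-aligned bilinear interpolation, evaluated pointwise
bilinear_oracle <- function(img, side) {
  n_r <- nrow(img); n_c <- ncol(img)
  out <- matrix(0, side, side)
  for (i in 0:(side - 1)) {
    for (j in 0:(side - 1)) {
      r <- if (side == 1) (n_r - 1) / 2 else i * (n_r - 1) / (side - 1)
      c <- if (side == 1) (n_c - 1) / 2 else j * (n_c - 1) / (side - 1)
      r0 <- floor(r); c0 <- floor(c)
      fr <- r - r0; fc <- c - c0
      r1 <- min(r0 + 1, n_r - 1); c1 <- min(c0 + 1, n_c - 1)
      out[i + 1, j + 1] <-
        (1 - fr) * (1 - fc) * img[r0 + 1, c0 + 1] +
        (1 - fr) * fc * img[r0 + 1, c1 + 1] +
        fr * (1 - fc) * img[r1 + 1, c0 + 1] +
        fr * fc * img[r1 + 1, c1 + 1]
    }
  }
  out
}

# random blob mask: union of a few disks, guaranteed nonempty with
# spread on both axes
random_blob_mask <- function(side, seed, ndisks = 3) {
  withr::with_seed(seed, {
    x <- matrix(rep(seq_len(side), each = side), side, side)
    y <- matrix(rep(seq_len(side), times = side), side, side)
    m <- matrix(FALSE, side, side)
    for (i in seq_len(ndisks)) {
      cx <- runif(1, 0.3, 0.7) * side
      cy <- runif(1, 0.3, 0.7) * side
      r <- runif(1, 0.08, 0.2) * side
      m <- m | ((x - cx)^2 + (y - cy)^2 <= r^2)
    }
    out <- matrix(0, side, side); out[m] <- 1
    out
  })
}

# exact 90-degree counterclockwise grid rotation
rotate90 <- function(mask) t(mask)[ncol(mask):1, , drop = FALSE]

seeded_matrix <- function(n, seed, min = 0, max = 1) {
  withr::with_seed(seed, matrix(runif(n * n, min, max), n, n))
}
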
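#' Configuration for the synthetic image generators
#'
#' @param n_per_class Images generated per class (>= 1).
#' @param seed Integer seed; identical configs produce bit-identical
#'   image sets.
#' @param image_side Square image side in pixels (>= 16, default 100).
#' @param noise_sigma Standard deviation of additive gray-level noise on
#'   the \[0, 1\] scale (default 0.01).
#' @param class_params Optional list of per-class parameter overrides.
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_per_class, seed = 1L, image_side = 100L,
                             noise_sigma = 0.01, class_params = NULL) {
  if (!is.numeric(image_side) || image_side < 16) {
    stop("image_side must be >= 16", call. = FALSE)
  }
  if (!is.numeric(n_per_class) || n_per_class < 1) {
    stop("n_per_class must be >= 1", call. = FALSE)
  }
  if (!is.numeric(noise_sigma) || noise_sigma < 0) {
    stop("noise_sigma must be >= 0", call. = FALSE)
  }
  if (!is.numeric(seed) || length(seed) != 1) {
    stop("seed must be a single integer", call. = FALSE)
  }
  structure(list(n_per_class = as.integer(n_per_class),
                 seed = as.integer(seed),
                 image_side = as.integer(image_side),
                 noise_sigma = noise_sigma,
                 class_params = class_params),
            class = "synthetic_config")
}

.labeled_image <- function(pixels, superordinate, basic, subordinate, id) {
  structure(list(pixels = pixels,
                 label = c(superordinate = superordinate, basic = basic,
                           subordinate = subordinate),
                 id = id),
            class = "labeled_image")
}

#' Generate the superordinate (artificial vs natural) image set
#'
#' Artificial images are compositions of 2-6 axis-aligned
#' constant-intensity rectangles and/or square-wave gratings: sharp
#' edges whose spectral energy concentrates in few harmonics. Natural
#' images are random-phase 1/f^beta noise textures with beta drawn
#' uniformly in \[1.5, 2.5\], min-max rescaled to \[0, 1\]: the smooth
#' power-law spectra typical of natural scenes. Artificial images
#' additionally receive `noise_sigma` Gaussian gray noise (the natural
#' family is stochastic already). The two families are separable in the
#' 3-dimensional frequency-feature space.
#'
#' @param cfg A `synthetic_config`.
#' @return A list of 2 x n_per_class `labeled_image` objects
#'   (grayscale), artificial first.
#' @export
gen_superordinate_set <- function(cfg) {
  .check_config(cfg)
  s <- cfg$image_side
  withr::with_seed(cfg$seed, {
    art <- lapply(seq_len(cfg$n_per_class), function(i)
      .labeled_image(.artificial_image(s, cfg$noise_sigma),
                     "artificial", "-", "-", sprintf("art_%04d", i)))
    nat <- lapply(seq_len(cfg$n_per_class), function(i)
      .labeled_image(.natural_texture(s),
                     "natural", "-", "-", sprintf("nat_%04d", i)))
    c(art, nat)
  })
}

.artificial_image <- function(s, noise_sigma) {
  img <- matrix(stats::runif(1, 0.15, 0.85), s, s)
  if (stats::runif(1) < 0.5) {
    # full-field square-wave grating (optionally overlaid with rectangles)
    period <- sample(12:25, 1)
    lo <- stats::runif(1, 0, 0.35); hi <- stats::runif(1, 0.65, 1)
    wave <- ((seq_len(s) - 1) %/% (period / 2)) %% 2
    img <- if (stats::runif(1) < 0.5) matrix(ifelse(wave, hi, lo), s, s)
           else matrix(ifelse(wave, hi, lo), s, s, byrow = TRUE)
    nrect <- sample(0:2, 1)
  } else {
    nrect <- sample(2:6, 1)
  }
  for (j in seq_len(nrect)) {
    w <- sample(round(s * 0.2):round(s * 0.7), 1)
    h <- sample(round(s * 0.2):round(s * 0.7), 1)
    x0 <- sample(seq_len(s - w + 1), 1)
    y0 <- sample(seq_len(s - h + 1), 1)
    img[y0:(y0 + h - 1), x0:(x0 + w - 1)] <- stats::runif(1)
  }
  if (noise_sigma > 0) {
    img <- img + matrix(stats::rnorm(s * s, 0, noise_sigma), s, s)
  }
  pmin(pmax(img, 0), 1)
}

.natural_texture <- function(s) {
  beta <- stats::runif(1, 1.5, 2.5)
  white <- matrix(stats::rnorm(s * s), s, s)
  fi <- c(0:floor(s / 2), -(ceiling(s / 2) - 1):-1) / s
  f <- sqrt(outer(fi^2, fi^2, "+"))
  amp <- ifelse(f > 0, f^(-beta / 2), 0)
  img <- Re(stats::fft(stats::fft(white) * amp, inverse = TRUE)) / (s * s)
  rng <- range(img)
  (img - rng[1]) / (rng[2] - rng[1])
}

#' Generate the basic-level (animal vs plant) silhouette set
#'
#' Binary masks. An "animal" is a horizontal ellipse body with four
#' rectangular legs and a circular head, with randomized proportions and
#' a small whole-body rotation (within +/- 15 degrees). A "plant" is,
#' equiprobably, a radial flower (petal count uniform in 5..12, plus a
#' stem) or a two-level branching tree with terminal foliage disks.
#' Every mask's foreground fraction lies in \[0.05, 0.6\].
#'
#' @param cfg A `synthetic_config`.
#' @return A list of 2 x n_per_class binary `labeled_image` objects,
#'   animals first.
#' @export
gen_basic_silhouette_set <- function(cfg) {
  .check_config(cfg)
  s <- cfg$image_side
  withr::with_seed(cfg$seed, {
    ani <- lapply(seq_len(cfg$n_per_class), function(i)
      .labeled_image(.bounded_fraction(function() .animal_mask(s)),
                     "natural", "animal", "-", sprintf("ani_%04d", i)))
    pla <- lapply(seq_len(cfg$n_per_class), function(i)
      .labeled_image(.bounded_fraction(function() .plant_mask(s)),
                     "natural", "plant", "-", sprintf("pla_%04d", i)))
    c(ani, pla)
  })
}

# redraw (deterministically, within the seeded stream) until the
# foreground fraction contract [0.05, 0.6] holds; ranges below make
# violations rare
.bounded_fraction <- function(gen, lo = 0.05, hi = 0.6, tries = 25L) {
  for (i in seq_len(tries)) {
    mask <- gen()
    frac <- mean(mask)
    if (frac >= lo && frac <= hi) return(mask)
  }
  stop("could not draw a mask with foreground fraction in [",
       lo, ", ", hi, "]", call. = FALSE)
}

.pixel_grid <- function(s) {
  list(x = matrix(rep(seq_len(s), each = s), s, s) - (s + 1) / 2,
       y = matrix(rep(seq_len(s), times = s), s, s) - (s + 1) / 2)
}

.animal_mask <- function(s) {
  g <- .pixel_grid(s)
  th <- stats::runif(1, -15, 15) * pi / 180
  # rotate sampling coordinates by -theta about the image center
  xr <- cos(th) * g$x + sin(th) * g$y
  yr <- -sin(th) * g$x + cos(th) * g$y
  cy <- -0.05 * s
  a <- stats::runif(1, 0.20, 0.30) * s     # body semi-axis, x
  b <- stats::runif(1, 0.10, 0.16) * s     # body semi-axis, y
  body <- ((xr / a)^2 + ((yr - cy) / b)^2) <= 1
  hr <- stats::runif(1, 0.07, 0.11) * s
  hx <- a * 0.95; hy <- cy - b * 0.7
  head <- ((xr - hx)^2 + (yr - hy)^2) <= hr^2
  legw <- stats::runif(1, 0.025, 0.045) * s
  legl <- stats::runif(1, 0.18, 0.28) * s
  legs <- matrix(FALSE, s, s)
  for (px in a * c(-0.75, -0.35, 0.25, 0.65)) {
    legs <- legs | (abs(xr - px) <= legw / 2 &
                      yr >= cy + b * 0.4 & yr <= cy + b * 0.4 + legl)
  }
  m <- matrix(0, s, s); m[body | head | legs] <- 1
  m
}

.plant_mask <- function(s) {
  if (stats::runif(1) < 0.5) .flower_mask(s) else .tree_mask(s)
}

.flower_mask <- function(s) {
  g <- .pixel_grid(s)
  cy <- -0.05 * s
  r <- sqrt(g$x^2 + (g$y - cy)^2)
  theta <- atan2(g$y - cy, g$x)
  r0 <- stats::runif(1, 0.18, 0.26) * s
  amp <- stats::runif(1, 0.35, 0.55) * r0
  k <- sample(5:12, 1)
  flower <- r <= r0 + amp * cos(k * theta)
  stemw <- 0.03 * s
  stem <- abs(g$x) <= stemw / 2 & g$y >= cy & g$y <= 0.42 * s
  m <- matrix(0, s, s); m[flower | stem] <- 1
  m
}

# thick line segment: points within w/2 of the segment p0 -> p1
.segment_mask <- function(g, p0, p1, w) {
  vx <- p1[1] - p0[1]; vy <- p1[2] - p0[2]
  len2 <- vx^2 + vy^2
  t <- pmin(pmax(((g$x - p0[1]) * vx + (g$y - p0[2]) * vy) / len2, 0), 1)
  dx <- g$x - (p0[1] + t * vx); dy <- g$y - (p0[2] + t * vy)
  dx^2 + dy^2 <= (w / 2)^2
}

.tree_mask <- function(s) {
  g <- .pixel_grid(s)
  m <- matrix(FALSE, s, s)
  base <- c(0, 0.42 * s)
  top <- c(0, stats::runif(1, 0.0, 0.1) * s)
  m <- m | .segment_mask(g, base, top, 0.07 * s)
  tips <- list()
  for (sgn in c(-1, 1)) {
    ang <- sgn * stats::runif(1, 25, 45) * pi / 180
    len <- stats::runif(1, 0.18, 0.26) * s
    tip <- c(top[1] + len * sin(ang), top[2] - len * cos(ang))
    m <- m | .segment_mask(g, top, tip, 0.05 * s)
    for (sgn2 in c(-1, 1)) {
      ang2 <- ang + sgn2 * stats::runif(1, 20, 40) * pi / 180
      len2 <- stats::runif(1, 0.12, 0.18) * s
      tip2 <- c(tip[1] + len2 * sin(ang2), tip[2] - len2 * cos(ang2))
      m <- m | .segment_mask(g, tip, tip2, 0.035 * s)
      fol <- stats::runif(1, 0.05, 0.08) * s
      m <- m | ((g$x - tip2[1])^2 + (g$y - tip2[2])^2 <= fol^2)
    }
  }
  out <- matrix(0, s, s); out[m] <- 1
  out
}

#' Generate the subordinate-level image set
#'
#' For each basic class (animal, plant), `classes_per_basic` subordinate
#' classes are defined by a frozen prototype silhouette (drawn once per
#' class with the silhouette generators) filled with a class-specific
#' oriented sinusoidal texture; orientation and frequency are assigned
#' deterministically distinct across classes. Each image is the
#' prototype with translation jitter of up to `jitter` pixels and
#' additive Gaussian noise (`noise_sigma`), clipped to \[0, 1\].
#'
#' @param cfg A `synthetic_config`.
#' @param classes_per_basic Subordinate classes under each basic class
#'   (>= 2).
#' @param jitter Maximum absolute translation in pixels (0 disables).
#' @return A list of 2 x classes_per_basic x n_per_class grayscale
#'   `labeled_image` objects.
#' @export
gen_subordinate_set <- function(cfg, classes_per_basic, jitter = 3L) {
  .check_config(cfg)
  if (classes_per_basic < 2) {
    stop("classes_per_basic must be >= 2", call. = FALSE)
  }
  s <- cfg$image_side
  n_classes <- 2L * classes_per_basic
  withr::with_seed(cfg$seed, {
    out <- list()
    q <- 0L
    for (basic in c("animal", "plant")) {
      for (j in seq_len(classes_per_basic)) {
        q <- q + 1L
        proto <- if (basic == "animal") {
          .bounded_fraction(function() .animal_mask(s))
        } else {
          .bounded_fraction(function() .plant_mask(s))
        }
        orient <- (q - 1) * pi / n_classes
        freq <- 4 + 1.5 * (q - 1)            # cycles per image side
        gx <- matrix(rep(seq_len(s), each = s), s, s) / s
        gy <- matrix(rep(seq_len(s), times = s), s, s) / s
        tex <- 0.55 + 0.4 * sin(2 * pi * freq *
                                  (gx * cos(orient) + gy * sin(orient)))
        base <- proto * tex
        sub <- sprintf("%s_%02d", basic, j)
        for (i in seq_len(cfg$n_per_class)) {
          img <- base
          if (jitter > 0) {
            img <- .translate(img, sample(-jitter:jitter, 1),
                              sample(-jitter:jitter, 1))
          }
          if (cfg$noise_sigma > 0) {
            img <- img + matrix(stats::rnorm(s * s, 0, cfg$noise_sigma), s, s)
          }
          out[[length(out) + 1L]] <- .labeled_image(
            pmin(pmax(img, 0), 1), "natural", basic, sub,
            sprintf("%s_%04d", sub, i))
        }
      }
    }
    out
  })
}

# integer translation with zero padding (dx: columns, dy: rows)
.translate <- function(img, dx, dy) {
  s <- nrow(img)
  out <- matrix(0, s, ncol(img))
  src_r <- seq_len(s) - dy
  src_c <- seq_len(ncol(img)) - dx
  ok_r <- src_r >= 1 & src_r <= s
  ok_c <- src_c >= 1 & src_c <= ncol(img)
  out[ok_r, ok_c] <- img[src_r[ok_r], src_c[ok_c]]
  out
}

.check_config <- function(cfg) {
  if (!inherits(cfg, "synthetic_config")) {
    stop("cfg must be a synthetic_config()", call. = FALSE)
  }
}
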
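#' Stack images into a pixel-by-sample matrix
#'
#' Vectorizes each image column-major (R's native scan order) into one
#' column of a d x n matrix. All images must share the same dimensions.
#'
#' @param images List of numeric matrices, or of `labeled_image` objects.
#' @param labels Optional character vector of per-image labels; for
#'   `labeled_image` input the basic-level label is taken automatically.
#' @return A list with `S` (d x n matrix), `side` (image dimensions) and
#'   `labels`.
#' @export
image_matrix <- function(images, labels = NULL) {
  stopifnot(length(images) >= 1)
  if (inherits(images[[1]], "labeled_image")) {
    if (is.null(labels)) {
      labels <- vapply(images, function(im) unname(im$label[2]), character(1))
    }
    images <- lapply(images, `[[`, "pixels")
  }
  dims <- dim(images[[1]])
  ok <- vapply(images, function(im) identical(dim(im), dims), logical(1))
  if (!all(ok)) stop("all images must share the same dimensions", call. = FALSE)
  S <- vapply(images, as.vector, numeric(prod(dims)))
  list(S = S, side = dims, labels = labels)
}

#' Fit a principal subspace with the small-covariance (Gram) trick
#'
#' Columns of S are centered by their mean; instead of the d x d
#' covariance, the n x n Gram matrix G = Sc' Sc is eigendecomposed and
#' each eigenvector v_i is mapped back to pixel space as u_i = Sc v_i,
#' then normalized to unit length. Eigenvalues below 1e-10 times the
#' largest are treated as null directions. The sign of each u_i is fixed
#' so its largest-magnitude entry is positive, making the basis
#' deterministic.
#'
#' @param S A d x n numeric matrix (columns = vectorized images), or a
#'   list of equally-sized image matrices.
#' @param k Number of leading eigenvectors to keep; must not exceed the
#'   numerical rank of the centered data (at most n - 1).
#' @return A list with `mean` (length-d vector), `basis` (d x k, columns
#'   orthonormal) and `eigenvalues` (length k, descending, nonnegative).
#' @export
fit_subspace <- function(S, k) {
  if (is.list(S)) S <- image_matrix(S)$S
  stopifnot(is.matrix(S))
  n <- ncol(S)
  if (n < 2) stop("need at least 2 images", call. = FALSE)
  mu <- rowMeans(S)
  Sc <- S - mu
  G <- crossprod(Sc)
  eg <- eigen(G, symmetric = TRUE)
  vals <- pmax(eg$values, 0)
  rank <- if (vals[1] > 0) sum(vals >= 1e-10 * vals[1]) else 0L
  if (k > rank) {
    stop("k = ", k, " exceeds the available rank ", rank, call. = FALSE)
  }
  U <- Sc %*% eg$vectors[, seq_len(k), drop = FALSE]
  U <- sweep(U, 2, sqrt(colSums(U^2)), "/")
  for (j in seq_len(k)) {
    i <- which.max(abs(U[, j]))
    if (U[i, j] < 0) U[, j] <- -U[, j]
  }
  list(mean = mu, basis = U, eigenvalues = vals[seq_len(k)])
}

#' Fit a pooled ("flat") eigenspace over all basic classes
#'
#' @param im An `image_matrix()` result with basic-level labels.
#' @param k Number of eigenvectors (defaults to n - 1, the rank bound
#'   after centering).
#' @return An object of class `eigenspace_model` with `mode = "flat"`.
#' @export
fit_flat <- function(im, k = ncol(im$S) - 1L) {
  .check_image_matrix(im)
  if (length(unique(im$labels)) < 2) {
    stop("flat model expects both basic classes in training data", call. = FALSE)
  }
  fit <- fit_subspace(im$S, k)
  structure(list(mode = "flat", side = im$side, mean = fit$mean,
                 basis = fit$basis, eigenvalues = fit$eigenvalues),
            class = "eigenspace_model")
}

#' Fit per-class ("conceptual") eigenspaces
#'
#' One subspace is fit independently on the training images of each
#' basic class (classes in sorted label order); projections onto the
#' per-class bases are later concatenated. Changing one class's training
#' images leaves the other classes' bases untouched.
#'
#' @param im An `image_matrix()` result with basic-level labels; every
#'   class needs at least 2 images.
#' @param k Eigenvectors per class: a single count recycled across
#'   classes, or a vector named by class. Default: each class's rank
#'   bound (class size - 1).
#' @return An object of class `eigenspace_model` with
#'   `mode = "conceptual"` and one `(mean, basis)` pair per class.
#' @export
fit_conceptual <- function(im, k = NULL) {
  .check_image_matrix(im)
  classes <- sort(unique(im$labels))
  if (length(classes) < 2) {
    stop("conceptual model expects at least two basic classes", call. = FALSE)
  }
  sizes <- table(im$labels)
  if (any(sizes < 2)) {
    stop("every basic class needs at least 2 training images", call. = FALSE)
  }
  if (is.null(k)) k <- as.integer(sizes[classes]) - 1L
  if (length(k) == 1L) k <- rep(k, length(classes))
  if (!is.null(names(k))) k <- k[classes]
  sub <- lapply(seq_along(classes), function(i) {
    cols <- im$labels == classes[i]
    fit_subspace(im$S[, cols, drop = FALSE], k[i])
  })
  names(sub) <- classes
  structure(list(mode = "conceptual", side = im$side, subspaces = sub),
            class = "eigenspace_model")
}

#' Project an image into an eigenspace model
#'
#' Flat mode returns u' (x - mean); conceptual mode concatenates the
#' centered projections onto every per-class basis, in sorted class
#' order.
#'
#' @param model An `eigenspace_model`.
#' @param image Numeric matrix matching the model's training image size.
#' @return A numeric feature vector (length k, or sum of per-class k).
#' @export
project <- function(model, image) {
  stopifnot(inherits(model, "eigenspace_model"))
  if (!identical(dim(image), as.integer(model$side))) {
    stop("image is ", paste(dim(image), collapse = "x"),
         " but model expects ", paste(model$side, collapse = "x"),
         call. = FALSE)
  }
  x <- as.vector(image)
  if (model$mode == "flat") {
    return(drop(crossprod(model$basis, x - model$mean)))
  }
  unlist(lapply(model$subspaces, function(s)
    drop(crossprod(s$basis, x - s$mean))), use.names = FALSE)
}

#' Project a set of images into an eigenspace model
#'
#' @param model An `eigenspace_model`.
#' @param images List of image matrices or `labeled_image` objects.
#' @return A matrix with one row per image.
#' @export
project_set <- function(model, images) {
  if (length(images) > 0 && inherits(images[[1]], "labeled_image")) {
    images <- lapply(images, `[[`, "pixels")
  }
  t(vapply(images, function(im) project(model, im),
           numeric(.feature_length(model))))
}

.feature_length <- function(model) {
  if (model$mode == "flat") return(ncol(model$basis))
  sum(vapply(model$subspaces, function(s) ncol(s$basis), integer(1)))
}

.check_image_matrix <- function(im) {
  if (!is.list(im) || is.null(im$S) || is.null(im$labels)) {
    stop("expected an image_matrix() result with labels", call. = FALSE)
  }
  stopifnot(ncol(im$S) == length(im$labels))
}
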
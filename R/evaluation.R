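#' Fuzzy c-means clustering
#'
#' Standard alternating optimization: graded memberships and cluster
#' centers are updated in turn until the maximum center shift falls
#' below `tol` or `max_iter` is reached. Features are z-score
#' standardized per dimension first (the frequency features span several
#' orders of magnitude), and memberships are initialized from the seeded
#' uniform distribution, so results are reproducible from `seed`. The
#' objective sum(u^m d^2) is recorded at every iteration; it is
#' non-increasing for this update scheme.
#'
#' @param x Numeric matrix, one row per observation.
#' @param centers Number of clusters (default 2).
#' @param m Fuzzifier exponent > 1 (default 2).
#' @param tol Convergence tolerance on the center shift.
#' @param max_iter Iteration cap.
#' @param seed Integer seed for the membership initialization.
#' @param standardize Z-score each column first (default TRUE).
#' @return An object of class `fuzzy_clustering`: `memberships` (n x c,
#'   row-stochastic), `centers`, `n_iter`, `converged`, `objective`
#'   (per-iteration trace).
#' @export
fuzzy_cmeans <- function(x, centers = 2L, m = 2, tol = 1e-8,
                         max_iter = 300L, seed = 1L, standardize = TRUE) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (n <= centers) stop("need more observations than clusters", call. = FALSE)
  stopifnot(m > 1)
  if (standardize) x <- .zscore(x)$x
  U <- withr::with_seed(seed, matrix(stats::runif(n * centers), n, centers))
  U <- U / rowSums(U)
  C_old <- matrix(Inf, centers, ncol(x))
  objective <- numeric(0)
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    Um <- U^m
    C <- (t(Um) %*% x) / colSums(Um)
    d2 <- outer(rowSums(x^2), rep(1, centers)) -
      2 * x %*% t(C) + outer(rep(1, n), rowSums(C^2))
    d2 <- pmax(d2, 0)
    U <- .fcm_memberships(d2, m)
    objective <- c(objective, sum(U^m * d2))
    shift <- max(abs(C - C_old))
    C_old <- C
    if (shift < tol) { converged <- TRUE; break }
  }
  structure(list(memberships = U, centers = C, n_iter = iter,
                 converged = converged, objective = objective),
            class = "fuzzy_clustering")
}

# membership update u_ij = (1/d2_ij)^(1/(m-1)) / sum_k (1/d2_ik)^(1/(m-1));
# a point sitting exactly on >=1 centers splits its membership among them
.fcm_memberships <- function(d2, m) {
  n <- nrow(d2); c <- ncol(d2)
  U <- matrix(0, n, c)
  zero <- d2 < .Machine$double.eps
  hit <- rowSums(zero) > 0
  if (any(hit)) U[hit, ] <- zero[hit, , drop = FALSE] / rowSums(zero[hit, , drop = FALSE])
  if (any(!hit)) {
    w <- d2[!hit, , drop = FALSE]^(-1 / (m - 1))
    U[!hit, ] <- w / rowSums(w)
  }
  U
}

#' Precision/recall/f-measure/accuracy of a two-cluster partition
#'
#' Cluster indices are mapped to the two truth classes by whichever of
#' the two assignments maximizes accuracy, so the metrics are invariant
#' to cluster relabeling. Precision, recall and f-measure are reported
#' for `positive_class`; accuracy is over all points.
#'
#' @param assignments Integer/factor vector of hard cluster indices.
#' @param truth Vector of true class labels (two classes).
#' @param positive_class The class precision/recall refer to
#'   (default "natural").
#' @return An object of class `cluster_metrics` with fields `f_measure`,
#'   `precision`, `recall`, `accuracy`, all in \[0, 1\].
#' @export
cluster_metrics <- function(assignments, truth, positive_class = "natural") {
  if (length(assignments) != length(truth)) {
    stop("assignments and truth differ in length", call. = FALSE)
  }
  classes <- sort(unique(as.character(truth)))
  stopifnot(length(classes) == 2, positive_class %in% classes)
  cl <- as.integer(factor(assignments))
  map1 <- classes[cl]
  map2 <- rev(classes)[cl]
  acc1 <- mean(map1 == truth); acc2 <- mean(map2 == truth)
  rec <- function(mp) mean(mp[truth == positive_class] == positive_class)
  mapped <- if (acc1 > acc2 || (acc1 == acc2 && rec(map1) >= rec(map2)))
    map1 else map2
  tp <- sum(mapped == positive_class & truth == positive_class)
  fp <- sum(mapped == positive_class & truth != positive_class)
  fn <- sum(mapped != positive_class & truth == positive_class)
  precision <- if (tp + fp == 0) 1 else tp / (tp + fp)
  recall <- if (tp + fn == 0) 1 else tp / (tp + fn)
  f <- if (precision + recall == 0) 0 else
    2 * precision * recall / (precision + recall)
  structure(list(f_measure = f, precision = precision, recall = recall,
                 accuracy = mean(mapped == truth)),
            class = "cluster_metrics")
}

#' Precision-recall sweep over membership thresholds
#'
#' The cluster most aligned with `positive_class` (under the
#' accuracy-maximizing mapping of hard argmax assignments) is taken as
#' the positive cluster; for each threshold a point is assigned positive
#' when its membership in that cluster is >= the threshold. When no
#' point clears the threshold, precision is reported as 1 with recall 0.
#'
#' @param clustering A `fuzzy_clustering` result (2 clusters).
#' @param truth True class labels.
#' @param thresholds Numeric vector in \[0, 1\].
#' @param positive_class Positive class label (default "natural").
#' @return A data.frame with columns `threshold`, `precision`, `recall`.
#' @export
pr_sweep <- function(clustering, truth, thresholds,
                     positive_class = "natural") {
  stopifnot(inherits(clustering, "fuzzy_clustering"),
            ncol(clustering$memberships) == 2,
            all(thresholds >= 0), all(thresholds <= 1))
  U <- clustering$memberships
  hard <- max.col(U)
  acc1 <- mean((hard == 1) == (truth == positive_class))
  pos_col <- if (acc1 >= 1 - acc1) 1L else 2L
  mem <- U[, pos_col]
  npos <- sum(truth == positive_class)
  rows <- lapply(thresholds, function(t) {
    sel <- mem >= t
    tp <- sum(sel & truth == positive_class)
    data.frame(threshold = t,
               precision = if (sum(sel) == 0) 1 else tp / sum(sel),
               recall = if (npos == 0) 1 else tp / npos)
  })
  do.call(rbind, rows)
}

#' Repeated-split linear-SVM classification harness
#'
#' Per run: a stratified random split holds out `1 - train_fraction` of
#' each class, features are z-scored with training-set statistics only,
#' a linear-kernel SVM (cost 1) is fit, and per-class plus total
#' accuracy are measured on the held-out images. Means and standard
#' deviations over `n_runs` are reported in percent; splits are
#' reproducible from `seed`.
#'
#' @param features Numeric matrix, one row per sample.
#' @param labels Class labels (>= 2 classes, each with >= 2 samples).
#' @param train_fraction Proportion of each class used for training.
#' @param n_runs Number of random splits (default 10).
#' @param seed Integer seed.
#' @param cost SVM regularization constant (default 1).
#' @return An object of class `classification_report`: `per_class`
#'   (data.frame class/mean/sd), `total` (mean, sd), `runs` (per-run
#'   accuracy matrix), `n_runs`, `train_fraction`, `seed`.
#' @export
classification_harness <- function(features, labels, train_fraction = 0.5,
                                   n_runs = 10L, seed = 1L, cost = 1) {
  features <- as.matrix(features)
  labels <- as.character(labels)
  stopifnot(nrow(features) == length(labels),
            train_fraction > 0, train_fraction < 1)
  classes <- sort(unique(labels))
  if (length(classes) < 2) stop("need at least 2 classes", call. = FALSE)
  sizes <- table(labels)
  if (any(sizes < 2)) stop("every class needs >= 2 samples", call. = FALSE)
  runs <- withr::with_seed(seed, {
    lapply(seq_len(n_runs), function(r) {
      tr <- unlist(lapply(classes, function(cl) {
        idx <- which(labels == cl)
        ntr <- min(max(round(train_fraction * length(idx)), 1L),
                   length(idx) - 1L)
        sample(idx, ntr)
      }))
      sc <- .zscore(features[tr, , drop = FALSE])
      xtr <- sc$x
      xte <- scale(features[-tr, , drop = FALSE], sc$center, sc$scale)
      fit <- e1071::svm(xtr, factor(labels[tr], levels = classes),
                        kernel = "linear", cost = cost, scale = FALSE)
      pred <- as.character(stats::predict(fit, xte))
      te_lab <- labels[-tr]
      acc <- vapply(classes, function(cl)
        100 * mean(pred[te_lab == cl] == cl), numeric(1))
      c(acc, total = 100 * mean(pred == te_lab),
        n_test = length(te_lab))
    })
  })
  runs <- do.call(rbind, runs)
  per_class <- data.frame(
    class = classes,
    mean = colMeans(runs[, classes, drop = FALSE]),
    sd = apply(runs[, classes, drop = FALSE], 2, stats::sd),
    row.names = NULL, stringsAsFactors = FALSE)
  structure(list(per_class = per_class,
                 total = c(mean = mean(runs[, "total"]),
                           sd = stats::sd(runs[, "total"])),
                 runs = runs, n_runs = n_runs,
                 train_fraction = train_fraction, seed = seed),
            class = "classification_report")
}

#' @export
print.classification_report <- function(x, ...) {
  cat(sprintf("Linear-SVM report: %d runs, train fraction %.2f\n",
              x$n_runs, x$train_fraction))
  cat(sprintf("Total accuracy: %.2f%% (sd %.2f)\n",
              x$total["mean"], x$total["sd"]))
  for (i in seq_len(nrow(x$per_class))) {
    cat(sprintf("  %-12s %.2f%% (sd %.2f)\n", x$per_class$class[i],
                x$per_class$mean[i], x$per_class$sd[i]))
  }
  invisible(x)
}

#' Mean relative per-class accuracy improvement, in percent
#'
#' For each class, 100 x (acc_new - acc_base) / acc_base; the mean over
#' classes is returned. Classes with zero baseline accuracy are excluded
#' with a warning.
#'
#' @param report_new,report_base `classification_report` objects over
#'   the same class set.
#' @return A single percentage (negative when the new features do worse).
#' @export
percentage_improvement <- function(report_new, report_base) {
  stopifnot(inherits(report_new, "classification_report"),
            inherits(report_base, "classification_report"))
  if (!identical(report_new$per_class$class, report_base$per_class$class)) {
    stop("reports cover different class sets", call. = FALSE)
  }
  a_new <- report_new$per_class$mean
  a_base <- report_base$per_class$mean
  keep <- a_base > 0
  if (!all(keep)) {
    warning("excluding ", sum(!keep),
            " class(es) with zero baseline accuracy")
  }
  mean(100 * (a_new[keep] - a_base[keep]) / a_base[keep])
}

# z-score columns; zero-variance columns are left unscaled (sd -> 1)
.zscore <- function(x) {
  center <- colMeans(x)
  scale <- apply(x, 2, stats::sd)
  scale[scale == 0 | is.na(scale)] <- 1
  list(x = scale(x, center, scale), center = center, scale = scale)
}
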
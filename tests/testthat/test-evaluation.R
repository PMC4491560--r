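two_clouds <- function(n_per, sep = 10, seed = 1) {
  withr::with_seed(seed, {
    x <- rbind(matrix(rnorm(n_per * 2, -sep / 2), n_per, 2),
               matrix(rnorm(n_per * 2, sep / 2), n_per, 2))
    list(x = x, truth = rep(c("artificial", "natural"), each = n_per))
  })
}

test_that("fuzzy c-means resolves well-separated clouds with confident memberships", {
  d <- two_clouds(25, sep = 10, seed = 1)
  fc <- fuzzy_cmeans(d$x, seed = 1)
  expect_true(fc$converged)
  expect_equal(rowSums(fc$memberships), rep(1, 50), tolerance = 1e-12)
  expect_true(all(apply(fc$memberships, 1, max) >= 0.9))
  # the two hard clusters coincide with the clouds
  hard <- max.col(fc$memberships)
  expect_equal(cluster_metrics(hard, d$truth)$accuracy, 1)
})

test_that("the FCM objective is non-increasing and runs are seed-reproducible", {
  d <- two_clouds(20, sep = 3, seed = 2)
  fc <- fuzzy_cmeans(d$x, seed = 7)
  expect_true(all(diff(fc$objective) <= 1e-10))
  fc2 <- fuzzy_cmeans(d$x, seed = 7)
  expect_identical(fc$memberships, fc2$memberships)
  expect_error(fuzzy_cmeans(d$x[1:2, ], centers = 2), "more observations")
})

test_that("FCM centers agree with the e1071 reference on separated clouds", {
  d <- two_clouds(30, sep = 8, seed = 3)
  fc <- fuzzy_cmeans(d$x, seed = 1, standardize = FALSE)
  ref <- withr::with_seed(2, e1071::cmeans(d$x, centers = 2, m = 2))
  ours <- fc$centers[order(fc$centers[, 1]), ]
  theirs <- ref$centers[order(ref$centers[, 1]), ]
  expect_equal(ours, theirs, tolerance = 1e-3, ignore_attr = TRUE)
})

test_that("a point equidistant from both centers gets half memberships", {
  pts <- rbind(c(-5, 0), c(-5, 1), c(-5, -1), c(5, 0), c(5, 1), c(5, -1),
               c(0, 0))
  fc <- fuzzy_cmeans(pts, seed = 1, standardize = FALSE, tol = 1e-12)
  expect_equal(unname(fc$memberships[7, ]), c(0.5, 0.5), tolerance = 1e-6)
})

test_that("cluster metrics follow the contingency-table formulas", {
  truth <- rep(c("natural", "artificial"), each = 10)
  perfect <- cluster_metrics(rep(c(1, 2), each = 10), truth)
  expect_equal(unclass(perfect)[c("f_measure", "precision", "recall",
                                  "accuracy")],
               list(f_measure = 1, precision = 1, recall = 1, accuracy = 1))
  # relabeled clusters give identical metrics
  flipped <- cluster_metrics(rep(c(2, 1), each = 10), truth)
  expect_equal(unclass(flipped), unclass(perfect))

  # everything assigned to one cluster, balanced truth
  one <- cluster_metrics(rep(1, 20), truth)
  expect_equal(one$recall, 1)
  expect_equal(one$precision, 0.5)
  expect_equal(one$accuracy, 0.5)
  expect_equal(one$f_measure, 2 / 3)

  expect_error(cluster_metrics(1:3, truth), "length")
})

test_that("the precision-recall sweep honors its threshold conventions", {
  d <- two_clouds(10, sep = 6, seed = 4)
  fc <- fuzzy_cmeans(d$x, seed = 1)
  sw <- pr_sweep(fc, d$truth, thresholds = seq(0, 1, by = 0.05))
  expect_equal(sw$recall[sw$threshold == 0], 1)
  expect_true(all(diff(sw$recall) <= 0))          # monotone non-increasing
  high <- pr_sweep(fc, d$truth, thresholds = 1 - 1e-12)
  if (max(fc$memberships[, max.col(fc$memberships)[1]]) < 1 - 1e-12) {
    expect_equal(high$precision, 1)
  }
  expect_error(pr_sweep(fc, d$truth, thresholds = 1.5), "thresholds")
})

test_that("empty-positive thresholds report precision 1 and recall 0", {
  fc <- structure(list(memberships = cbind(c(.8, .7, .3), c(.2, .3, .7)),
                       centers = NULL, n_iter = 1L, converged = TRUE,
                       objective = 0),
                  class = "fuzzy_clustering")
  truth <- c("natural", "natural", "artificial")
  sw <- pr_sweep(fc, truth, thresholds = c(0.95))
  expect_equal(sw$precision, 1)
  expect_equal(sw$recall, 0)
})

test_that("the SVM harness is exact on separable data and seed-stable", {
  d <- two_clouds(20, sep = 12, seed = 5)
  rep1 <- classification_harness(d$x, d$truth, train_fraction = 0.5,
                                 n_runs = 10, seed = 3)
  expect_equal(unname(rep1$total["mean"]), 100)
  expect_equal(unname(rep1$total["sd"]), 0)
  rep2 <- classification_harness(d$x, d$truth, train_fraction = 0.5,
                                 n_runs = 10, seed = 3)
  expect_identical(rep1$runs, rep2$runs)
  expect_true(all(rep1$per_class$mean >= 0 & rep1$per_class$mean <= 100))
})

test_that("shuffled labels score at chance level", {
  X <- withr::with_seed(6, matrix(rnorm(400), 200, 2))
  labels <- rep(c("a", "b"), 100)
  rep <- classification_harness(X, labels, train_fraction = 0.5,
                                n_runs = 10, seed = 1)
  expect_gte(rep$total["mean"], 40)
  expect_lte(rep$total["mean"], 60)
})

test_that("per-class accuracies weighted by test size reproduce the totals", {
  d <- two_clouds(15, sep = 2, seed = 7)
  d$truth[1:5] <- "natural"                # unbalanced classes
  rep <- classification_harness(d$x, d$truth, train_fraction = 0.6,
                                n_runs = 5, seed = 2)
  sizes <- table(d$truth)
  n_te <- vapply(names(sizes), function(cl) {
    n <- sizes[[cl]]
    n - min(max(round(0.6 * n), 1), n - 1)
  }, numeric(1))
  for (r in seq_len(nrow(rep$runs))) {
    weighted <- sum(rep$runs[r, names(sizes)] * n_te) / sum(n_te)
    expect_equal(weighted, unname(rep$runs[r, "total"]), tolerance = 1e-10)
  }
})

test_that("percentage improvement averages per-class relative gains", {
  mk <- function(acc) {
    structure(list(per_class = data.frame(class = c("a", "b"), mean = acc,
                                          sd = 0)),
              class = "classification_report")
  }
  expect_equal(percentage_improvement(mk(c(60, 88)), mk(c(50, 80))), 15)
  expect_equal(percentage_improvement(mk(c(50, 80)), mk(c(50, 80))), 0)
  expect_lt(percentage_improvement(mk(c(40, 70)), mk(c(50, 80))), 0)
  expect_warning(percentage_improvement(mk(c(50, 80)), mk(c(0, 80))),
                 "zero baseline")
  bad <- mk(c(1, 2)); bad$per_class$class <- c("a", "c")
  expect_error(percentage_improvement(bad, mk(c(1, 2))), "class sets")
})
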
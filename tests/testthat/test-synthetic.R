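test_that("configs are validated", {
  expect_error(synthetic_config(5, image_side = 8), "image_side")
  expect_error(synthetic_config(0), "n_per_class")
  expect_error(synthetic_config(5, noise_sigma = -0.1), "noise_sigma")
  expect_s3_class(synthetic_config(5), "synthetic_config")
  expect_error(gen_superordinate_set(list(n_per_class = 5)),
               "synthetic_config")
})

test_that("the superordinate set has the right size, labels and range", {
  cfg <- synthetic_config(n_per_class = 5, seed = 1, image_side = 32)
  imgs <- gen_superordinate_set(cfg)
  expect_length(imgs, 10)
  sup <- vapply(imgs, function(im) unname(im$label[1]), character(1))
  expect_equal(sum(sup == "artificial"), 5)
  expect_equal(sum(sup == "natural"), 5)
  expect_true(all(vapply(imgs, function(im)
    all(im$pixels >= 0 & im$pixels <= 1), logical(1))))
  expect_length(unique(vapply(imgs, `[[`, character(1), "id")), 10)
})

test_that("generators are bit-identical under equal configs", {
  cfg <- synthetic_config(n_per_class = 3, seed = 9, image_side = 40)
  expect_identical(gen_superordinate_set(cfg), gen_superordinate_set(cfg))
  expect_identical(gen_basic_silhouette_set(cfg),
                   gen_basic_silhouette_set(cfg))
  expect_identical(gen_subordinate_set(cfg, 2), gen_subordinate_set(cfg, 2))
  # and the outer RNG state is untouched
  withr::with_seed(1, {
    before <- runif(1)
  })
  withr::with_seed(1, {
    invisible(gen_superordinate_set(cfg))
    expect_equal(runif(1), before)
  })
})

test_that("silhouettes are binary with bounded foreground fraction", {
  cfg <- synthetic_config(n_per_class = 4, seed = 3)
  masks <- gen_basic_silhouette_set(cfg)
  expect_length(masks, 8)
  for (im in masks) {
    expect_true(all(im$pixels %in% c(0, 1)))
    frac <- mean(im$pixels)
    expect_gte(frac, 0.05)
    expect_lte(frac, 0.6)
    expect_equal(unname(im$label[1]), "natural")   # taxonomy consistency
  }
  basics <- vapply(masks, function(im) unname(im$label[2]), character(1))
  expect_equal(as.integer(table(basics)[c("animal", "plant")]), c(4L, 4L))
})

test_that("the subordinate set nests 2 x classes_per_basic classes", {
  cfg <- synthetic_config(n_per_class = 10, seed = 2)
  imgs <- gen_subordinate_set(cfg, classes_per_basic = 6)
  expect_length(imgs, 120)
  labs <- t(vapply(imgs, function(im) im$label, character(3)))
  expect_equal(length(unique(labs[, 3])), 12)
  expect_equal(sum(labs[, 2] == "animal"), 60)
  expect_equal(sum(labs[, 2] == "plant"), 60)
  # every subordinate class sits under a single basic class
  expect_true(all(tapply(labs[, 2], labs[, 3],
                         function(v) length(unique(v))) == 1))
  expect_true(all(table(labs[, 3]) == 10))
  expect_error(gen_subordinate_set(cfg, classes_per_basic = 1), ">= 2")
})

test_that("noise-free, jitter-free subordinate images are identical per class", {
  cfg <- synthetic_config(n_per_class = 4, seed = 5, noise_sigma = 0)
  imgs <- gen_subordinate_set(cfg, classes_per_basic = 2, jitter = 0)
  labs <- vapply(imgs, function(im) unname(im$label[3]), character(1))
  for (cl in unique(labs)) {
    pix <- lapply(imgs[labs == cl], `[[`, "pixels")
    for (p in pix[-1]) expect_identical(p, pix[[1]])
  }
})

test_that("frequency features separate the two superordinate families", {
  cfg <- synthetic_config(n_per_class = 50, seed = 7)
  ft <- frequency_feature_table(gen_superordinate_set(cfg))
  X <- scale(as.matrix(ft[, c("f1", "f2", "f3")]))
  km <- withr::with_seed(1, stats::kmeans(X, 2, nstart = 10))
  tab <- table(km$cluster, ft$superordinate)
  purity <- sum(apply(tab, 1, max)) / sum(tab)
  expect_gte(purity, 0.95)
})

test_that("conceptual eigen-features beat flat ones on the subordinate set", {
  cfg <- synthetic_config(n_per_class = 20, seed = 5)
  imgs <- gen_subordinate_set(cfg, classes_per_basic = 3)
  im <- image_matrix(imgs)
  labs <- vapply(imgs, function(x) unname(x$label[3]), character(1))
  flat <- fit_flat(im, k = ncol(im$S) - 1L)
  conc <- fit_conceptual(im)
  r_flat <- classification_harness(project_set(flat, imgs), labs,
                                   train_fraction = 0.5, n_runs = 10,
                                   seed = 5)
  r_conc <- classification_harness(project_set(conc, imgs), labs,
                                   train_fraction = 0.5, n_runs = 10,
                                   seed = 5)
  expect_gte(r_conc$total["mean"], r_flat$total["mean"])
})

test_that("image sets round-trip through the PNG tree and manifest", {
  root <- file.path(withr::local_tempdir(), "ds")
  cfg <- synthetic_config(n_per_class = 2, seed = 4, image_side = 32)
  imgs <- gen_basic_silhouette_set(cfg)
  manifest <- write_image_set(imgs, root)
  expect_equal(nrow(manifest), 4)
  expect_true(file.exists(file.path(root, "manifest.csv")))
  expect_true(all(file.exists(file.path(root, manifest$path))))
  expect_match(manifest$path[1], "natural/animal/-/")

  back <- read_image_set(root)
  expect_length(back, 4)
  # binary masks survive 8-bit PNG exactly
  expect_equal(back[[1]]$pixels, imgs[[1]]$pixels)
  expect_identical(back[[3]]$label, imgs[[3]]$label)

  expect_error(write_image_set(imgs, root), "nonempty")
  md5_a <- tools::md5sum(file.path(root, "manifest.csv"))
  write_image_set(imgs, root, overwrite = TRUE)
  expect_identical(unname(tools::md5sum(file.path(root, "manifest.csv"))),
                   unname(md5_a))
  expect_error(read_image_set(file.path(root, "nope")), "manifest")
})

test_that("grayscale pixels survive PNG round trips within 8-bit precision", {
  root <- file.path(withr::local_tempdir(), "gs")
  cfg <- synthetic_config(n_per_class = 1, seed = 6, image_side = 32)
  imgs <- gen_superordinate_set(cfg)
  write_image_set(imgs, root)
  back <- read_image_set(root)
  expect_lt(max(abs(back[[1]]$pixels - imgs[[1]]$pixels)), 1 / 255)
})
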
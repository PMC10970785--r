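test_that("component-count rules follow the one-fifth and classes-minus-one conventions", {
  expect_equal(max_pca_components(100, 9000, 3), 20)
  expect_equal(max_pca_components(10, 4, 3), 2)
  expect_equal(max_pca_components(12, 9000, 10), 2)   # df cap
  expect_equal(max_pca_components(6, 9000, 2), 1)     # never below 1
  expect_error(max_pca_components(3, 10, 3), "more events")

  expect_equal(ld_dimensions(3), 2L)
  expect_equal(ld_dimensions(2), 1L)
  expect_error(ld_dimensions(1), "2 classes")
})

test_that("a single-bin signal dominates the discriminant and separates training", {
  d <- one_bin_signal()
  m <- pcalda(d$x, d$labels, n_pc = 10)
  expect_equal(loading_ranks(m)$bin[1], 7)
  ld <- project_ld(m, d$x)
  a <- ld[d$labels == "a", 1]
  b <- ld[d$labels == "b", 1]
  expect_true(max(b) < min(a) || max(a) < min(b))
})

test_that("projecting the training set reproduces the class centroids", {
  ds <- tiny_dataset(seed = 2, n_classes = 3)
  fp <- preprocess_dataset(ds)
  m <- pcalda(fp$x, fp$manifest$class_label)
  ld <- project_ld(m, fp$x)
  for (cl in m$class_labels) {
    expect_equal(colMeans(ld[fp$manifest$class_label == cl, , drop = FALSE]),
                 m$class_centroids[cl, ], tolerance = 1e-10,
                 ignore_attr = TRUE)
  }
})

test_that("LD axes match a dense generalized-eigenvector oracle and MASS::lda", {
  set.seed(5)
  for (trial in 1:10) {
    n <- sample(30:50, 1)
    p <- sample(4:6, 1)
    x <- matrix(rnorm(2 * n * p), ncol = p)
    x[seq_len(n), 1] <- x[seq_len(n), 1] + 2
    labels <- rep(c("a", "b"), each = n)
    m <- pcalda(x, labels, n_pc = p)
    w <- m$pca_loadings %*% m$ld_axes
    w <- w / sqrt(sum(w^2))
    w_bf <- bf_lda_direction(x, labels, n_pc = p)
    expect_lt(max(abs(w - align_sign(w, w_bf))), 1e-8)
  }
  # cross-check against MASS's own LDA scaling direction
  d <- one_bin_signal(n_per_class = 40, n_bins = 6, signal_bin = 3)
  m <- pcalda(d$x, d$labels, n_pc = 6)
  w <- m$pca_loadings %*% m$ld_axes
  w <- w / sqrt(sum(w^2))
  sc <- MASS::lda(d$x, grouping = d$labels)$scaling[, 1]
  sc <- sc / sqrt(sum(sc^2))
  expect_lt(max(abs(w - align_sign(w, sc))), 1e-6)
})

test_that("fit rejects degenerate designs and caps the component count", {
  d <- one_bin_signal(n_per_class = 10, n_bins = 5, signal_bin = 3)
  expect_error(pcalda(d$x, rep("a", 20)), "2 classes")
  expect_error(pcalda(d$x, c("a", rep("b", 19))), ">= 2 events")
  m <- pcalda(d$x, d$labels, n_pc = 50)   # above every cap
  expect_lte(m$n_pc, 5)
})

test_that("scree fractions are nonincreasing, bounded, and reflect structure", {
  # points on a line
  set.seed(8)
  t <- rnorm(100)
  line <- outer(t, c(1, 2, -1)) + matrix(rnorm(300, sd = 1e-3), ncol = 3)
  lab <- rep(c("a", "b"), 50)
  m <- pcalda(line, lab, n_pc = 3)
  s <- scree(m)
  expect_gt(s[1], 0.99)
  expect_true(all(diff(s) <= 1e-12))
  expect_lte(sum(s), 1 + 1e-9)

  # isotropic noise: roughly equal fractions
  iso <- matrix(rnorm(2000 * 5), ncol = 5)
  mi <- pcalda(iso, rep(c("a", "b"), 1000), n_pc = 5)
  si <- scree(mi)
  expect_lt(max(abs(si - 0.2)) / 0.2, 0.10)
})

test_that("loading ranks are permutation-equivariant and tie-break by bin index", {
  d <- one_bin_signal(n_per_class = 25, n_bins = 9)
  m1 <- pcalda(d$x, d$labels, n_pc = 9)
  perm <- c(4, 9, 1, 7, 2, 8, 3, 6, 5)
  m2 <- pcalda(d$x[, perm], d$labels, n_pc = 9)
  r1 <- loading_ranks(m1)
  r2 <- loading_ranks(m2)
  # bin b in the original equals position match(b, perm) in the permuted fit
  expect_equal(match(r1$bin, perm), r2$bin)
  expect_equal(r1$importance, r2$importance, tolerance = 1e-9)

  fake <- structure(list(pca_loadings = diag(4)[, 1:2], ld_axes = diag(2),
                         bins = 1:4),
                    class = "pcalda")
  expect_equal(loading_ranks(fake)$bin, c(1, 2, 3, 4))
})

test_that("retained principal components preserve pairwise distances at full rank", {
  set.seed(11)
  x <- matrix(rnorm(40 * 6), ncol = 6)
  lab <- rep(c("a", "b"), 20)
  m <- pcalda(x, lab, n_pc = 6)
  xc <- sweep(x, 2, m$global_mean)
  scores <- xc %*% m$pca_loadings
  expect_equal(as.matrix(dist(scores)), as.matrix(dist(xc)),
               tolerance = 1e-9)
})

test_that("near-saturated component counts separate even unstructured labels", {
  set.seed(21)
  x <- matrix(rnorm(40 * 50), ncol = 50)     # no class signal at all
  lab <- rep(c("a", "b"), each = 20)
  m <- pcalda(x, lab, n_pc = 38)
  pred <- predict(m, x, threshold = 0, outlier_quantile = 1)
  expect_gt(mean(pred$predicted_class == lab), 0.95)
})

test_that("models survive a JSON round trip losslessly", {
  ds <- tiny_dataset(seed = 6, n_classes = 3)
  fp <- preprocess_dataset(ds)
  m <- pcalda(fp$x, fp$manifest$class_label)
  path <- withr::local_tempfile(fileext = ".json")
  write_pcalda(m, path)
  m2 <- read_pcalda(path)
  expect_equal(m2$pca_loadings, m$pca_loadings, tolerance = 1e-14,
               ignore_attr = TRUE)
  expect_equal(m2$ld_axes, m$ld_axes, tolerance = 1e-14, ignore_attr = TRUE)
  expect_equal(m2$class_centroids, m$class_centroids, tolerance = 1e-14)
  expect_equal(m2$class_covariances, m$class_covariances, tolerance = 1e-14)
  p1 <- predict(m, fp$x)
  p2 <- predict(m2, fp$x)
  expect_equal(p1$predicted_class, p2$predicted_class)
})
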
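test_that("squared Mahalanobis distance matches hand values and stats::mahalanobis", {
  expect_equal(mahalanobis_sq(c(1, 2), c(1, 2), diag(2)), 0)
  expect_equal(mahalanobis_sq(c(3, 4), c(0, 0), diag(2)), 25)  # identity = Euclidean^2
  expect_equal(mahalanobis_sq(c(1, 0), c(0, 0), diag(2, 2)), 0.5)

  set.seed(3)
  for (i in 1:25) {
    p <- sample(2:5, 1)
    A <- matrix(rnorm(p * p), p)
    S <- crossprod(A) + diag(p)
    x <- rnorm(p)
    mu <- rnorm(p)
    expect_lt(abs(mahalanobis_sq(x, mu, S) -
                  stats::mahalanobis(x, mu, S)), 1e-8)
  }
  expect_error(mahalanobis_sq(c(1, 1), c(0, 0), matrix(c(1, 2, 2, 1), 2)),
               "positive-definite")
})

test_that("class posteriors follow the Gaussian-kernel closed form", {
  expect_equal(unname(class_posteriors(c(a = 1, b = 1))), c(0.5, 0.5))
  p <- class_posteriors(c(a = 0, b = 500))
  expect_gt(p[1], 1 - 1e-12)

  p2 <- class_posteriors(c(a = 1, b = 4))
  expect_equal(unname(p2[1]), exp(-0.5) / (exp(-0.5) + exp(-2)),
               tolerance = 1e-12)

  # log-space normalization: no underflow, shift invariance for equal covs
  big <- class_posteriors(c(a = 4000, b = 4006))
  expect_equal(sum(big), 1, tolerance = 1e-12)
  expect_equal(unname(big), unname(class_posteriors(c(a = 0, b = 6))),
               tolerance = 1e-10)
  expect_error(class_posteriors(c(a = 1)), "2 classes")
  expect_error(class_posteriors(c(a = 1, b = 2), priors = c(0.7, 0.6)),
               "priors")
})

test_that("prediction assigns classified / unclassifiable / outlier statuses", {
  set.seed(17)
  n <- 60
  x <- rbind(matrix(rnorm(n * 4), ncol = 4),
             matrix(rnorm(n * 4, mean = 2.5), ncol = 4))
  labels <- rep(c("a", "b"), each = n)
  m <- pcalda(x, labels, n_pc = 4)

  # class centroid back-projected is called with posterior ~ 1
  centroid_a <- colMeans(x[labels == "a", ])
  pa <- predict(m, centroid_a)
  expect_equal(pa$status, "classified")
  expect_equal(pa$predicted_class, "a")
  expect_gt(pa$posterior.a, 0.999)

  # midpoint is unclassifiable at a 0.95 threshold
  mid <- (colMeans(x[labels == "a", ]) + colMeans(x[labels == "b", ])) / 2
  pm <- predict(m, mid, threshold = 0.95)
  expect_equal(pm$status, "unclassifiable")
  expect_true(is.na(pm$predicted_class))

  # a point far from every cluster is an outlier with no prediction
  far <- centroid_a + 200
  pf <- predict(m, far)
  expect_equal(pf$status, "outlier")
  expect_true(is.na(pf$predicted_class))
})

test_that("classification statistics separate accuracy from duty cycle", {
  pred <- data.frame(
    event_id = as.character(1:10),
    status = c(rep("classified", 8), "unclassifiable", "outlier"),
    predicted_class = c(rep("a", 6), "b", "b", NA, NA),
    stringsAsFactors = FALSE)
  truth <- c(rep("a", 7), "a", "a", "b")  # 6 of 8 classified are correct
  st <- classification_statistics(pred, truth)
  expect_equal(st$accuracy, 0.75)
  expect_equal(st$duty_cycle, 0.8)
  expect_equal(unname(st$counts["classified"]), 8L, ignore_attr = TRUE)

  none <- pred
  none$status <- "unclassifiable"
  st0 <- classification_statistics(none, truth)
  expect_true(is.na(st0$accuracy))
  expect_equal(st0$duty_cycle, 0)
  expect_error(classification_statistics(pred, truth[1:3]), "length")
})

test_that("raising the threshold never increases the classified fraction", {
  ds <- tiny_dataset(seed = 12, n_classes = 3, class_separation = 2)
  fp <- preprocess_dataset(ds)
  m <- pcalda(fp$x, fp$manifest$class_label)
  fracs <- vapply(c(0, 0.4, 0.6, 0.8, 0.9, 0.95, 0.99, 0.999), function(th) {
    mean(predict(m, fp$x, threshold = th, outlier_quantile = 1)$status ==
           "classified")
  }, numeric(1))
  expect_true(all(diff(fracs) <= 0))
})
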
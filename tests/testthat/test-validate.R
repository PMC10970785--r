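test_that("specimen-aware splits hold out round(f * n) specimens per class, never leaking", {
  ds <- tiny_dataset(seed = 3, n_classes = 3, specimens_per_class = 10,
                     events_per_specimen = 3)
  man <- ds$manifest
  sp <- specimen_split(man$specimen_id, man$class_label, 0.2, seed = 1)
  held <- sp$test_specimens
  per_class <- table(sub("_sp.*", "", held))
  expect_equal(unname(per_class), rep(2L, 3), ignore_attr = TRUE)

  for (s in 1:100) {
    f <- sample(c(0.1, 0.2, 0.3, 0.5), 1)
    spl <- specimen_split(man$specimen_id, man$class_label, f, seed = s)
    expect_length(intersect(man$specimen_id[spl$train],
                            man$specimen_id[spl$test]), 0)
  }
  expect_identical(specimen_split(man$specimen_id, man$class_label, 0.2, 7),
                   specimen_split(man$specimen_id, man$class_label, 0.2, 7))
  expect_false(identical(
    specimen_split(man$specimen_id, man$class_label, 0.2, 7)$test_specimens,
    specimen_split(man$specimen_id, man$class_label, 0.2, 8)$test_specimens))
  one <- c("s1", "s1", "s2")
  expect_error(specimen_split(one, c("a", "a", "b"), 0.5),
               "specimens per class")
})

test_that("mixed-class permutation balances every true class across pseudo-classes", {
  labels <- rep(c("x", "y"), each = 4)
  perm <- permute_labels_mixed(labels, seed = 2)
  tab <- table(true = labels, pseudo = perm)
  expect_true(all(tab == 2))
  expect_setequal(unique(perm), c("x", "y"))

  # composition within one event of equality for uneven counts, any k
  labels3 <- rep(c("a", "b", "c"), times = c(10, 11, 12))
  perm3 <- permute_labels_mixed(labels3, seed = 5)
  tab3 <- table(true = labels3, pseudo = perm3)
  expect_true(all(apply(tab3, 1, function(r) diff(range(r)) <= 1)))
  expect_error(permute_labels_mixed(rep("a", 5)), "2 classes")
})

test_that("pseudo-class split is near-equal, seeded, and guards degenerate k", {
  pl <- pseudo_classes(409, 3, seed = 1)
  expect_equal(sum(table(pl)), 409)
  expect_lte(diff(range(table(pl))), 1)
  expect_identical(pseudo_classes(50, 3, seed = 4), pseudo_classes(50, 3, seed = 4))
  expect_error(pseudo_classes(5, 5), "pseudo-class")
})

test_that("kappa and AUROC match brute-force oracles", {
  cm <- matrix(c(40, 20, 10, 30), 2)
  expect_equal(cohen_kappa(cm), 0.4, tolerance = 1e-12)

  set.seed(31)
  for (i in 1:30) {
    rcm <- matrix(rpois(16, 20), 4)
    expect_lt(abs(cohen_kappa(rcm) - bf_kappa(rcm)), 1e-10)
  }
  expect_error(cohen_kappa(matrix(c(5, 0, 0, 0), 2)), "undefined")

  expect_equal(auroc(c(1, 2, 3, 4), c(FALSE, FALSE, TRUE, TRUE)), 1)
  expect_equal(auroc(rep(1, 10), rep(c(TRUE, FALSE), 5)), 0.5)
  for (i in 1:30) {
    sc <- round(runif(60), 1)   # coarse grid forces ties
    pos <- runif(60) > 0.5
    if (any(pos) && any(!pos)) {
      expect_lt(abs(auroc(sc, pos) - bf_auroc(sc, pos)), 1e-10)
    }
  }
  # independent package cross-check
  sc <- runif(80)
  pos <- runif(80) > 0.4
  expect_equal(auroc(sc, pos),
               as.numeric(pROC::auc(pROC::roc(pos, sc, quiet = TRUE,
                                              direction = "<"))),
               tolerance = 1e-10)
})

test_that("confusion metrics report per-class sensitivity and specificity", {
  cm <- matrix(c(50, 0, 0, 0, 45, 5, 0, 5, 45), 3,
               dimnames = list(truth = letters[1:3], pred = letters[1:3]))
  met <- confusion_metrics(cm)
  expect_equal(unname(met$sensitivity), c(1, 0.9, 0.9))
  expect_equal(unname(met$specificity[1]), 1)
  diagm <- diag(3) * 20
  expect_equal(cohen_kappa(diagm), 1)
  expect_error(confusion_metrics(matrix(0, 2, 2)), "empty")
  expect_error(confusion_metrics(matrix(1, 2, 3)), "square")
})

test_that("per-specimen concordance counts modal agreement among classified calls", {
  pred <- data.frame(
    status = c("classified", "classified", "classified",
               "classified", "unclassifiable", "classified"),
    predicted_class = c("a", "a", "b", "a", NA, "a"),
    stringsAsFactors = FALSE)
  specs <- c("s1", "s1", "s1", "s2", "s2", "s3")
  cc <- concordance(pred, specs)
  expect_equal(unname(cc$per_specimen["s1"]), 2 / 3)
  # s2 has one classified event, s3 one: both excluded from the mean
  expect_true(is.na(cc$per_specimen["s2"]))
  expect_equal(cc$mean, 2 / 3)
})

test_that("cross-validation reports are reproducible and carry coherent accounting", {
  ds <- tiny_dataset(seed = 8, n_classes = 3, specimens_per_class = 4,
                     events_per_specimen = 6, class_separation = 8)
  fp <- preprocess_dataset(ds)
  r1 <- crossvalidate(fp$x, fp$manifest$class_label, fp$manifest$specimen_id,
                      repeats = 3, seed = 21)
  r2 <- crossvalidate(fp$x, fp$manifest$class_label, fp$manifest$specimen_id,
                      repeats = 3, seed = 21)
  expect_identical(r1$confusion_matrix, r2$confusion_matrix)
  expect_identical(r1$accuracy, r2$accuracy)
  expect_equal(sum(r1$confusion_matrix) + r1$unclassified_count,
               r1$n_predictions)
  expect_gt(r1$accuracy, 0.9)
  expect_true(r1$kappa <= 1 && r1$kappa >= -1)
})

test_that("a full-usage learning-curve point equals plain cross-validation", {
  ds <- tiny_dataset(seed = 10, n_classes = 2, specimens_per_class = 5,
                     events_per_specimen = 5)
  fp <- preprocess_dataset(ds)
  lc <- learning_curve(fp$x, fp$manifest$class_label, fp$manifest$specimen_id,
                       usage_fractions = 1.0, repeats = 3, seed = 9)
  cv <- crossvalidate(fp$x, fp$manifest$class_label, fp$manifest$specimen_id,
                      repeats = 3, seed = 9)
  expect_equal(lc$accuracy, cv$accuracy)
  expect_equal(lc$n_pc_cap, max(cv$n_pc_used))
  expect_error(
    learning_curve(fp$x, fp$manifest$class_label, fp$manifest$specimen_id,
                   usage_fractions = 0.1, repeats = 1, seed = 1),
    "specimens")
  expect_error(
    learning_curve(fp$x, fp$manifest$class_label, fp$manifest$specimen_id,
                   pc_rule = "fixed"),
    "n_pc")
})
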
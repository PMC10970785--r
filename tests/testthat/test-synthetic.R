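test_that("generator produces the configured design exactly and reproducibly", {
  cfg <- synthetic_config(n_classes = 3, specimens_per_class = 4,
                          events_per_specimen = 5, n_bins = 40, seed = 7)
  d1 <- generate_dataset(cfg)
  expect_equal(nrow(d1$manifest), 3 * 4 * 5)
  expect_equal(length(unique(d1$manifest$specimen_id)), 12)
  expect_equal(unname(table(d1$manifest$class_label)), rep(20L, 3),
               ignore_attr = TRUE)
  expect_true(all(vapply(d1$scans, function(s) all(s >= 0), logical(1))))
  expect_equal(d1$manifest$n_scans,
               vapply(d1$scans, nrow, integer(1), USE.NAMES = FALSE))

  d2 <- generate_dataset(cfg)
  expect_identical(d1, d2)
  d3 <- generate_dataset(synthetic_config(n_classes = 3,
                                          specimens_per_class = 4,
                                          events_per_specimen = 5,
                                          n_bins = 40, seed = 8))
  expect_false(identical(d1$scans, d3$scans))
})

test_that("invalid configurations are rejected", {
  expect_error(synthetic_config(n_classes = 0), "counts")
  expect_error(synthetic_config(poor_quality_fraction = 1.5), "fractions")
  expect_error(synthetic_config(class_separation = -1), "nonnegative")
  expect_error(synthetic_config(contaminant_bin = 2000), "contaminant_bin")
  expect_error(synthetic_config(contaminant_bin = 5), "contaminant_classes")
  expect_error(scenario_preset("no_such_regime"))
})

test_that("hierarchical variance components are recovered empirically", {
  cfg <- synthetic_config(n_classes = 1, specimens_per_class = 25,
                          events_per_specimen = 25, scans_per_event = 3,
                          n_bins = 150, class_separation = 0,
                          specimen_sd = 2, event_sd = 1, seed = 31)
  ds <- generate_dataset(cfg)
  fp <- preprocess_dataset(ds, normalization = "none")
  spec <- fp$manifest$specimen_id
  # Within-specimen variance per bin, averaged over specimens and bins.
  within <- mean(vapply(split(seq_len(nrow(fp$x)), spec), function(i) {
    mean(apply(fp$x[i, , drop = FALSE], 2, stats::var))
  }, numeric(1)))
  # Between-specimen variance of specimen means (bias-corrected by the
  # within-specimen contribution mean_var / m).
  spec_means <- do.call(rbind, lapply(split(seq_len(nrow(fp$x)), spec),
                                      function(i) colMeans(fp$x[i, , drop = FALSE])))
  between <- mean(apply(spec_means, 2, stats::var)) - within / 25
  expect_lt(abs(within - 1) / 1, 0.1)
  expect_lt(abs(between - 4) / 4, 0.1)
})

test_that("poor-quality fraction is realized within binomial error", {
  cfg <- synthetic_config(n_classes = 2, specimens_per_class = 5,
                          events_per_specimen = 60, scans_per_event = 4,
                          n_bins = 50, poor_quality_fraction = 0.2, seed = 13)
  ds <- generate_dataset(cfg)
  frac <- mean(ds$truth$poor_quality)
  expect_lt(abs(frac - 0.2), 3.5 * sqrt(0.2 * 0.8 / 600))
  # Degraded events violate both default QC rules.
  poor <- which(ds$truth$poor_quality)
  expect_true(all(ds$manifest$n_scans[poor] < 3))
  tics <- vapply(ds$scans[poor], sum, numeric(1))
  expect_true(all(tics <= 1e3))
})

test_that("contaminant feature appears only in the configured classes", {
  ds <- generate_dataset(synthetic_config(
    n_classes = 3, specimens_per_class = 2, events_per_specimen = 6,
    n_bins = 60, contaminant_bin = 10, contaminant_classes = "class2",
    contaminant_intensity = 40, seed = 3))
  fp <- preprocess_dataset(ds, normalization = "none")
  in_cls <- fp$manifest$class_label == "class2"
  expect_gt(mean(fp$x[in_cls, 10]) - mean(fp$x[!in_cls, 10]), 30)
})

test_that("zero class separation removes class structure from the means", {
  ds <- generate_dataset(synthetic_config(n_classes = 3,
                                          specimens_per_class = 2,
                                          events_per_specimen = 3,
                                          n_bins = 50,
                                          class_separation = 0, seed = 5))
  means <- ds$truth$class_means
  expect_equal(means[1, ], means[2, ])
  expect_equal(means[1, ], means[3, ])
})

test_that("scenario presets encode their regimes", {
  d <- scenario_preset("distinct_classes")
  expect_gt(d$class_separation, 5 * d$event_sd)
  p <- scenario_preset("pseudo_class_single_tissue")
  expect_equal(p$n_classes, 1L)
  expect_equal(p$class_separation, 0)
  ct <- scenario_preset("contaminated")
  expect_false(is.null(ct$contaminant_bin))
  expect_equal(ct$contaminant_classes, "class1")
  h <- scenario_preset("heterogeneous")
  expect_gte(h$specimen_sd, h$class_separation / 2)
})

test_that("peak export and CSV round trips reproduce the binned scans", {
  ds <- tiny_dataset(seed = 9)
  pk <- dataset_peaks(ds)
  ev <- ds$manifest$event_id[1]
  rebinned <- vapply(pk[[ev]], function(p) bin_spectrum(p, ds$binning),
                     numeric(ds$binning$n_bins))
  expect_equal(t(rebinned), ds$scans[[ev]], tolerance = 1e-12,
               ignore_attr = TRUE)

  dir <- withr::local_tempdir()
  write_dataset(ds, dir)
  back <- read_dataset(dir)
  expect_equal(back$manifest, ds$manifest)
  expect_equal(back$scans[[ev]], ds$scans[[ev]], tolerance = 1e-12,
               ignore_attr = TRUE)
})
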
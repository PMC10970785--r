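test_that("binning follows the half-open floor convention and sums co-binned peaks", {
  sp <- binning_spec(100, 1000, 0.1)
  v <- bin_spectrum(data.frame(mz = 767.5232, intensity = 100), sp)
  expect_equal(which(v > 0), 6676L)  # 0-based index 6675
  expect_equal(v[6676], 100)

  sp2 <- binning_spec(500, 510, 0.1)
  v2 <- bin_spectrum(data.frame(mz = c(500.01, 500.09), intensity = c(5, 7)), sp2)
  expect_equal(v2[1], 12)
  expect_equal(sum(v2), 12)

  expect_equal(sum(bin_spectrum(data.frame(mz = numeric(0),
                                           intensity = numeric(0)), sp2)), 0)
})

test_that("binning conserves in-range intensity and drops out-of-range peaks", {
  sp <- binning_spec(200, 300, 0.1)
  set.seed(1)
  for (i in 1:20) {
    mz <- runif(50, 150, 350)
    it <- rexp(50)
    v <- bin_spectrum(data.frame(mz = mz, intensity = it), sp)
    in_range <- mz >= 200 & mz < 300
    expect_equal(sum(v), sum(it[in_range]), tolerance = 1e-12)
    expect_equal(attr(v, "dropped"), sum(!in_range))
  }
  expect_error(binning_spec(300, 200), "mz_min")
})

test_that("event aggregation is scan-wise linear", {
  sp <- binning_spec(0, 10, 1)
  scan <- c(0, 3, 0, 2, 0, 0, 0, 1, 0, 0)
  expect_equal(aggregate_event(rbind(scan, scan, scan)), 3 * scan)
  expect_equal(aggregate_event(rbind(scan)), scan)
  disjoint <- rbind(c(1, 0, 0, 0, 0, 0, 0, 0, 0, 0),
                    c(0, 0, 5, 0, 0, 0, 0, 0, 0, 0))
  expect_equal(aggregate_event(disjoint), colSums(disjoint))
  expect_error(aggregate_event(matrix(0, 0, 10)), "no scans")
  # peak-list scans are binned first
  pk <- list(data.frame(mz = 1.5, intensity = 2),
             data.frame(mz = 1.7, intensity = 3))
  expect_equal(aggregate_event(pk, sp)[2], 5)
})

test_that("QC fails short or weak events with the exact reasons", {
  crit <- qc_criteria()
  ok <- list(n_scans = 3, scans = NULL)
  strong <- rep(500, 10)   # TIC 5000
  expect_equal(qc_filter(ok, strong, crit),
               list(status = "pass", reasons = character(0)))

  short <- list(n_scans = 2, scans = NULL)
  expect_equal(qc_filter(short, strong, crit)$reasons, "min_scans")

  weak <- rep(50, 10)      # TIC 500
  expect_equal(qc_filter(ok, weak, crit)$reasons, "min_total_intensity")
  expect_setequal(qc_filter(short, weak, crit)$reasons,
                  c("min_scans", "min_total_intensity"))

  # boundary: the floor is strict (TIC must exceed it)
  expect_equal(qc_filter(ok, rep(100, 10), crit)$reasons,
               "min_total_intensity")

  crit2 <- qc_criteria(required_bins = c(1, 4))
  gap <- strong; gap[4] <- 0
  expect_equal(qc_filter(ok, gap, crit2)$reasons, "required_bins")
})

test_that("QC is label-blind and runs on raw pre-normalization intensities", {
  ds <- tiny_dataset(seed = 4, poor_quality_fraction = 0.3)
  fp1 <- preprocess_dataset(ds)
  shuffled <- ds
  set.seed(99)
  shuffled$manifest$class_label <- sample(shuffled$manifest$class_label)
  fp2 <- preprocess_dataset(shuffled)
  expect_identical(fp1$qc_log$status, fp2$qc_log$status)
  expect_identical(fp1$qc_log$reasons, fp2$qc_log$reasons)
  # TIC-normalized rows sum to 1, yet they passed the raw 10^3 floor
  expect_true(all(abs(rowSums(fp1$x) - 1) < 1e-9))
  expect_true(all(rowSums(fp1$raw) > 1e3))
})

test_that("normalization methods match their definitions", {
  expect_equal(normalize_spectrum(c(2, 3, 5), "tic"), c(0.2, 0.3, 0.5))
  expect_equal(normalize_spectrum(c(0, 2, 4), "nonzero_median"),
               c(0, 2 / 3, 4 / 3))
  ref <- c(1, 2, 3)
  expect_equal(normalize_spectrum(ref, "median_fold_change", reference = ref),
               log(ref + 1e-9))
  expect_error(normalize_spectrum(c(0, 0), "tic"), "all-zero")
  expect_error(normalize_spectrum(c(1, 2), "median_fold_change"), "reference")
  # tic idempotence
  v <- runif(20)
  expect_equal(normalize_spectrum(normalize_spectrum(v, "tic"), "tic"),
               normalize_spectrum(v, "tic"), tolerance = 1e-12)
})

test_that("replicate similarity matches hand-computed cosine and CV", {
  r <- rbind(c(1, 1), c(1, 3))
  sim <- replicate_similarity(r)
  expect_equal(sim$cosine, 4 / (sqrt(2) * sqrt(10)), tolerance = 1e-12)

  same <- rbind(c(1, 2, 3), c(1, 2, 3), c(1, 2, 3))
  s2 <- replicate_similarity(same)
  expect_equal(s2$cosine, 1)
  expect_equal(s2$cv, 0)

  ortho <- rbind(c(1, 0), c(0, 1))
  expect_equal(replicate_similarity(ortho)$cosine, 0)
  expect_error(replicate_similarity(rbind(c(1, 2))), "2 replicates")
})
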
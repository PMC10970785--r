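#' m/z binning specification
#'
#' Fixed-width, half-open, left-closed bins anchored at `mz_min`:
#' bin index of a peak is `floor((mz - mz_min) / bin_width)` (0-based
#' internally; reported 1-based in R). The 100 mDa default is the window
#' generally sufficient for time-of-flight ambient-MS fingerprints, where
#' binning also absorbs mass drift that would otherwise need lock-mass
#' correction.
#'
#' @param mz_min,mz_max m/z range covered (`mz_min < mz_max`); peaks at or
#'   above `mz_max` are out of range.
#' @param bin_width Bin width in m/z units (default 0.1 = 100 mDa).
#' @return An object of class `binning_spec` with `n_bins =
#'   ceiling((mz_max - mz_min) / bin_width)`.
#' @export
binning_spec <- function(mz_min = 100, mz_max = 1000, bin_width = 0.1) {
  if (!(mz_min < mz_max)) stop("mz_min must be < mz_max", call. = FALSE)
  if (bin_width <= 0) stop("bin_width must be positive", call. = FALSE)
  n_bins <- as.integer(ceiling((mz_max - mz_min) / bin_width - 1e-9))
  structure(list(mz_min = mz_min, mz_max = mz_max, bin_width = bin_width,
                 n_bins = n_bins),
            class = "binning_spec")
}

bin_centers <- function(spec) {
  spec$mz_min + (seq_len(spec$n_bins) - 0.5) * spec$bin_width
}

#' Bin a peak list into a fixed-width fingerprint
#'
#' Sums intensities of co-binned peaks; out-of-range peaks are dropped (their
#' count is recorded in the `dropped` attribute), so total in-range intensity
#' is conserved exactly.
#'
#' @param peaks data.frame (or matrix) with columns `mz`, `intensity`, or a
#'   two-column matrix.
#' @param spec A [binning_spec()].
#' @return Numeric vector of length `spec$n_bins` with attribute `dropped`
#'   (number of out-of-range peaks).
#' @examples
#' sp <- binning_spec(100, 1000, 0.1)
#' v <- bin_spectrum(data.frame(mz = 767.5232, intensity = 100), sp)
#' which(v > 0)  # bin 6676 (1-based; floor((767.5232-100)/0.1) = 6675)
#' @export
bin_spectrum <- function(peaks, spec) {
  stopifnot(inherits(spec, "binning_spec"))
  if (is.matrix(peaks)) peaks <- data.frame(mz = peaks[, 1], intensity = peaks[, 2])
  out <- numeric(spec$n_bins)
  if (is.null(peaks) || nrow(peaks) == 0) {
    attr(out, "dropped") <- 0L
    return(out)
  }
  if (any(peaks$intensity < 0)) stop("negative intensities", call. = FALSE)
  idx0 <- floor((peaks$mz - spec$mz_min) / spec$bin_width)
  ok <- idx0 >= 0 & idx0 < spec$n_bins
  tab <- tapply(peaks$intensity[ok], idx0[ok], sum)
  out[as.integer(names(tab)) + 1L] <- as.numeric(tab)
  attr(out, "dropped") <- sum(!ok)
  out
}

#' Aggregate an event's scans into one fingerprint
#'
#' Sums scans bin-wise so that each sampling event contributes a single data
#' point to downstream modeling. Scans may be dense bin vectors (a matrix of
#' `n_scans x n_bins`) or per-peak data.frames, which are binned first.
#'
#' @param event Either an `event_dataset` element context — a list with a
#'   `scans` matrix — or directly a matrix / list of peak data.frames.
#' @param spec A [binning_spec()]; required for peak-list scans.
#' @return Numeric vector of length `n_bins`.
#' @export
aggregate_event <- function(event, spec = NULL) {
  scans <- if (is.list(event) && !is.null(event$scans)) event$scans else event
  if (is.matrix(scans)) {
    if (nrow(scans) < 1) stop("event has no scans", call. = FALSE)
    return(colSums(scans))
  }
  if (is.data.frame(scans)) scans <- list(scans)
  if (length(scans) < 1) stop("event has no scans", call. = FALSE)
  if (is.null(spec)) stop("binning_spec required for peak-list scans", call. = FALSE)
  binned <- vapply(scans, function(pk) bin_spectrum(pk, spec),
                   numeric(spec$n_bins))
  rowSums(binned)
}

#' Quality-control criteria for sampling events
#'
#' Defaults encode the minimal-signal rule used for soft-tissue ambient-MS
#' work: at least three 1-s scans and a raw (pre-normalization) total ion
#' intensity above 10^3 counts. Optional criteria: required non-zero bins,
#' a replicate cosine-similarity floor and a replicate CV ceiling.
#'
#' @param min_scans Minimum scans per event (default 3).
#' @param min_total_intensity Raw event TIC floor (default 1e3); events with
#'   TIC at or below this fail.
#' @param required_bins Optional integer vector of 1-based bins that must be
#'   non-zero.
#' @param min_cosine Optional floor on mean pairwise replicate cosine.
#' @param max_cv Optional ceiling on the median per-bin replicate CV.
#' @return Object of class `qc_criteria`.
#' @export
qc_criteria <- function(min_scans = 3, min_total_intensity = 1e3,
                        required_bins = NULL, min_cosine = NULL,
                        max_cv = NULL) {
  if (min_scans < 1) stop("min_scans must be >= 1", call. = FALSE)
  if (min_total_intensity < 0) stop("min_total_intensity must be >= 0", call. = FALSE)
  if (!is.null(min_cosine) && (min_cosine < 0 || min_cosine > 1)) {
    stop("min_cosine must lie in [0, 1]", call. = FALSE)
  }
  structure(list(min_scans = as.integer(min_scans),
                 min_total_intensity = min_total_intensity,
                 required_bins = required_bins,
                 min_cosine = min_cosine, max_cv = max_cv),
            class = "qc_criteria")
}

#' Apply QC criteria to one sampling event
#'
#' QC is label-blind and operates on raw (pre-normalization) intensities; it
#' never raises on data content, so every collection attempt can be logged
#' for duty-cycle accounting.
#'
#' @param event List with at least `n_scans`; optionally a `scans` matrix
#'   (needed for the replicate-similarity criteria).
#' @param binned Raw binned event fingerprint (from [aggregate_event()]).
#' @param criteria A [qc_criteria()] object.
#' @return List with `status` ("pass"/"fail") and `reasons` (character vector
#'   of violated criteria codes: "min_scans", "min_total_intensity",
#'   "required_bins", "min_cosine", "max_cv").
#' @export
qc_filter <- function(event, binned, criteria = qc_criteria()) {
  stopifnot(inherits(criteria, "qc_criteria"))
  reasons <- character(0)
  n_scans <- event$n_scans %||% (if (is.matrix(event$scans)) nrow(event$scans) else NA)
  if (!is.na(n_scans) && n_scans < criteria$min_scans) {
    reasons <- c(reasons, "min_scans")
  }
  if (sum(binned) <= criteria$min_total_intensity) {
    reasons <- c(reasons, "min_total_intensity")
  }
  if (!is.null(criteria$required_bins) &&
      any(binned[criteria$required_bins] == 0)) {
    reasons <- c(reasons, "required_bins")
  }
  if ((!is.null(criteria$min_cosine) || !is.null(criteria$max_cv)) &&
      is.matrix(event$scans) && nrow(event$scans) >= 2) {
    sim <- replicate_similarity(event$scans)
    if (!is.null(criteria$min_cosine) && sim$cosine < criteria$min_cosine) {
      reasons <- c(reasons, "min_cosine")
    }
    if (!is.null(criteria$max_cv) && !is.na(sim$cv) && sim$cv > criteria$max_cv) {
      reasons <- c(reasons, "max_cv")
    }
  }
  list(status = if (length(reasons)) "fail" else "pass", reasons = reasons)
}

#' Normalize a binned spectrum
#'
#' @param values Nonnegative numeric vector (one binned spectrum).
#' @param method One of `"tic"` (divide by total intensity; result sums to 1),
#'   `"nonzero_median"` (divide by the median of strictly positive bins), or
#'   `"median_fold_change"` (divide by the median ratio to a reference
#'   spectrum over bins positive in both, then `log(value + eps)`).
#' @param reference Reference spectrum (typically the dataset median
#'   spectrum); required for `"median_fold_change"`.
#' @param eps Pseudocount used inside the log transform (default 1e-9).
#' @return Normalized numeric vector.
#' @examples
#' normalize_spectrum(c(2, 3, 5), "tic")            # 0.2 0.3 0.5
#' normalize_spectrum(c(0, 2, 4), "nonzero_median") # 0 2/3 4/3
#' @export
normalize_spectrum <- function(values,
                               method = c("tic", "nonzero_median",
                                          "median_fold_change", "none"),
                               reference = NULL, eps = 1e-9) {
  method <- match.arg(method)
  if (method == "none") return(values)
  if (method == "median_fold_change") {
    if (is.null(reference)) {
      stop("median_fold_change requires a reference spectrum", call. = FALSE)
    }
    both <- values > 0 & reference > 0
    fold <- if (any(both)) stats::median(values[both] / reference[both]) else 1
    if (fold <= 0) fold <- 1
    return(log(values / fold + eps))
  }
  denom <- switch(method,
    tic = sum(values),
    nonzero_median = stats::median(values[values > 0]))
  if (!length(denom) || is.na(denom) || denom <= 0) {
    stop("cannot normalize an all-zero spectrum", call. = FALSE)
  }
  values / denom
}

#' Replicate similarity: mean pairwise cosine and per-bin CV
#'
#' @param replicates Matrix (rows = replicate spectra) or list of vectors.
#' @return List with `cosine` (mean pairwise cosine over all replicate
#'   pairs), `cv` (median per-bin coefficient of variation over bins with
#'   non-zero mean) and `per_bin_cv`.
#' @export
replicate_similarity <- function(replicates) {
  if (is.list(replicates) && !is.matrix(replicates)) {
    replicates <- do.call(rbind, replicates)
  }
  if (nrow(replicates) < 2) stop("need >= 2 replicates", call. = FALSE)
  n <- nrow(replicates)
  norms <- sqrt(rowSums(replicates^2))
  cos_sum <- 0
  npair <- 0L
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      denom <- norms[i] * norms[j]
      cos_sum <- cos_sum + if (denom > 0) {
        sum(replicates[i, ] * replicates[j, ]) / denom
      } else 0
      npair <- npair + 1L
    }
  }
  mu <- colMeans(replicates)
  sdv <- apply(replicates, 2, stats::sd)
  per_bin <- ifelse(mu > 0, sdv / mu, NA_real_)
  cv <- if (any(mu > 0)) stats::median(per_bin[mu > 0]) else NA_real_
  list(cosine = cos_sum / npair, cv = cv, per_bin_cv = per_bin)
}

#' Preprocess a dataset into a QC-filtered, normalized fingerprint matrix
#'
#' Runs the data-quality checkpoint stage: aggregates each event's scans,
#' applies QC on raw intensities, logs every attempt, and normalizes the
#' passing fingerprints.
#'
#' @param dataset An `event_dataset` (from [generate_dataset()] or
#'   [read_dataset()]).
#' @param qc A [qc_criteria()] object.
#' @param normalization Normalization method (see [normalize_spectrum()]).
#' @return Object of class `fingerprints`: list with
#'   \describe{
#'     \item{x}{normalized matrix, QC-passing events x bins.}
#'     \item{raw}{raw aggregated matrix for the same events.}
#'     \item{manifest}{manifest rows of passing events.}
#'     \item{qc_log}{data.frame(event_id, status, reasons) for every attempt.}
#'     \item{duty_cycle_qc}{passing / attempted events.}
#'     \item{binning, normalization}{metadata.}
#'   }
#' @export
preprocess_dataset <- function(dataset, qc = qc_criteria(),
                               normalization = "tic") {
  stopifnot(inherits(dataset, "event_dataset"))
  n <- nrow(dataset$manifest)
  p <- dataset$binning$n_bins
  raw <- matrix(0, nrow = n, ncol = p,
                dimnames = list(dataset$manifest$event_id, NULL))
  status <- character(n)
  reasons <- character(n)
  for (i in seq_len(n)) {
    ev <- list(n_scans = dataset$manifest$n_scans[i],
               scans = dataset$scans[[dataset$manifest$event_id[i]]])
    raw[i, ] <- aggregate_event(ev$scans, dataset$binning)
    res <- qc_filter(ev, raw[i, ], qc)
    status[i] <- res$status
    reasons[i] <- paste(res$reasons, collapse = ";")
  }
  qc_log <- data.frame(event_id = dataset$manifest$event_id,
                       status = status, reasons = reasons,
                       stringsAsFactors = FALSE)
  keep <- status == "pass"
  x <- raw[keep, , drop = FALSE]
  if (normalization == "median_fold_change") {
    ref <- apply(x, 2, stats::median)
    x <- t(apply(x, 1, normalize_spectrum, method = normalization,
                 reference = ref))
  } else if (normalization != "none") {
    x <- t(apply(x, 1, normalize_spectrum, method = normalization))
  }
  structure(list(x = x, raw = raw[keep, , drop = FALSE],
                 manifest = dataset$manifest[keep, , drop = FALSE],
                 qc_log = qc_log,
                 duty_cycle_qc = mean(keep),
                 binning = dataset$binning,
                 normalization = normalization),
            class = "fingerprints")
}

#' @export
print.fingerprints <- function(x, ...) {
  cat(sprintf("Fingerprint matrix: %d events x %d bins (%s-normalized)\n",
              nrow(x$x), ncol(x$x), x$normalization))
  cat(sprintf("  QC pass rate: %.3f (%d of %d attempts)\n", x$duty_cycle_qc,
              nrow(x$x), nrow(x$qc_log)))
  invisible(x)
}

#' Read sampling events from an mzML file
#'
#' Maps each spectrum in the file to one 1-s scan of a single sampling event.
#' Requires the `mzR` package.
#'
#' @param path Path to an mzML file.
#' @param spec A [binning_spec()].
#' @param event_id Identifier for the resulting event.
#' @return A one-event `event_dataset`.
#' @export
read_mzml_event <- function(path, spec, event_id = basename(path)) {
  if (!requireNamespace("mzR", quietly = TRUE)) {
    stop("the mzR package is required to read mzML files", call. = FALSE)
  }
  handle <- mzR::openMSfile(path)
  on.exit(mzR::close(handle))
  pk <- mzR::peaks(handle)
  if (is.matrix(pk)) pk <- list(pk)
  scans <- do.call(rbind, lapply(pk, function(m) bin_spectrum(m, spec)))
  manifest <- data.frame(event_id = event_id, specimen_id = event_id,
                         class_label = NA_character_, n_scans = nrow(scans),
                         location_tag = "", stringsAsFactors = FALSE)
  structure(list(manifest = manifest,
                 scans = stats::setNames(list(scans), event_id),
                 binning = spec, truth = NULL),
            class = "event_dataset")
}
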
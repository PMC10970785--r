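#' Top class-discriminating features of a fitted model
#'
#' The loading-plot shortlist: the `n` bins with the largest composite
#' projection weight (see [loading_ranks()]), the starting point for ion
#' identification and sparse re-modeling.
#'
#' @param model A fitted [pcalda()] model.
#' @param n Number of features to keep (default 100).
#' @param binning Optional [binning_spec()]; when given, a
#'   `representative_mz` column (bin-centre m/z) is added.
#' @return data.frame with `bin`, `importance`, `rank` (and optionally
#'   `representative_mz`), deterministic given the model (ties broken by
#'   ascending bin index).
#' @export
select_top_features <- function(model, n = 100, binning = NULL) {
  ranks <- loading_ranks(model)
  if (n > nrow(ranks)) {
    stop("n exceeds the number of bins in the model", call. = FALSE)
  }
  out <- ranks[seq_len(n), , drop = FALSE]
  out$rank <- seq_len(n)
  if (!is.null(binning)) {
    out$representative_mz <- bin_centers(binning)[out$bin]
  }
  rownames(out) <- NULL
  out
}

#' Feature annotation table
#'
#' Records the identification status of candidate features. Identification
#' itself (MS/MS, database lookup) happens offline; this table is its input
#' form. A `flagged_artifact` feature — e.g. an ion traced to an exogenous
#' agent rather than tissue biology — is never retained in a sparse model.
#'
#' @param bin_index Integer bin indices.
#' @param status One of `"identified_biological"`, `"unidentified"`,
#'   `"flagged_artifact"` per bin.
#' @param representative_mz Optional m/z per bin.
#' @param note Optional free-text note per bin.
#' @return data.frame of class `feature_annotations`.
#' @export
feature_annotations <- function(bin_index, status,
                                representative_mz = NA_real_,
                                note = "") {
  status <- match.arg(status,
                      c("identified_biological", "unidentified",
                        "flagged_artifact"),
                      several.ok = TRUE)
  out <- data.frame(bin_index = as.integer(bin_index),
                    representative_mz = representative_mz,
                    status = rep(status, length.out = length(bin_index)),
                    note = rep(note, length.out = length(bin_index)),
                    stringsAsFactors = FALSE)
  class(out) <- c("feature_annotations", class(out))
  out
}

#' Filter a feature shortlist through its annotations
#'
#' @param features data.frame from [select_top_features()] (needs a `bin`
#'   column).
#' @param annotations A [feature_annotations()] table; unannotated bins are
#'   treated as `"unidentified"`.
#' @param keep `"all_unflagged"` (drop only `flagged_artifact`; default) or
#'   `"identified_only"` (keep only `identified_biological`).
#' @param n_bins Optional total bin count for validating annotation indices.
#' @return The retained subset of `features`, order preserved.
#' @export
apply_annotations <- function(features, annotations,
                              keep = c("all_unflagged", "identified_only"),
                              n_bins = NULL) {
  keep <- match.arg(keep)
  if (!is.null(n_bins) && any(annotations$bin_index > n_bins |
                              annotations$bin_index < 1)) {
    stop("annotation refers to an unknown bin", call. = FALSE)
  }
  status <- annotations$status[match(features$bin, annotations$bin_index)]
  status[is.na(status)] <- "unidentified"
  mask <- if (keep == "identified_only") {
    status == "identified_biological"
  } else {
    status != "flagged_artifact"
  }
  features[mask, , drop = FALSE]
}

#' Refit a PCA-LDA model on a retained feature set
#'
#' Sparse m/z analysis: the identical pipeline restricted to the retained
#' bins, with the PC cap re-derived from the reduced dimensionality. The
#' returned model remembers its bin subset, so [predict.pcalda()] accepts
#' full-width fingerprint matrices.
#'
#' @param x Full fingerprint matrix (events x all bins).
#' @param labels Class label per event.
#' @param bins Integer indices of retained bins (>= 2).
#' @param n_pc Optional PC count; defaults to the one-fifth rule on the
#'   reduced matrix.
#' @param ... Further arguments passed to [pcalda()].
#' @return A `pcalda` model whose `bins` element holds the retained
#'   indices.
#' @export
fit_sparse <- function(x, labels, bins, n_pc = NULL, ...) {
  bins <- sort(unique(as.integer(bins)))
  if (length(bins) < 2) stop("need >= 2 retained features", call. = FALSE)
  x <- as.matrix(x)
  if (any(bins < 1 | bins > ncol(x))) {
    stop("retained bins outside the fingerprint width", call. = FALSE)
  }
  model <- pcalda(x[, bins, drop = FALSE], labels, n_pc = n_pc, ...)
  model$bins <- bins
  model
}
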
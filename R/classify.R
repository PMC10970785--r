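#' Squared Mahalanobis distance
#'
#' `(x - centroid)' Sigma^-1 (x - centroid)` for a positive-definite
#' covariance.
#'
#' @param x Numeric vector (a point in LD space).
#' @param centroid Class centroid.
#' @param covariance Positive-definite covariance matrix.
#' @return Nonnegative scalar.
#' @examples
#' mahalanobis_sq(c(1, 0), c(0, 0), diag(2, 2))  # 0.5
#' @export
mahalanobis_sq <- function(x, centroid, covariance) {
  d <- as.numeric(x - centroid)
  R <- tryCatch(chol(covariance), error = function(e) {
    stop("covariance is not positive-definite", call. = FALSE)
  })
  z <- backsolve(R, d, transpose = TRUE)
  sum(z^2)
}

#' Class posterior probabilities from Mahalanobis distances
#'
#' Gaussian-kernel posteriors: `posterior_k` is proportional to
#' `prior_k * exp(-d2_k / 2) / sqrt(det Sigma_k)`, normalized in log space so
#' that distant points never underflow to an undefined result.
#'
#' @param distances Named numeric vector of per-class squared Mahalanobis
#'   distances.
#' @param priors Per-class prior probabilities (default uniform); must sum
#'   to 1.
#' @param log_dets Per-class log-determinants of the LD-space covariances
#'   (default 0, i.e. equal covariance volumes).
#' @return Posterior probabilities summing to 1.
#' @examples
#' class_posteriors(c(a = 1, b = 4))  # c(0.8176, 0.1824)
#' @export
class_posteriors <- function(distances, priors = NULL, log_dets = NULL) {
  k <- length(distances)
  if (k < 2) stop("need at least 2 classes", call. = FALSE)
  if (is.null(priors)) priors <- rep(1 / k, k)
  if (abs(sum(priors) - 1) > 1e-8) stop("priors must sum to 1", call. = FALSE)
  if (is.null(log_dets)) log_dets <- rep(0, k)
  lk <- log(priors) - distances / 2 - log_dets / 2
  post <- exp(lk - logsumexp(lk))
  post / sum(post)
}

#' Classify fingerprints with a PCA-LDA model
#'
#' Projects each spectrum into LD space, computes per-class squared
#' Mahalanobis distances and Gaussian posteriors, and assigns a status:
#' \describe{
#'   \item{outlier}{minimum distance exceeds the chi-square quantile
#'     `outlier_quantile` (dof = number of LD axes) for every class — the
#'     spectrum resembles none of the competing classes; no prediction.}
#'   \item{classified}{highest posterior reaches `threshold`; the arg-max
#'     class is called (ties broken by ascending class-label order).}
#'   \item{unclassifiable}{otherwise — a low-confidence no-call, excluded
#'     from accuracy but counted against the duty cycle.}
#' }
#'
#' @param object A fitted [pcalda()] model.
#' @param newdata Matrix (events x bins) or single fingerprint vector,
#'   binned identically to the training data.
#' @param threshold Minimum posterior probability for a class call
#'   (default 0.95).
#' @param outlier_quantile Chi-square quantile defining the outlier envelope
#'   (default 0.999).
#' @param priors Optional class priors (default uniform).
#' @param event_id Optional identifiers for the rows of `newdata`.
#' @param ... Unused.
#' @return data.frame of class `class_prediction`: `event_id`, `status`,
#'   `predicted_class`, one `posterior.<class>` and one `d2.<class>` column
#'   per class, and `threshold_used`.
#' @export
predict.pcalda <- function(object, newdata, threshold = 0.95,
                           outlier_quantile = 0.999, priors = NULL,
                           event_id = NULL, ...) {
  ld <- project_ld(object, newdata)
  n <- nrow(ld)
  cls <- object$class_labels
  k <- length(cls)
  if (is.null(event_id)) {
    event_id <- rownames(ld) %||% as.character(seq_len(n))
  }
  log_dets <- vapply(object$class_covariances,
                     function(S) determinant(S, logarithm = TRUE)$modulus[1],
                     numeric(1))
  cutoff <- stats::qchisq(outlier_quantile, df = object$n_ld)

  d2 <- matrix(0, n, k, dimnames = list(NULL, cls))
  for (j in seq_len(k)) {
    S <- object$class_covariances[[j]]
    R <- chol(S)
    dc <- sweep(ld, 2, object$class_centroids[j, ])
    z <- backsolve(R, t(dc), transpose = TRUE)
    d2[, j] <- colSums(z^2)
  }
  post <- matrix(0, n, k, dimnames = list(NULL, cls))
  for (i in seq_len(n)) {
    post[i, ] <- class_posteriors(d2[i, ], priors = priors,
                                  log_dets = log_dets)
  }
  best <- max.col(post, ties.method = "first")
  maxp <- post[cbind(seq_len(n), best)]
  status <- ifelse(apply(d2, 1, min) > cutoff, "outlier",
                   ifelse(maxp >= threshold, "classified", "unclassifiable"))
  predicted <- ifelse(status == "classified", cls[best], NA_character_)

  out <- data.frame(event_id = event_id, status = status,
                    predicted_class = predicted,
                    threshold_used = threshold,
                    stringsAsFactors = FALSE)
  colnames(post) <- paste0("posterior.", cls)
  colnames(d2) <- paste0("d2.", cls)
  out <- cbind(out, as.data.frame(post), as.data.frame(d2))
  class(out) <- c("class_prediction", class(out))
  out
}

#' Posterior and distance matrices from a prediction table
#'
#' @param pred A `class_prediction` data.frame.
#' @return List with `posteriors` and `d2` matrices (events x classes).
#' @export
prediction_scores <- function(pred) {
  pc <- grep("^posterior\\.", names(pred), value = TRUE)
  dc <- grep("^d2\\.", names(pred), value = TRUE)
  list(posteriors = as.matrix(pred[, pc, drop = FALSE]),
       d2 = as.matrix(pred[, dc, drop = FALSE]))
}

#' Accuracy-over-classified and duty-cycle accounting
#'
#' No decision is made for unclassifiable or outlier events, so they are
#' excluded from accuracy but retained in the duty cycle — the fraction of
#' attempts that produced a class call.
#'
#' @param predictions A `class_prediction` data.frame.
#' @param truth True class label per event.
#' @return List with `accuracy` (correct / classified; `NA` when nothing was
#'   classified), `duty_cycle` (classified / total), and `counts` (by
#'   status).
#' @export
classification_statistics <- function(predictions, truth) {
  if (nrow(predictions) != length(truth)) {
    stop("predictions and truth differ in length", call. = FALSE)
  }
  classified <- predictions$status == "classified"
  n_cls <- sum(classified)
  acc <- if (n_cls > 0) {
    mean(predictions$predicted_class[classified] ==
           as.character(truth)[classified])
  } else NA_real_
  counts <- table(factor(predictions$status,
                         levels = c("classified", "unclassifiable", "outlier")))
  list(accuracy = acc,
       duty_cycle = n_cls / nrow(predictions),
       counts = counts)
}
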
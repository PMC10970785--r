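#' Specimen-aware train/test split
#'
#' Splits at the specimen level, stratified by class, so that no data points
#' from the same specimen populate both the training and the test side —
#' the safeguard against optimism when a model contains dependent events
#' from the same specimen. Per class, `round(fraction * specimens-in-class)`
#' specimens (at least 1) are held out.
#'
#' @param specimens Specimen id per event.
#' @param labels Class label per event.
#' @param fraction Held-out fraction of specimens per class (0 < f < 1).
#' @param seed Integer seed; identical seeds give identical splits.
#' @return List with integer event indices `train` and `test`, plus
#'   `test_specimens`.
#' @export
specimen_split <- function(specimens, labels, fraction = 0.2, seed = 1) {
  if (fraction <= 0 || fraction >= 1) stop("fraction must be in (0,1)", call. = FALSE)
  specimens <- as.character(specimens)
  labels <- as.character(labels)
  # Stratify by each specimen's modal label (for permuted/pseudo labelings a
  # specimen can carry mixed labels; its modal label keeps strata balanced).
  spec_class <- vapply(split(labels, specimens), function(l) {
    names(sort(table(l), decreasing = TRUE))[1]
  }, character(1))
  with_seed(seed, {
    held <- unlist(lapply(split(names(spec_class), spec_class), function(ids) {
      n_hold <- max(1L, round(fraction * length(ids)))
      if (n_hold >= length(ids)) {
        stop("a class would lose all its specimens; need >= 2 specimens per class",
             call. = FALSE)
      }
      sample(ids, n_hold)
    }), use.names = FALSE)
    test <- which(specimens %in% held)
    list(train = setdiff(seq_along(specimens), test), test = test,
         test_specimens = sort(held))
  })
}

# Event-level random split ("leaky": events of one specimen can populate
# both sides). Kept for didactic comparison with the specimen-aware default.
event_split <- function(n, fraction = 0.2, seed = 1) {
  with_seed(seed, {
    test <- sort(sample.int(n, max(1L, round(fraction * n))))
    list(train = setdiff(seq_len(n), test), test = test,
         test_specimens = character(0))
  })
}

#' Mixed-class permuted relabeling
#'
#' Builds the falsely annotated control labeling: each pseudo-class is
#' composed of an equal share (within one event) of events from every true
#' class, so a model fitted to it should show no class discrimination. The
#' event set and spectra are untouched; only labels move.
#'
#' @param labels True class label per event.
#' @param seed Integer seed (shuffling within classes and remainder
#'   assignment are seeded).
#' @param specimens Optional specimen ids; when supplied, all events of a
#'   specimen move together (specimen-blocked variant).
#' @return Character vector of pseudo-class labels (same label set as the
#'   input).
#' @export
permute_labels_mixed <- function(labels, seed = 1, specimens = NULL) {
  labels <- as.character(labels)
  cls <- sort(unique(labels))
  k <- length(cls)
  if (k < 2) stop("need >= 2 classes to permute", call. = FALSE)
  out <- character(length(labels))
  with_seed(seed, {
    if (is.null(specimens)) {
      for (cl in cls) {
        idx <- sample(which(labels == cl))
        # Deal round-robin from a random starting pseudo-class: every
        # pseudo-class receives floor or ceiling of n/k events of class cl.
        start <- sample.int(k, 1)
        assign_to <- cls[((start + seq_along(idx) - 2) %% k) + 1]
        out[idx] <- assign_to
      }
    } else {
      specimens <- as.character(specimens)
      for (cl in cls) {
        ids <- sample(unique(specimens[labels == cl]))
        start <- sample.int(k, 1)
        to <- cls[((start + seq_along(ids) - 2) %% k) + 1]
        for (i in seq_along(ids)) {
          out[specimens == ids[i] & labels == cl] <- to[i]
        }
      }
    }
  })
  out
}

#' Pseudo-class relabeling of a single class
#'
#' Splits one homogeneous class into `k` near-equal pseudo-classes — the
#' "no real structure" chance-level baseline.
#'
#' @param n_events Number of events (or a vector of event ids).
#' @param k Number of pseudo-classes (>= 2).
#' @param seed Integer seed.
#' @return Character vector of pseudo-class labels `pseudo1..pseudok`, sizes
#'   differing by at most 1.
#' @export
pseudo_classes <- function(n_events, k = 3, seed = 1) {
  n <- if (length(n_events) == 1 && is.numeric(n_events)) n_events else length(n_events)
  if (k < 2) stop("k must be >= 2", call. = FALSE)
  if (floor(n / k) < 2) {
    stop("too few events per pseudo-class (each needs >= 2)", call. = FALSE)
  }
  with_seed(seed, {
    lab <- rep(sprintf("pseudo%d", seq_len(k)), length.out = n)
    sample(lab)
  })
}

#' Repeated leave-p-out cross-validation
#'
#' The robustness workhorse: for each repeat, a fresh specimen-aware split
#' (default 20% of specimens per class held out), a PCA-LDA model fitted on
#' the training side under the component-count rule, and prediction of the
#' held-out events. Results are aggregated over repeats into a validation
#' report.
#'
#' @param x Fingerprint matrix (events x bins).
#' @param labels Class label per event.
#' @param specimens Specimen id per event.
#' @param p Held-out fraction (default 0.2).
#' @param repeats Number of repeated splits (default 25).
#' @param n_pc `NULL` for the adaptive one-fifth rule applied to each
#'   training set, or a fixed count.
#' @param threshold Posterior threshold for class calls (default 0: every
#'   non-outlier event is called, so accuracy reflects the raw model).
#' @param outlier_quantile Chi-square outlier envelope (default 1 = no
#'   outlier gating: cross-validation measures the raw model, and when LD
#'   axes are fitted near the component cap the training covariances
#'   understate new-specimen spread, so an absolute envelope would silently
#'   discard valid test events; no-call behavior is studied through
#'   `threshold` and [predict.pcalda()] instead).
#' @param ridge Covariance ridge passed to [pcalda()].
#' @param split_level `"specimen"` (default) or `"event"` — the latter is the
#'   leaky variant in which dependent events of one specimen may populate
#'   both sides; it exists to demonstrate that bias, not for reporting.
#' @param seed Integer seed.
#' @return A `validation_report`: list with `confusion_matrix` (truth x
#'   predicted, classified events only), `unclassified_count`, `accuracy`,
#'   `per_class_sensitivity`, `per_class_specificity`, `kappa`, `auroc_ovr`,
#'   `duty_cycle`, `concordance`, `fold_assignments`, `n_pc_used`,
#'   `n_events_tested`.
#' @export
crossvalidate <- function(x, labels, specimens, p = 0.2, repeats = 25,
                          n_pc = NULL, threshold = 0,
                          outlier_quantile = 1, ridge = 1e-6,
                          split_level = c("specimen", "event"), seed = 1) {
  split_level <- match.arg(split_level)
  x <- as.matrix(x)
  labels <- as.character(labels)
  specimens <- as.character(specimens)
  cls <- sort(unique(labels))
  k <- length(cls)
  counts <- table(labels)
  if (max(counts) > 1.2 * min(counts)) {
    warning("class event counts differ by > 20%; balanced designs are recommended",
            call. = FALSE)
  }

  cm <- matrix(0L, k, k, dimnames = list(truth = cls, predicted = cls))
  unclassified <- 0L
  total <- 0L
  folds <- vector("list", repeats)
  scores <- NULL
  truth_all <- character(0)
  pred_tables <- vector("list", repeats)
  spec_all <- character(0)
  n_pc_used <- integer(repeats)
  tested_events <- character(0)

  for (r in seq_len(repeats)) {
    sd_r <- derive_seed(seed, r)
    sp <- if (split_level == "specimen") {
      specimen_split(specimens, labels, fraction = p, seed = sd_r)
    } else {
      event_split(length(labels), fraction = p, seed = sd_r)
    }
    if (length(unique(labels[sp$train])) < k) {
      stop("a training fold lost a class entirely", call. = FALSE)
    }
    npc_r <- n_pc %||% max_pca_components(length(sp$train), ncol(x), k)
    model <- pcalda(x[sp$train, , drop = FALSE], labels[sp$train],
                    n_pc = npc_r, ridge = ridge)
    pred <- predict(model, x[sp$test, , drop = FALSE],
                    threshold = threshold,
                    outlier_quantile = outlier_quantile,
                    event_id = rownames(x)[sp$test] %||%
                      as.character(sp$test))
    n_pc_used[r] <- model$n_pc

    truth_r <- labels[sp$test]
    cls_mask <- pred$status == "classified"
    if (any(cls_mask)) {
      cm_r <- table(factor(truth_r[cls_mask], levels = cls),
                    factor(pred$predicted_class[cls_mask], levels = cls))
      cm <- cm + as.matrix(cm_r)
    }
    unclassified <- unclassified + sum(!cls_mask)
    total <- total + length(truth_r)
    scores <- rbind(scores, prediction_scores(pred)$posteriors)
    truth_all <- c(truth_all, truth_r)
    spec_all <- c(spec_all, specimens[sp$test])
    pred_tables[[r]] <- pred
    folds[[r]] <- sp$test_specimens
    tested_events <- union(tested_events,
                           rownames(x)[sp$test] %||% as.character(sp$test))
  }

  met <- confusion_metrics(cm, scores = scores, truth = truth_all)
  all_pred <- do.call(rbind, pred_tables)
  conc <- concordance(all_pred, spec_all)
  structure(list(confusion_matrix = cm,
                 unclassified_count = unclassified,
                 accuracy = if (sum(cm) > 0) sum(diag(cm)) / sum(cm) else NA_real_,
                 per_class_sensitivity = met$sensitivity,
                 per_class_specificity = met$specificity,
                 kappa = met$kappa,
                 auroc_ovr = met$auroc,
                 duty_cycle = sum(cm) / total,
                 concordance = conc$mean,
                 per_specimen_concordance = conc$per_specimen,
                 fold_assignments = folds,
                 n_pc_used = n_pc_used,
                 n_events_tested = length(tested_events),
                 n_predictions = total,
                 class_labels = cls,
                 params = list(p = p, repeats = repeats, threshold = threshold,
                               split_level = split_level, seed = seed)),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat("Cross-validation report\n")
  cat(sprintf("  accuracy (over classified): %.4f  duty cycle: %.4f  kappa: %.4f\n",
              x$accuracy, x$duty_cycle, x$kappa))
  cat(sprintf("  %d predictions over %d repeats; %d unclassified\n",
              x$n_predictions, length(x$fold_assignments),
              x$unclassified_count))
  print(x$confusion_matrix)
  invisible(x)
}

#' Confusion-matrix metrics: sensitivity, specificity, kappa, AUROC
#'
#' @param cm Square confusion matrix (truth in rows, predictions in
#'   columns).
#' @param scores Optional matrix of per-event per-class posterior scores
#'   (columns named `posterior.<class>` or plain class names), required for
#'   AUROC.
#' @param truth True labels matching `scores` rows.
#' @return List with per-class one-vs-rest `sensitivity` and `specificity`,
#'   Cohen's `kappa` = (p_o - p_e) / (1 - p_e) with p_e from the row/column
#'   marginals, and per-class one-vs-rest `auroc` (rank statistic with
#'   midrank tie handling; `NA` without scores).
#' @export
confusion_metrics <- function(cm, scores = NULL, truth = NULL) {
  cm <- as.matrix(cm)
  if (nrow(cm) != ncol(cm)) stop("confusion matrix must be square", call. = FALSE)
  if (sum(cm) == 0) stop("empty confusion matrix", call. = FALSE)
  k <- nrow(cm)
  cls <- rownames(cm) %||% as.character(seq_len(k))
  n <- sum(cm)
  sens <- diag(cm) / rowSums(cm)
  spec <- vapply(seq_len(k), function(i) {
    tn <- n - sum(cm[i, ]) - sum(cm[, i]) + cm[i, i]
    fp <- sum(cm[, i]) - cm[i, i]
    if (tn + fp == 0) NA_real_ else tn / (tn + fp)
  }, numeric(1))
  names(sens) <- names(spec) <- cls
  kap <- cohen_kappa(cm)
  auc <- rep(NA_real_, k)
  names(auc) <- cls
  if (!is.null(scores) && !is.null(truth)) {
    colnames(scores) <- sub("^posterior\\.", "", colnames(scores))
    for (i in seq_len(k)) {
      if (cls[i] %in% colnames(scores)) {
        auc[i] <- auroc(scores[, cls[i]], truth == cls[i])
      }
    }
  }
  list(sensitivity = sens, specificity = spec, kappa = kap, auroc = auc)
}

#' Cohen's kappa from a confusion matrix
#'
#' @param cm Square confusion matrix.
#' @return `(p_o - p_e) / (1 - p_e)`; errors when `p_e = 1`.
#' @examples
#' cohen_kappa(matrix(c(40, 20, 10, 30), 2))  # 0.4
#' @export
cohen_kappa <- function(cm) {
  cm <- as.matrix(cm)
  n <- sum(cm)
  po <- sum(diag(cm)) / n
  pe <- sum(rowSums(cm) * colSums(cm)) / n^2
  if (abs(1 - pe) < 1e-15) stop("kappa undefined: expected agreement is 1", call. = FALSE)
  (po - pe) / (1 - pe)
}

#' One-vs-rest AUROC via the midrank statistic
#'
#' @param score Numeric score (higher = more positive).
#' @param positive Logical vector: is the event a positive?
#' @return AUROC in [0, 1]; `NA` if either group is empty.
#' @export
auroc <- function(score, positive) {
  positive <- as.logical(positive)
  n1 <- sum(positive)
  n0 <- sum(!positive)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(score, ties.method = "average")
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Per-specimen concordance of predictions
#'
#' Spatially invariant classification: the fraction of a specimen's
#' classified events agreeing with the specimen's modal call. Specimens with
#' fewer than 2 classified events are excluded from the dataset mean.
#'
#' @param predictions A `class_prediction` data.frame.
#' @param specimens Specimen id per prediction row.
#' @return List with `per_specimen` (named vector) and `mean`.
#' @export
concordance <- function(predictions, specimens) {
  cls_mask <- predictions$status == "classified"
  calls <- split(predictions$predicted_class[cls_mask],
                 as.character(specimens)[cls_mask])
  per <- vapply(calls, function(v) {
    if (length(v) < 2) return(NA_real_)
    max(table(v)) / length(v)
  }, numeric(1))
  list(per_specimen = per,
       mean = if (any(!is.na(per))) mean(per, na.rm = TRUE) else NA_real_)
}

#' Learning curves over data-usage fractions
#'
#' Subsamples specimens (stratified by class, seeded) at each usage
#' fraction, runs [crossvalidate()] on the subset, and records the accuracy
#' and the PC cap used. With `pc_rule = "adaptive_fifth"` the cap is
#' re-derived from each fraction's training size (the anti-overfitting
#' practice); with `pc_rule = "fixed"` the supplied `n_pc` is used at every
#' fraction (capped only by feasibility), which reproduces the overfitting
#' signature at low usage.
#'
#' @param x,labels,specimens As in [crossvalidate()].
#' @param usage_fractions Fractions of the data used (default 0.1..1.0).
#' @param pc_rule `"adaptive_fifth"` or `"fixed"`.
#' @param n_pc Fixed PC count (required for `pc_rule = "fixed"`).
#' @param usage_level `"specimen"` (default): each fraction subsamples whole
#'   specimens, so the curve tracks performance against independent-specimen
#'   count — the question a sample-size analysis asks. `"event"`: each
#'   fraction subsamples events across all specimens (stratified by class),
#'   the classic data-usage curve; combined with `split_level = "event"` it
#'   reproduces the optimistic-overfitting regime in which dependent events
#'   of one specimen populate both sides of the split.
#' @param p,repeats,threshold,ridge,split_level,seed As in
#'   [crossvalidate()].
#' @param saturation_tol Absolute accuracy change below which successive
#'   fractions are flagged as saturated (default 0.02).
#' @return data.frame with one row per fraction: `fraction`, `n_specimens`,
#'   `n_events`, `n_pc_cap`, `accuracy`, `kappa`, `duty_cycle`,
#'   `delta_accuracy`, `saturated`.
#' @export
learning_curve <- function(x, labels, specimens,
                           usage_fractions = seq(0.1, 1, by = 0.1),
                           pc_rule = c("adaptive_fifth", "fixed"),
                           n_pc = NULL, p = 0.2, repeats = 10,
                           threshold = 0, ridge = 1e-6,
                           split_level = c("specimen", "event"),
                           usage_level = c("specimen", "event"),
                           seed = 1, saturation_tol = 0.02) {
  pc_rule <- match.arg(pc_rule)
  split_level <- match.arg(split_level)
  usage_level <- match.arg(usage_level)
  if (pc_rule == "fixed" && is.null(n_pc)) {
    stop("pc_rule = 'fixed' requires n_pc", call. = FALSE)
  }
  x <- as.matrix(x)
  labels <- as.character(labels)
  specimens <- as.character(specimens)
  spec_class <- vapply(split(labels, specimens), function(l) {
    names(sort(table(l), decreasing = TRUE))[1]
  }, character(1))
  by_class <- split(names(spec_class), spec_class)

  by_class_events <- split(seq_along(labels), labels)

  rows <- lapply(seq_along(usage_fractions), function(fi) {
    f <- usage_fractions[fi]
    if (f >= 1) {
      # Full usage is exactly leave-p-out CV on the whole dataset.
      rep_f <- crossvalidate(x, labels, specimens, p = p, repeats = repeats,
                             n_pc = if (pc_rule == "adaptive_fifth") NULL else n_pc,
                             threshold = threshold, ridge = ridge,
                             split_level = split_level, seed = seed)
      return(data.frame(fraction = f,
                        n_specimens = length(unique(specimens)),
                        n_events = length(labels),
                        n_pc_cap = max(rep_f$n_pc_used),
                        accuracy = rep_f$accuracy,
                        kappa = rep_f$kappa,
                        duty_cycle = rep_f$duty_cycle))
    }
    cm <- NULL
    total <- 0L
    caps <- integer(repeats)
    n_ev <- 0L
    n_sp <- 0L
    # A fresh usage subsample per repeat, so curve points average over both
    # the subsampling and the split variability.
    for (r in seq_len(repeats)) {
      sub_seed <- derive_seed(seed, 1000L * fi + r)
      idx <- with_seed(sub_seed, {
        if (usage_level == "specimen") {
          chosen <- unlist(lapply(by_class, function(ids) {
            n_use <- round(f * length(ids))
            if (n_use < 2) {
              stop(sprintf(
                "usage fraction %.2f leaves < 2 specimens in a class", f),
                call. = FALSE)
            }
            sample(ids, n_use)
          }), use.names = FALSE)
          which(specimens %in% chosen)
        } else {
          sort(unlist(lapply(by_class_events, function(ev) {
            n_use <- max(4L, round(f * length(ev)))
            sample(ev, n_use)
          }), use.names = FALSE))
        }
      })
      npc_f <- if (pc_rule == "adaptive_fifth") NULL else n_pc
      rep_f <- crossvalidate(x[idx, , drop = FALSE], labels[idx],
                             specimens[idx], p = p, repeats = 1,
                             n_pc = npc_f, threshold = threshold,
                             ridge = ridge, split_level = split_level,
                             seed = derive_seed(seed, 2000L * fi + r))
      cm <- if (is.null(cm)) rep_f$confusion_matrix else
        cm + rep_f$confusion_matrix
      total <- total + rep_f$n_predictions
      caps[r] <- max(rep_f$n_pc_used)
      n_ev <- length(idx)
      n_sp <- length(unique(specimens[idx]))
    }
    data.frame(fraction = f,
               n_specimens = n_sp,
               n_events = n_ev,
               n_pc_cap = max(caps),
               accuracy = sum(diag(cm)) / sum(cm),
               kappa = cohen_kappa(cm),
               duty_cycle = sum(cm) / total)
  })
  out <- do.call(rbind, rows)
  out$delta_accuracy <- c(NA, diff(out$accuracy))
  out$saturated <- !is.na(out$delta_accuracy) &
    abs(out$delta_accuracy) < saturation_tol
  attr(out, "pc_rule") <- pc_rule
  attr(out, "saturation_tol") <- saturation_tol
  out
}
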
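#' Maximum principal-component count rule
#'
#' The empirical cap used for ambient-MS fingerprint models: approximately
#' one-fifth (20%) of the number of data points, further limited by the
#' degrees of freedom available after class centering and by the number of
#' bins. Never below 1.
#'
#' @param n_events Number of training data points (sampling events).
#' @param n_bins Number of m/z bins (variables).
#' @param n_classes Number of classes.
#' @return `min(floor(n_events / 5), n_events - n_classes, n_bins)`, at
#'   least 1.
#' @examples
#' max_pca_components(100, 9000, 3)  # 20
#' max_pca_components(10, 4, 3)      # 2
#' @export
max_pca_components <- function(n_events, n_bins, n_classes) {
  if (n_events <= n_classes) {
    stop("need more events than classes", call. = FALSE)
  }
  max(1L, min(floor(n_events / 5), n_events - n_classes, n_bins))
}

#' Linear-discriminant dimensionality rule
#'
#' The number of discriminant dimensions is the number of classes minus one.
#'
#' @param n_classes Number of classes (>= 2).
#' @return `n_classes - 1`.
#' @export
ld_dimensions <- function(n_classes) {
  if (n_classes < 2) stop("LDA requires >= 2 classes", call. = FALSE)
  as.integer(n_classes - 1)
}

# Orient a set of column vectors so each column's largest-magnitude
# coefficient is positive (reproducible sign convention).
fix_signs <- function(m) {
  for (j in seq_len(ncol(m))) {
    i <- which.max(abs(m[, j]))
    if (m[i, j] < 0) m[, j] <- -m[, j]
  }
  m
}

#' Fit a supervised PCA-LDA fingerprint model
#'
#' Mean-centers the fingerprint matrix, reduces it to `n_pc` principal
#' components (via singular value decomposition), and solves Fisher's linear
#' discriminant in PC-score space as the generalized eigenproblem maximizing
#' between-class over pooled within-class scatter. Per-class centroids and
#' covariance matrices are then estimated in LD space (with a diagonal ridge
#' so Mahalanobis distances are always defined).
#'
#' The within-class scatter is pooled across classes for axis estimation
#' (standard Fisher formulation), while per-class covariances are retained
#' separately for Mahalanobis scoring. Centering only (no per-bin scaling) is
#' applied by default, matching TIC-normalized intensity semantics.
#'
#' @param x Numeric matrix, events x bins (rows optionally named by
#'   event id).
#' @param labels Class label per row.
#' @param n_pc Number of principal components; defaults to
#'   [max_pca_components()]. Values above the hard cap
#'   `min(n_events - n_classes, n_bins)` or the numerical rank are reduced.
#' @param n_ld Number of discriminant axes; defaults to and may not exceed
#'   [ld_dimensions()].
#' @param ridge Relative ridge added to the diagonal of each per-class LD
#'   covariance: `ridge * trace / n_ld` (default 1e-6).
#' @param scale Logical; also scale bins to unit variance before PCA
#'   (default FALSE).
#' @return Object of class `pcalda` with elements `global_mean`,
#'   `pca_loadings` (bins x n_pc), `pca_eigenvalues`, `ld_axes`
#'   (n_pc x n_ld), `class_labels`, `class_centroids` (classes x n_ld),
#'   `class_covariances`, `n_pc`, `n_ld`, `total_variance`,
#'   `training_summary`, `bins` (column indices the model consumes).
#' @export
pcalda <- function(x, labels, n_pc = NULL, n_ld = NULL, ridge = 1e-6,
                   scale = FALSE) {
  x <- as.matrix(x)
  labels <- as_class_factor(labels)
  n <- nrow(x)
  p <- ncol(x)
  k <- nlevels(labels)
  if (k < 2) stop("LDA requires >= 2 classes", call. = FALSE)
  counts <- table(labels)
  if (any(counts < 2)) {
    stop("every class needs >= 2 events: ",
         paste(names(counts)[counts < 2], collapse = ", "), call. = FALSE)
  }
  if (is.null(n_pc)) n_pc <- max_pca_components(n, p, k)
  n_pc <- min(n_pc, n - k, p)
  if (n_pc < 1) stop("no usable principal components", call. = FALSE)
  if (is.null(n_ld)) n_ld <- ld_dimensions(k)
  if (n_ld > k - 1) stop("n_ld may not exceed n_classes - 1", call. = FALSE)

  mu <- colMeans(x)
  xc <- sweep(x, 2, mu)
  scl <- NULL
  if (scale) {
    scl <- apply(xc, 2, stats::sd)
    scl[scl == 0] <- 1
    xc <- sweep(xc, 2, scl, "/")
  }

  sv <- svd(xc, nu = 0, nv = min(n - 1, p))
  ev_all <- sv$d^2 / (n - 1)                  # PC variances, descending
  tol <- max(sv$d) * 1e-10
  rank <- sum(sv$d > tol)
  n_pc <- min(n_pc, rank)
  loadings <- fix_signs(sv$v[, seq_len(n_pc), drop = FALSE])
  scores <- xc %*% loadings

  # Fisher LDA in score space: maximize between- over within-class scatter.
  cls <- levels(labels)
  grand <- colMeans(scores)
  Sw <- matrix(0, n_pc, n_pc)
  Sb <- matrix(0, n_pc, n_pc)
  means <- matrix(0, k, n_pc, dimnames = list(cls, NULL))
  for (i in seq_len(k)) {
    si <- scores[labels == cls[i], , drop = FALSE]
    means[i, ] <- colMeans(si)
    d <- sweep(si, 2, means[i, ])
    Sw <- Sw + crossprod(d)
    db <- means[i, ] - grand
    Sb <- Sb + nrow(si) * tcrossprod(db)
  }
  Sw <- Sw / (n - k)
  Sb <- Sb / max(1, k - 1)
  # Small absolute ridge keeps Sw invertible when n_pc approaches n - k.
  diag(Sw) <- diag(Sw) + 1e-8 * sum(diag(Sw)) / n_pc

  R <- tryCatch(chol(Sw), error = function(e) NULL)
  if (is.null(R)) stop("within-class scatter is degenerate", call. = FALSE)
  Rinv <- backsolve(R, diag(n_pc))
  M <- crossprod(Rinv, Sb %*% Rinv)
  M <- (M + t(M)) / 2
  eg <- eigen(M, symmetric = TRUE)
  axes <- Rinv %*% eg$vectors[, seq_len(n_ld), drop = FALSE]
  axes <- apply(axes, 2, function(a) a / sqrt(sum(a^2)))
  axes <- fix_signs(matrix(axes, nrow = n_pc))

  ld <- scores %*% axes
  centroids <- matrix(0, k, n_ld, dimnames = list(cls, NULL))
  covs <- vector("list", k)
  names(covs) <- cls
  for (i in seq_len(k)) {
    li <- ld[labels == cls[i], , drop = FALSE]
    centroids[i, ] <- colMeans(li)
    cv <- stats::cov(li)
    cv <- (cv + t(cv)) / 2
    diag(cv) <- diag(cv) + ridge * sum(diag(cv)) / n_ld
    covs[[i]] <- cv
  }

  structure(list(global_mean = mu,
                 scale = scl,
                 pca_loadings = loadings,
                 pca_eigenvalues = ev_all[seq_len(n_pc)],
                 all_eigenvalues = ev_all,
                 ld_axes = axes,
                 ld_eigenvalues = eg$values[seq_len(n_ld)],
                 class_labels = cls,
                 class_centroids = centroids,
                 class_covariances = covs,
                 n_pc = n_pc,
                 n_ld = as.integer(n_ld),
                 ridge = ridge,
                 total_variance = sum(ev_all),
                 training_summary = list(n_events = n,
                                         per_class = as.integer(counts)),
                 bins = seq_len(p)),
            class = "pcalda")
}

#' @export
print.pcalda <- function(x, ...) {
  cat(sprintf("PCA-LDA model: %d classes, %d PCs, %d LD axes, %d bins\n",
              length(x$class_labels), x$n_pc, x$n_ld, length(x$global_mean)))
  cat("  classes:", paste(x$class_labels, collapse = ", "), "\n")
  invisible(x)
}

#' Project fingerprints into a model's LD space
#'
#' @param model A fitted [pcalda()] model.
#' @param x Matrix (or vector) of fingerprints. If wider than the model's
#'   bin set (e.g. a full-width matrix offered to a sparse model), the
#'   model's `bins` columns are extracted first.
#' @return Matrix of LD coordinates, rows matching `x`.
#' @export
project_ld <- function(model, x) {
  stopifnot(inherits(model, "pcalda"))
  if (is.vector(x)) x <- matrix(x, nrow = 1)
  x <- as.matrix(x)
  p <- length(model$global_mean)
  if (ncol(x) != p) {
    if (max(model$bins) <= ncol(x)) {
      x <- x[, model$bins, drop = FALSE]
    } else {
      stop("fingerprint width does not match the model's binning", call. = FALSE)
    }
  }
  xc <- sweep(x, 2, model$global_mean)
  if (!is.null(model$scale)) xc <- sweep(xc, 2, model$scale, "/")
  (xc %*% model$pca_loadings) %*% model$ld_axes
}

#' Scree fractions of explained variance
#'
#' @param model A fitted [pcalda()] model.
#' @return Vector of length `n_pc`: each retained component's eigenvalue
#'   divided by the total variance of the centered training data.
#'   Nonincreasing; sums to at most 1.
#' @export
scree <- function(model) {
  stopifnot(inherits(model, "pcalda"))
  model$pca_eigenvalues / model$total_variance
}

#' Rank bins by their contribution to class discrimination
#'
#' The importance of bin `b` is the Euclidean norm, over LD axes, of the
#' composite PCA-then-LD projection weight of `b` — the quantity a loading
#' plot displays. Ties are broken by ascending bin index.
#'
#' @param model A fitted [pcalda()] model.
#' @return data.frame with columns `bin` (index into the model's bin set),
#'   `importance`, sorted by decreasing importance.
#' @export
loading_ranks <- function(model) {
  stopifnot(inherits(model, "pcalda"))
  w <- model$pca_loadings %*% model$ld_axes      # bins x n_ld
  imp <- sqrt(rowSums(w^2))
  ord <- order(-imp, seq_along(imp))
  data.frame(bin = model$bins[ord], importance = imp[ord])
}

#' Serialize a PCA-LDA model to a single JSON file
#'
#' Versioned schema containing all matrices, labels, component rules and a
#' config hash, so a model round-trips losslessly through text.
#'
#' @param model A [pcalda()] model.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_pcalda <- function(model, path) {
  stopifnot(inherits(model, "pcalda"))
  payload <- list(schema = "tissueprint/pcalda/1",
                  global_mean = model$global_mean,
                  scale = model$scale,
                  pca_loadings = model$pca_loadings,
                  pca_eigenvalues = model$pca_eigenvalues,
                  all_eigenvalues = model$all_eigenvalues,
                  ld_axes = model$ld_axes,
                  ld_eigenvalues = model$ld_eigenvalues,
                  class_labels = model$class_labels,
                  class_centroids = model$class_centroids,
                  class_covariances = model$class_covariances,
                  n_pc = model$n_pc, n_ld = model$n_ld,
                  ridge = model$ridge,
                  total_variance = model$total_variance,
                  training_summary = model$training_summary,
                  bins = model$bins)
  # Compact fingerprint (dims, labels, matrix checksums) rather than the
  # full serialized payload, so hashing stays O(1) for wide models.
  payload$config_hash <- fnv1a(paste(
    payload$schema, payload$n_pc, payload$n_ld,
    paste(payload$class_labels, collapse = ","),
    sprintf("%.15g", c(sum(payload$global_mean), sum(payload$pca_loadings),
                       sum(payload$ld_axes), sum(payload$class_centroids),
                       payload$total_variance)),
    collapse = "|"))
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE,
                       null = "null")
  invisible(path)
}

#' Read a model written by [write_pcalda()]
#'
#' @param path JSON file path.
#' @return A `pcalda` model.
#' @export
read_pcalda <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(j$schema, "tissueprint/pcalda/1")) {
    stop("unrecognized model schema", call. = FALSE)
  }
  m <- list(global_mean = as.numeric(j$global_mean),
            scale = if (length(j$scale) == 0) NULL else as.numeric(j$scale),
            pca_loadings = as.matrix(j$pca_loadings),
            pca_eigenvalues = as.numeric(j$pca_eigenvalues),
            all_eigenvalues = as.numeric(j$all_eigenvalues),
            ld_axes = as.matrix(j$ld_axes),
            ld_eigenvalues = as.numeric(j$ld_eigenvalues),
            class_labels = as.character(j$class_labels),
            class_centroids = as.matrix(j$class_centroids),
            class_covariances = lapply(j$class_covariances, as.matrix),
            n_pc = as.integer(j$n_pc), n_ld = as.integer(j$n_ld),
            ridge = j$ridge,
            total_variance = j$total_variance,
            training_summary = j$training_summary,
            bins = as.integer(j$bins))
  rownames(m$class_centroids) <- m$class_labels
  names(m$class_covariances) <- m$class_labels
  class(m) <- "pcalda"
  m
}
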
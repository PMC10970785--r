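# Independent brute-force oracles and small fixtures used across tests.

# Tiny generated dataset for fast structural tests.
tiny_dataset <- function(seed = 1, ...) {
  args <- list(n_classes = 2, specimens_per_class = 3, events_per_specimen = 4,
               scans_per_event = 3, n_bins = 30, class_separation = 6,
               specimen_sd = 0.5, event_sd = 1, seed = seed)
  extra <- list(...)
  args[names(extra)] <- extra
  generate_dataset(do.call(synthetic_config, args))
}

# Gaussian-class matrix with a single informative bin (bin 7 by default).
one_bin_signal <- function(n_per_class = 30, n_bins = 12, signal_bin = 7,
                           offset = 10, seed = 42) {
  set.seed(seed)
  x <- matrix(rnorm(2 * n_per_class * n_bins), ncol = n_bins)
  x[seq_len(n_per_class), signal_bin] <- x[seq_len(n_per_class), signal_bin] + offset
  list(x = x, labels = rep(c("a", "b"), each = n_per_class))
}

# Brute-force Fisher discriminant in bin space via a dense generalized
# eigen-solve (independent route: explicit inverse + nonsymmetric eigen).
bf_lda_direction <- function(x, labels, n_pc) {
  labels <- factor(labels)
  n <- nrow(x)
  k <- nlevels(labels)
  xc <- sweep(x, 2, colMeans(x))
  pca <- eigen(stats::cov(xc), symmetric = TRUE)
  V <- pca$vectors[, seq_len(n_pc), drop = FALSE]
  s <- xc %*% V
  grand <- colMeans(s)
  Sw <- matrix(0, n_pc, n_pc)
  Sb <- matrix(0, n_pc, n_pc)
  for (cl in levels(labels)) {
    si <- s[labels == cl, , drop = FALSE]
    m <- colMeans(si)
    Sw <- Sw + crossprod(sweep(si, 2, m))
    Sb <- Sb + nrow(si) * tcrossprod(m - grand)
  }
  Sw <- Sw / (n - k)
  Sb <- Sb / max(1, k - 1)
  diag(Sw) <- diag(Sw) + 1e-8 * sum(diag(Sw)) / n_pc
  eg <- eigen(solve(Sw) %*% Sb)
  a <- Re(eg$vectors[, 1])
  w <- V %*% a
  w / sqrt(sum(w^2))
}

# O(n^2) pair-counting AUROC with half-credit for ties.
bf_auroc <- function(score, positive) {
  pos <- score[positive]
  neg <- score[!positive]
  tot <- 0
  for (p in pos) tot <- tot + sum(p > neg) + 0.5 * sum(p == neg)
  tot / (length(pos) * length(neg))
}

# Cohen's kappa from first principles with explicit loops.
bf_kappa <- function(cm) {
  n <- sum(cm)
  po <- 0
  pe <- 0
  for (i in seq_len(nrow(cm))) {
    po <- po + cm[i, i] / n
    pe <- pe + (sum(cm[i, ]) / n) * (sum(cm[, i]) / n)
  }
  (po - pe) / (1 - pe)
}

# Align the sign of vector b to a before comparing directions.
align_sign <- function(a, b) if (sum(a * b) < 0) -b else b
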
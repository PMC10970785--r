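# Internal helpers shared across modules.

#' Evaluate an expression under a temporary RNG state
#'
#' Seeds the R random number generator, evaluates `expr`, and restores the
#' caller's RNG state afterwards so that seeded package functions never
#' disturb user-level randomness.
#'
#' @param seed Integer seed (must be < 2^31).
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("seed must be a single integer", call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a stream-specific sub-seed from a base seed; keeps values inside the
# 32-bit signed integer range R requires.
derive_seed <- function(seed, stream) {
  as.integer((as.double(seed) * 48271 + stream * 16807) %% 2147483647)
}

# log(sum(exp(x))) without overflow/underflow.
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# 32-bit FNV-1a hash of a character scalar, returned as 8 hex digits.
# Used for config fingerprints in run logs and reports.
fnv1a <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  bytes <- utf8ToInt(x)
  h <- 2166136261
  for (b in bytes) {
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), as.integer(b))
    h <- (h * 16777619) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Consistent ordered factor of class labels: alphabetical level order is the
# package-wide tie-break convention.
as_class_factor <- function(labels, levels = NULL) {
  if (is.null(levels)) levels <- sort(unique(as.character(labels)))
  factor(as.character(labels), levels = levels)
}
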
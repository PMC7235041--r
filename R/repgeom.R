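#' Item dissimilarity matrices
#'
#' An `item_dm` stores the condensed (upper-triangle, row-major) vector of
#' pairwise dissimilarities over an ordered item set -- the universal
#' currency of the pipeline. Entry order matches [stats::dist()]:
#' (1,2), (1,3), ..., (1,n), (2,3), ...
#'
#' @param condensed Numeric vector of length `n * (n - 1) / 2`.
#' @param items Character vector of item identifiers (length `n`).
#' @return An object of class `item_dm`.
#' @export
item_dm <- function(condensed, items) {
  n <- length(items)
  if (length(condensed) != n * (n - 1) / 2) {
    stop("condensed length does not match item count", call. = FALSE)
  }
  if (!all(is.finite(condensed))) {
    stop("dissimilarities must be finite", call. = FALSE)
  }
  structure(list(n_items = n, items = as.character(items),
                 condensed = as.numeric(condensed)),
            class = "item_dm")
}

#' @export
print.item_dm <- function(x, ...) {
  cat(sprintf("<item_dm> %d items, %d pairs; range [%.3g, %.3g]\n",
              x$n_items, length(x$condensed), min(x$condensed),
              max(x$condensed)))
  invisible(x)
}

#' @rdname item_dm
#' @param x An `item_dm`.
#' @export
as.matrix.item_dm <- function(x, ...) {
  m <- matrix(0, x$n_items, x$n_items, dimnames = list(x$items, x$items))
  m[upper.tri(m)] <- condensed_to_upper(x$condensed, x$n_items)
  m <- m + t(m)
  m
}

# dist order is (1,2)..(1,n),(2,3)..: identical to row-major upper triangle,
# but R's upper.tri() indexing is column-major, so reorder explicitly.
condensed_to_upper <- function(condensed, n) {
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)  # column-major
  pos <- dist_pair_index(idx[, "row"], idx[, "col"], n)
  condensed[pos]
}

# index of pair (i, j), i < j, in dist/condensed order
dist_pair_index <- function(i, j, n) {
  (i - 1) * n - i * (i - 1) / 2 + (j - i)
}

#' Pairwise item labels of a condensed DM
#'
#' @param items Character vector of item ids.
#' @return Data frame with columns `item_a`, `item_b` in condensed order.
#' @export
condensed_pairs <- function(items) {
  n <- length(items)
  i <- rep(seq_len(n - 1), times = (n - 1):1)
  j <- unlist(lapply(seq_len(n - 1), function(a) (a + 1):n))
  data.frame(item_a = items[i], item_b = items[j],
             stringsAsFactors = FALSE)
}

#' Correlation-distance DM from an item pattern matrix
#'
#' Computes, for every item pair, `1 - Pearson r` between the two items'
#' feature vectors (beta-estimate patterns). This is the standard MVPA
#' correlation distance; entries lie in `[0, 2]`.
#'
#' @param patterns Numeric matrix, items x features (>= 2 items, >= 2
#'   features), with item ids as row names (generated if absent).
#' @return An `item_dm`.
#' @export
compute_item_dm <- function(patterns) {
  patterns <- as.matrix(patterns)
  if (nrow(patterns) < 2L) stop("need at least 2 items", call. = FALSE)
  if (ncol(patterns) < 2L) {
    stop("degenerate pattern: feature vectors need length >= 2", call. = FALSE)
  }
  sds <- apply(patterns, 1, stats::sd)
  if (any(!is.finite(sds)) || any(sds == 0)) {
    stop("degenerate pattern: zero-variance feature vector", call. = FALSE)
  }
  items <- rownames(patterns)
  if (is.null(items)) items <- paste0("item", seq_len(nrow(patterns)))
  r <- stats::cor(t(patterns))
  # column-major lower triangle lists pairs (1,2),(1,3),..,(2,3),..: dist order
  item_dm(1 - r[lower.tri(r)], items)
}

#' Fisher z-transform of a correlation
#'
#' `atanh(r)` after clipping `r` into `[-1 + clip_eps, 1 - clip_eps]` so that
#' perfect correlations map to finite values.
#'
#' @param r Correlation value(s) in `[-1, 1]`.
#' @param clip_eps Small positive clipping margin (default `1e-7`).
#' @return Numeric z value(s).
#' @export
fisher_z <- function(r, clip_eps = 1e-7) {
  if (any(abs(r) > 1 + 1e-12, na.rm = TRUE)) {
    stop("correlation outside [-1, 1]", call. = FALSE)
  }
  atanh(pmin(pmax(r, -1 + clip_eps), 1 - clip_eps))
}

#' Normalized correlation between two DMs
#'
#' Both condensed vectors are mean-centered and scaled to unit norm; the
#' statistic is their dot product, which equals the Pearson correlation of
#' the two condensed vectors and lies in `[-1, 1]`.
#'
#' @param dm_a,dm_b `item_dm` objects (or bare condensed numeric vectors) over
#'   the same items in the same order.
#' @return A single correlation value.
#' @export
normalized_correlation <- function(dm_a, dm_b) {
  a <- if (inherits(dm_a, "item_dm")) dm_a$condensed else as.numeric(dm_a)
  b <- if (inherits(dm_b, "item_dm")) dm_b$condensed else as.numeric(dm_b)
  if (length(a) != length(b)) {
    stop("DMs have different numbers of pairs", call. = FALSE)
  }
  if (inherits(dm_a, "item_dm") && inherits(dm_b, "item_dm") &&
      !identical(dm_a$items, dm_b$items)) {
    stop("DMs are over different item sets/orders", call. = FALSE)
  }
  a <- a - mean(a)
  b <- b - mean(b)
  na <- sqrt(sum(a^2))
  nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) {
    stop("degenerate DM: constant condensed vector", call. = FALSE)
  }
  sum((a / na) * (b / nb))
}

#' One-sample t-test against zero
#'
#' Thin wrapper over [stats::t.test()] returning the fields used throughout
#' the pipeline (two-sided).
#'
#' @param values Numeric vector (n >= 2, non-zero variance), typically
#'   Fisher-z correlation values.
#' @return List with `statistic` (t), `df` (`n - 1`), `p` (two-sided) and
#'   `mean`.
#' @export
one_sample_t <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 2L) stop("need n >= 2", call. = FALSE)
  if (stats::sd(values) == 0) {
    stop("degenerate sample: zero variance", call. = FALSE)
  }
  tt <- stats::t.test(values, mu = 0)
  list(statistic = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, mean = mean(values))
}
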
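# Fixed-margin permutation test for within-cluster co-activation of OR genes.

#' Binarize a normalized matrix into an activity matrix
#'
#' Entry 1 where the normalized value reaches `threshold` (inclusive), 0
#' otherwise. Rows are restricted to `or_genes` and, optionally, columns to
#' `cells`.
#'
#' @param norm Normalized matrix.
#' @param or_genes OR gene ids (rows to keep).
#' @param threshold Activity threshold, inclusive (default 50).
#' @param cells Optional cell ids (columns to keep).
#' @return An integer 0/1 matrix with attribute `threshold`.
#' @export
binarize_activity <- function(norm, or_genes, threshold = 50, cells = NULL) {
  m <- norm[or_genes, , drop = FALSE]
  if (!is.null(cells)) m <- m[, cells, drop = FALSE]
  A <- (m >= threshold) + 0L
  attr(A, "threshold") <- threshold
  A
}

cluster_vector <- function(A, annotation) {
  cl <- annotation$cluster_id[match(rownames(A), annotation$gene_id)]
  if (any(is.na(match(rownames(A), annotation$gene_id)))) {
    abort("activity matrix contains genes missing from the annotation",
          class = "orselect_validation_error")
  }
  cl[is.na(cl)] <- paste0(".singleton.", rownames(A)[is.na(cl)])
  cl
}

#' Within-cluster co-activation statistic
#'
#' For every cell with at least one active gene, the fraction of its active
#' clusters (clusters containing >= 1 active gene) that contain more than one
#' active gene; the statistic is the mean of this fraction over such cells
#' (`variant = "frequency"`, the default). The `"count"` variant instead
#' averages the absolute number of clusters with > 1 active gene over all
#' cells. Genes without a cluster form singleton clusters and can therefore
#' never co-activate.
#'
#' @param A Binary activity matrix (genes x cells).
#' @param clusters Character vector of cluster ids aligned with `rownames(A)`,
#'   or a gene annotation tibble (with `gene_id`, `cluster_id`) from which it
#'   is derived.
#' @param variant `"frequency"` or `"count"`.
#' @return A single number.
#' @export
cocluster_statistic <- function(A, clusters, variant = c("frequency", "count")) {
  variant <- match.arg(variant)
  if (is.data.frame(clusters)) clusters <- cluster_vector(A, clusters)
  stopifnot(length(clusters) == nrow(A))
  per_cluster <- rowsum(A + 0L, clusters)
  n_multi <- colSums(per_cluster >= 2)
  if (variant == "count") return(mean(n_multi))
  n_any <- colSums(per_cluster >= 1)
  has <- n_any > 0
  if (!any(has)) {
    abort("no cell has any active gene; the co-activation frequency is undefined",
          class = "orselect_validation_error")
  }
  mean(n_multi[has] / n_any[has])
}

#' Shuffle a binary matrix preserving both margins
#'
#' Applies `n_trades` curveball trades: each trade picks two rows, pools the
#' columns unique to either, and reallocates them at random. Row sums and
#' column sums are preserved exactly; as the number of trades grows the state
#' approaches a uniform draw from the set of all binary matrices with those
#' margins.
#'
#' @param A Binary matrix.
#' @param n_trades Number of trades; default 5 x nrow(A).
#' @return A shuffled binary matrix with the same dimnames and margins.
#' @export
shuffle_margins <- function(A, n_trades = 5 * nrow(A)) {
  out <- curveball_shuffle(A + 0L, as.integer(n_trades))
  dimnames(out) <- dimnames(A)
  attributes(out)$threshold <- attr(A, "threshold")
  out
}

#' Permutation test for within-cluster co-activation
#'
#' Tests whether OR genes that are jointly active in the same cells co-locate
#' in genomic clusters more than expected if active genes were allocated at
#' random, holding fixed both how many genes each cell activates and how many
#' cells each gene is active in. The null is sampled with curveball trades
#' chained from the previous state after an initial burn-in; the p-value is
#' the one-sided upper tail with the add-one (permutation-inclusive)
#' correction, so it can never be exactly zero.
#'
#' @inheritParams cocluster_statistic
#' @param n_perm Number of permutations (default 1000).
#' @param n_trades Trades per permutation; default 5 x nrow(A). Burn-in of the
#'   same length precedes the first draw.
#' @param seed Optional integer seed; the result records it and is fully
#'   reproducible from it.
#' @return An object of class `cocluster_test`: a list with `observed`,
#'   `observed_count` (the count-variant statistic, as a diagnostic),
#'   `null_values`, `p_value`, `n_perm`, `n_trades`, `seed`, `variant`.
#' @seealso [tidy.cocluster_test()], [glance.cocluster_test()],
#'   [autoplot.cocluster_test()]
#' @export
cocluster_test <- function(A, clusters, n_perm = 1000, n_trades = 5 * nrow(A),
                           seed = NULL, variant = c("frequency", "count")) {
  variant <- match.arg(variant)
  if (is.data.frame(clusters)) clusters <- cluster_vector(A, clusters)
  if (!is.null(seed)) set.seed(seed)
  observed <- cocluster_statistic(A, clusters, variant)
  observed_count <- cocluster_statistic(A, clusters, "count")
  null_values <- numeric(n_perm)
  state <- A + 0L
  state <- curveball_shuffle(state, as.integer(n_trades))  # burn-in
  for (b in seq_len(n_perm)) {
    state <- curveball_shuffle(state, as.integer(n_trades))
    null_values[b] <- tryCatch(
      cocluster_statistic(state, clusters, variant),
      error = function(e) {
        warn("undefined statistic on a shuffle; recording 0")
        0
      })
  }
  p_value <- (1 + sum(null_values >= observed - 1e-12)) / (1 + n_perm)
  structure(list(observed = observed, observed_count = observed_count,
                 null_values = null_values, p_value = p_value,
                 n_perm = n_perm, n_trades = n_trades, seed = seed,
                 variant = variant),
            class = "cocluster_test")
}

#' @export
print.cocluster_test <- function(x, ...) {
  cat("Fixed-margin co-activation permutation test\n")
  cat(sprintf("  statistic (%s variant): %.4f\n", x$variant, x$observed))
  cat(sprintf("  permutations: %d (%d trades each), p = %.4g\n",
              x$n_perm, x$n_trades, x$p_value))
  invisible(x)
}

#' Tidy the null sample of a co-activation permutation test
#' @param x A `cocluster_test`.
#' @param ... Unused.
#' @return A tibble (`permutation`, `statistic`).
#' @export
tidy.cocluster_test <- function(x, ...) {
  tibble(permutation = seq_along(x$null_values), statistic = x$null_values)
}

#' One-row summary of a co-activation permutation test
#' @param x A `cocluster_test`.
#' @param ... Unused.
#' @return A one-row tibble.
#' @export
glance.cocluster_test <- function(x, ...) {
  tibble(observed = x$observed, observed_count = x$observed_count,
         p_value = x$p_value, n_perm = x$n_perm, n_trades = x$n_trades,
         variant = x$variant,
         null_mean = mean(x$null_values), null_sd = stats::sd(x$null_values))
}
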
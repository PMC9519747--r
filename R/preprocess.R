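# Gene retention, library-size normalization, detectability.

#' Retain genes with at least one cell above a count threshold
#'
#' Keeps exactly the genes whose maximum per-cell raw count is strictly greater
#' than `min_count` (default 40), preserving gene order. The strict inequality
#' matters at the boundary: a gene whose best cell has exactly `min_count`
#' counts is dropped. This retains sporadically but solidly expressed genes
#' (such as odorant receptors in a handful of cells) while discarding
#' ubiquitous low-level noise.
#'
#' @param counts Raw integer count matrix (genes x cells).
#' @param min_count Strict lower bound on the per-gene maximum count.
#' @return The filtered count matrix.
#' @export
filter_genes <- function(counts, min_count = 40) {
  keep <- apply(counts, 1, max) > min_count
  if (!any(keep)) warn("no gene passes the retention filter; returning an empty matrix")
  counts[keep, , drop = FALSE]
}

#' Library-size normalization to a common per-cell total
#'
#' Scales each cell's counts by `scale_target / library_size`, so every cell
#' with a nonzero library sums to `scale_target` ("normalized pseudocounts").
#' Cells with an all-zero library are left all-zero. Zeros stay zero and
#' within-cell rank order is unchanged, so count-scale activity thresholds
#' (e.g. 50 normalized counts) are directly comparable across cells.
#'
#' @param counts Count matrix (genes x cells), usually after [filter_genes()].
#' @param scale_target Per-cell total after scaling; the default `"median"`
#'   uses the median library size of the input cells.
#' @return A numeric matrix with attribute `scale_target`.
#' @export
normalize_counts <- function(counts, scale_target = "median") {
  lib <- colSums(counts)
  if (identical(scale_target, "median")) scale_target <- stats::median(lib)
  scale_target <- as.numeric(scale_target)
  if (!is.finite(scale_target) || scale_target <= 0) {
    abort("scale_target must be a positive number or \"median\"",
          class = "orselect_validation_error")
  }
  f <- ifelse(lib > 0, scale_target / lib, 0)
  norm <- sweep(counts, 2, f, `*`)
  dimnames(norm) <- dimnames(counts)
  attr(norm, "scale_target") <- scale_target
  norm
}

#' Natural-log view of normalized counts
#'
#' `log(1 + x)` of the normalized matrix. This view feeds plots and
#' fold-change displays only; all activity/detectability thresholds in this
#' package operate on the normalized count scale.
#'
#' @param norm Normalized matrix from [normalize_counts()].
#' @return A numeric matrix.
#' @export
log_normalized <- function(norm) {
  out <- log1p(norm)
  attr(out, "scale_target") <- attr(norm, "scale_target")
  out
}

#' Genes detectable under a level/cell-count rule
#'
#' A gene is detectable if at least `min_cells` cells (within `cells`, default
#' all) express it at `min_level` normalized counts or more. Both bounds are
#' inclusive. The defaults (35 counts in 15 cells) are the rule used to decide
#' which transcription factors are expressed well enough to be screened.
#'
#' @param norm Normalized matrix.
#' @param min_level Inclusive expression level threshold (normalized counts).
#' @param min_cells Inclusive minimum number of qualifying cells.
#' @param cells Optional character vector of cell ids restricting the tally.
#' @return Character vector of detectable gene ids (in matrix order).
#' @export
detectable_genes <- function(norm, min_level = 35, min_cells = 15, cells = NULL) {
  if (!is.null(cells)) {
    missing <- setdiff(cells, colnames(norm))
    if (length(missing) > 0) {
      abort(sprintf("unknown cell id(s): %s", paste(utils::head(missing, 5), collapse = ", ")),
            class = "orselect_lookup_error")
    }
    norm <- norm[, cells, drop = FALSE]
  }
  if (ncol(norm) == 0) return(character(0))
  n_hit <- rowSums(norm >= min_level)
  rownames(norm)[n_hit >= min_cells]
}
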
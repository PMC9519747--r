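# Differential expression screen across OR-expression phase transitions.

#' Wilcoxon rank-sum test between two expression vectors
#'
#' Thin wrapper around [stats::wilcox.test()]: exact null for small tie-free
#' samples, tie-corrected normal approximation with continuity correction
#' otherwise. When every value in both groups is identical the test carries no
#' information and p = 1 is returned directly.
#'
#' @param x,y Numeric vectors (each nonempty).
#' @return A list with `statistic` (the Mann-Whitney U for `x`) and `p_value`
#'   (two-sided).
#' @export
wilcoxon_rank_sum <- function(x, y) {
  stopifnot(length(x) >= 1, length(y) >= 1)
  if (length(unique(c(x, y))) == 1) {
    return(list(statistic = length(x) * length(y) / 2, p_value = 1))
  }
  wt <- suppressWarnings(stats::wilcox.test(x, y))
  list(statistic = unname(wt$statistic), p_value = wt$p.value)
}

#' Log2 fold change between group means with a pseudocount
#'
#' `log2((mean_b + pseudocount) / (mean_a + pseudocount))`, oriented so a
#' positive value means higher expression in group b (the later phase).
#'
#' @param mean_a,mean_b Nonnegative group means (normalized counts).
#' @param pseudocount Stabilising offset (default 1).
#' @return Numeric log2 fold change (vectorised).
#' @export
log2_fold_change <- function(mean_a, mean_b, pseudocount = 1) {
  log2((mean_b + pseudocount) / (mean_a + pseudocount))
}

de_one_transition <- function(norm, cells_a, cells_b, genes, label_a, label_b,
                              alpha, min_fold, pseudocount) {
  if (length(cells_a) < 3 || length(cells_b) < 3) {
    abort(sprintf("transition %s -> %s has a group with < 3 cells", label_a, label_b),
          class = "orselect_validation_error")
  }
  ma <- norm[genes, cells_a, drop = FALSE]
  mb <- norm[genes, cells_b, drop = FALSE]
  p <- vapply(seq_along(genes), function(i) {
    wilcoxon_rank_sum(ma[i, ], mb[i, ])$p_value
  }, numeric(1))
  mean_a <- unname(rowMeans(ma))
  mean_b <- unname(rowMeans(mb))
  lfc <- log2_fold_change(mean_a, mean_b, pseudocount)
  p_adj <- stats::p.adjust(p, method = "bonferroni")
  out <- tibble(
    gene_id = genes,
    transition = paste0(label_a, "_to_", label_b),
    group_a = label_a, group_b = label_b,
    mean_a = mean_a, mean_b = mean_b,
    log2_fc = lfc,
    p_value = p, p_adjusted = p_adj,
    significant = p_adj < alpha & abs(lfc) >= log2(min_fold),
    direction = ifelse(lfc >= 0, "up", "down"))
  out[order(out$p_adjusted, out$gene_id), ]
}

#' Screen genes for differential expression at phase transitions
#'
#' For each gene in `genes` (typically transcription factors, cofactors and
#' chromatin remodelers pre-filtered with [detectable_genes()]), tests the
#' silent-to-multigenic and multigenic-to-monogenic transitions with the
#' Wilcoxon rank-sum test on normalized expression. Multiple testing is
#' controlled per transition with Bonferroni over the genes tested, and a gene
#' is called significant only if it additionally changes at least
#' `min_fold`-fold (pseudocount-stabilised, on the normalized count scale).
#'
#' @param segmentation Output of [segment_phases()].
#' @param norm Normalized matrix.
#' @param genes Gene ids to test.
#' @param alpha Significance level on the Bonferroni-adjusted p (default 0.05).
#' @param min_fold Minimum fold change (default 2, i.e. |log2 FC| >= 1).
#' @param pseudocount Offset for the fold change (default 1).
#' @return A tibble, one row per gene per transition, sorted by adjusted p
#'   then gene id within transition.
#' @export
phase_de <- function(segmentation, norm, genes, alpha = 0.05, min_fold = 2,
                     pseudocount = 1) {
  missing <- setdiff(genes, rownames(norm))
  if (length(missing) > 0) {
    abort(sprintf("genes absent from the matrix: %s",
                  paste(utils::head(missing, 5), collapse = ", ")),
          class = "orselect_lookup_error")
  }
  cells_of <- function(ph) segmentation$cell_id[segmentation$phase == ph]
  dplyr::bind_rows(
    de_one_transition(norm, cells_of("silent"), cells_of("multigenic"), genes,
                      "silent", "multigenic", alpha, min_fold, pseudocount),
    de_one_transition(norm, cells_of("multigenic"), cells_of("monogenic"), genes,
                      "multigenic", "monogenic", alpha, min_fold, pseudocount))
}
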
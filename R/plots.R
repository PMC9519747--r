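# ggplot2 displays of the main result types.

#' @import ggplot2
NULL

stage_fill <- function() {
  scale_colour_viridis_d(option = "plasma", end = 0.9, drop = FALSE)
}

#' Aggregate OR expression along pseudotime
#'
#' One point per cell, ordered by pseudotime and coloured by stage: the
#' silent-phase flatline, the steep multigenic onset at Late.INP, and the
#' sustained high levels through iOSN/mOSN.
#'
#' @param profiles Output of [or_cell_profiles()].
#' @return A ggplot.
#' @export
plot_aggregate_or <- function(profiles) {
  df <- dplyr::mutate(profiles, stage = factor(.data$stage, neuronal_stages()))
  ggplot(df, aes(.data$pseudotime, .data$aggregate_or, colour = .data$stage)) +
    geom_point(size = 1.2) +
    stage_fill() +
    labs(x = "pseudotime", y = "aggregate OR expression (normalized counts)",
         colour = "stage") +
    theme_classic()
}

#' Winner and runner-up expression by stage
#'
#' Violin plots of the per-cell rank-1..4 OR expression values per lineage
#' stage, log-scaled, with the activity threshold marked. The widening gap
#' between winner and runners-up after Late.INP is the monogenic transition.
#'
#' @param profiles Output of [or_cell_profiles()].
#' @param threshold Horizontal reference line (default the profiles'
#'   threshold attribute, else 50).
#' @return A ggplot.
#' @export
plot_winner_runnerup <- function(profiles, threshold = NULL) {
  if (is.null(threshold)) threshold <- attr(profiles, "threshold") %||% 50
  long <- or_rank_long(profiles)
  long$stage <- factor(long$stage, neuronal_stages())
  ggplot(long, aes(.data$stage, .data$value + 1)) +
    geom_violin(scale = "width", fill = "grey85") +
    geom_hline(yintercept = threshold, linetype = "dotted") +
    scale_y_log10() +
    facet_grid(rows = vars(.data$rank_label)) +
    labs(x = NULL, y = "normalized counts + 1") +
    theme_bw() +
    theme(axis.text.x = element_text(angle = 45, hjust = 1))
}

#' Pseudotime course of a single gene
#'
#' @param course Output of [pseudotime_course()].
#' @param log_scale Plot log(1 + value) (default TRUE).
#' @return A ggplot.
#' @export
plot_pseudotime_course <- function(course, log_scale = TRUE) {
  df <- dplyr::mutate(course,
                      y = if (log_scale) log1p(.data$value) else .data$value,
                      stage = factor(.data$stage, c(neuronal_stages(), "other")))
  ggplot(df, aes(.data$pseudotime, .data$y, colour = .data$stage)) +
    geom_point(size = 1) +
    geom_smooth(aes(group = 1), method = "loess", formula = y ~ x,
                se = FALSE, colour = "black", linewidth = 0.5) +
    stage_fill() +
    labs(x = "pseudotime",
         y = if (log_scale) "log(1 + normalized counts)" else "normalized counts") +
    theme_classic()
}

#' Null distribution of the co-activation permutation test
#'
#' Histogram of the permuted statistics with the observed value marked.
#'
#' @param object A [cocluster_test()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.cocluster_test <- function(object, ...) {
  ggplot(tidy(object), aes(.data$statistic)) +
    geom_histogram(bins = 30, fill = "grey70", colour = "grey40") +
    geom_vline(xintercept = object$observed, colour = "red") +
    labs(x = sprintf("co-activation statistic (%s variant)", object$variant),
         y = "permutations",
         subtitle = sprintf("observed = %.3f, p = %.3g (%d permutations)",
                            object$observed, object$p_value, object$n_perm)) +
    theme_classic()
}

#' Volcano plot of a phase-transition DE screen
#'
#' @param de Output of [phase_de()].
#' @param alpha,min_fold Thresholds to mark (defaults 0.05 and 2).
#' @return A ggplot, faceted by transition.
#' @export
plot_volcano <- function(de, alpha = 0.05, min_fold = 2) {
  df <- dplyr::mutate(de, mlp = -log10(pmax(.data$p_adjusted, 1e-300)))
  ggplot(df, aes(.data$log2_fc, .data$mlp, colour = .data$significant)) +
    geom_point(size = 1) +
    geom_vline(xintercept = c(-1, 1) * log2(min_fold), linetype = "dotted") +
    geom_hline(yintercept = -log10(alpha), linetype = "dotted") +
    scale_colour_manual(values = c(`FALSE` = "grey60", `TRUE` = "firebrick")) +
    facet_wrap(vars(.data$transition)) +
    labs(x = "log2 fold change", y = "-log10 adjusted p") +
    theme_bw()
}

#' Phase distributions of active clusters and chromosomes
#'
#' Bar panels of [summarize_phase_distributions()].
#'
#' @param dist Output of [summarize_phase_distributions()].
#' @return A ggplot.
#' @export
plot_phase_distributions <- function(dist) {
  ggplot(dist, aes(.data$n_active, .data$n_cells)) +
    geom_col(fill = "grey40") +
    facet_grid(rows = vars(.data$metric), cols = vars(.data$phase)) +
    labs(x = "active per cell", y = "cells") +
    theme_bw()
}
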
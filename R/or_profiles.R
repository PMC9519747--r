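# Per-cell OR ranking, activity states, active cluster/chromosome counts,
# and phase segmentation along pseudotime.

or_gene_set <- function(annotation) {
  g <- annotation$gene_id[annotation$is_or]
  if (length(g) == 0) abort("annotation flags no OR genes", class = "orselect_validation_error")
  g
}

check_cell <- function(norm, cell_id) {
  if (!cell_id %in% colnames(norm)) {
    abort(sprintf("unknown cell id: %s", cell_id), class = "orselect_lookup_error")
  }
}

#' Rank OR genes within one cell
#'
#' Sorts the cell's OR genes by normalized expression, descending, ties broken
#' lexicographically by gene id. The winner is the rank-1 gene provided it
#' reaches the activity threshold; runners-up are ranks 2..`top_k` regardless
#' of threshold (their sub-threshold decay is itself informative).
#'
#' @param norm Normalized matrix.
#' @param or_genes Character vector of OR gene ids (subset of rownames).
#' @param cell_id Cell to rank.
#' @param top_k Number of ranks to report (default 4: winner + 3 runners-up).
#' @param threshold Activity threshold in normalized counts (default 50).
#' @return A tibble with columns `rank`, `gene_id`, `value` and attributes
#'   `winner` (gene id or NA) and `cell_id`.
#' @export
rank_or_genes <- function(norm, or_genes, cell_id, top_k = 4, threshold = 50) {
  check_cell(norm, cell_id)
  if (length(or_genes) == 0) abort("or_genes is empty", class = "orselect_validation_error")
  v <- norm[or_genes, cell_id]
  o <- order(-v, or_genes)
  k <- min(top_k, length(or_genes))
  out <- tibble(rank = seq_len(k), gene_id = or_genes[o][seq_len(k)],
                value = unname(v[o][seq_len(k)]))
  attr(out, "winner") <- if (out$value[1] >= threshold) out$gene_id[1] else NA_character_
  attr(out, "cell_id") <- cell_id
  out
}

#' Aggregate OR expression per cell
#'
#' Sum of normalized expression over all OR genes, per cell.
#'
#' @inheritParams rank_or_genes
#' @param cell_id Optional single cell id; default all cells.
#' @return A named numeric vector (or a scalar for a single cell).
#' @export
aggregate_or_expression <- function(norm, or_genes, cell_id = NULL) {
  agg <- colSums(norm[or_genes, , drop = FALSE])
  if (is.null(cell_id)) return(agg)
  check_cell(norm, cell_id)
  unname(agg[cell_id])
}

#' Call the OR activity state from the number of active ORs
#'
#' `silent` for 0 ORs at or above the threshold, `monogenic_like` for exactly
#' one, `multigenic` for two or more. Vectorised.
#'
#' @param n_active Integer vector of active-OR counts.
#' @return A factor with levels silent < monogenic_like < multigenic.
#' @export
call_state <- function(n_active) {
  factor(ifelse(n_active == 0, "silent",
         ifelse(n_active == 1, "monogenic_like", "multigenic")),
         levels = c("silent", "monogenic_like", "multigenic"))
}

# cluster labels for counting: unassigned ORs become their own singleton
# cluster (or are dropped when unclustered = "exclude")
counting_clusters <- function(annotation, genes, unclustered = c("singleton", "exclude")) {
  unclustered <- match.arg(unclustered)
  ann <- annotation[match(genes, annotation$gene_id), ]
  if (anyNA(ann$gene_id)) {
    abort("some OR genes are missing from the annotation", class = "orselect_validation_error")
  }
  cl <- if ("cluster_id" %in% names(ann)) ann$cluster_id else rep(NA_character_, nrow(ann))
  keep <- rep(TRUE, length(genes))
  if (unclustered == "singleton") {
    cl[is.na(cl)] <- paste0(".singleton.", genes[is.na(cl)])
  } else {
    keep <- !is.na(cl)
  }
  list(cluster = cl, chrom = ann$chrom, keep = keep)
}

#' Per-cell OR expression profiles
#'
#' The workhorse table behind the phase analysis: for every cell, the winner
#' and runner-up OR genes with their normalized values, aggregate OR
#' expression, the number of active ORs and of distinct active clusters and
#' chromosomes (an OR is active at `threshold` normalized counts or more), and
#' the resulting activity state. The invariant
#' `n_active_chromosomes <= n_active_clusters <= n_active_or` holds for every
#' row. ORs outside any annotated cluster count as their own singleton cluster
#' by default.
#'
#' @param cell_meta Cell metadata tibble (`cell_id`, `stage`, `pseudotime`).
#' @param norm Normalized matrix covering the cells in `cell_meta`.
#' @param annotation Gene annotation with `is_or`, `chrom` and (after
#'   [assign_genes_to_clusters()]) `cluster_id`.
#' @param threshold Activity threshold in normalized counts (default 50).
#' @param top_k Ranks to report (default 4).
#' @param unclustered `"singleton"` (default) or `"exclude"`: how ORs with no
#'   annotated cluster enter the cluster/chromosome counts.
#' @return A tibble, one row per cell, in `cell_meta` order.
#' @export
or_cell_profiles <- function(cell_meta, norm, annotation, threshold = 50, top_k = 4,
                             unclustered = c("singleton", "exclude")) {
  unclustered <- match.arg(unclustered)
  missing <- setdiff(cell_meta$cell_id, colnames(norm))
  if (length(missing) > 0) {
    abort(sprintf("cells absent from the matrix: %s",
                  paste(utils::head(missing, 5), collapse = ", ")),
          class = "orselect_lookup_error")
  }
  ors <- or_gene_set(annotation)
  ors <- intersect(rownames(norm), ors)
  if (length(ors) == 0) abort("no OR gene present in the matrix", class = "orselect_validation_error")
  m <- norm[ors, cell_meta$cell_id, drop = FALSE]

  cc <- counting_clusters(annotation, ors, unclustered)
  active <- m >= threshold
  n_active_or <- colSums(active)
  counted <- active[cc$keep, , drop = FALSE]
  by_cluster <- rowsum(counted + 0L, cc$cluster[cc$keep])
  by_chrom <- rowsum(counted + 0L, cc$chrom[cc$keep])
  n_active_clusters <- colSums(by_cluster >= 1)
  n_active_chrom <- colSums(by_chrom >= 1)

  k <- min(top_k, length(ors))
  ranked <- apply(m, 2, function(v) {
    o <- order(-v, ors)[seq_len(k)]
    c(o, v[o])
  })
  idx <- ranked[seq_len(k), , drop = FALSE]
  val <- ranked[k + seq_len(k), , drop = FALSE]

  prof <- tibble(
    cell_id = cell_meta$cell_id,
    stage = cell_meta$stage,
    pseudotime = cell_meta$pseudotime,
    winner = unname(ifelse(val[1, ] >= threshold, ors[idx[1, ]], NA_character_)),
    winner_value = unname(val[1, ]),
    aggregate_or = unname(colSums(m)),
    n_active_or = as.integer(n_active_or),
    n_active_clusters = as.integer(n_active_clusters),
    n_active_chromosomes = as.integer(n_active_chrom),
    state = call_state(n_active_or)
  )
  if (k >= 2) {
    for (r in 2:k) {
      prof[[paste0("runnerup", r - 1)]] <- unname(ors[idx[r, ]])
      prof[[paste0("runnerup", r - 1, "_value")]] <- unname(val[r, ])
    }
  }
  attr(prof, "threshold") <- threshold
  prof
}

#' Count active clusters and chromosomes for one cell
#'
#' Distinct clusters and distinct chromosomes carrying at least one OR gene
#' expressed at `threshold` normalized counts or more in the given cell.
#'
#' @inheritParams or_cell_profiles
#' @param cell_id Cell to count.
#' @return Named integer vector `c(n_active_clusters, n_active_chromosomes)`.
#' @export
count_active <- function(norm, annotation, cell_id, threshold = 50,
                         unclustered = c("singleton", "exclude")) {
  check_cell(norm, cell_id)
  ors <- intersect(rownames(norm), or_gene_set(annotation))
  act <- ors[norm[ors, cell_id] >= threshold]
  cc <- counting_clusters(annotation, act, unclustered)
  c(n_active_clusters = length(unique(cc$cluster[cc$keep])),
    n_active_chromosomes = length(unique(cc$chrom[cc$keep])))
}

#' Cells of a stage with >= 2 active ORs in one cluster
#'
#' Counts, among cells of `stage`, those expressing at least two OR genes at
#' the activity threshold from the same annotated cluster. ORs without a
#' cluster cannot contribute (a singleton cluster never reaches two genes).
#'
#' @inheritParams or_cell_profiles
#' @param stage Stage label to restrict to (default `"Late.INP"`).
#' @return Integer count of qualifying cells.
#' @export
count_same_cluster_multis <- function(cell_meta, norm, annotation,
                                      stage = "Late.INP", threshold = 50) {
  cells <- cell_meta$cell_id[cell_meta$stage == stage]
  ors <- intersect(rownames(norm), or_gene_set(annotation))
  cl <- annotation$cluster_id[match(ors, annotation$gene_id)]
  keep <- !is.na(cl)
  if (length(cells) == 0 || !any(keep)) return(0L)
  active <- norm[ors[keep], cells, drop = FALSE] >= threshold
  per_cluster <- rowsum(active + 0L, cl[keep])
  sum(colSums(per_cluster >= 2) > 0)
}

#' Segment the lineage into silent / multigenic / monogenic phases
#'
#' The canonical segmentation is by stage: qGBC, GBC, Early.INP and Mid.INP
#' form the silent phase, Late.INP the multigenic phase, and iOSN plus mOSN
#' the monogenic phase. The optional `mode = "state"` variant instead derives
#' each cell's phase from its activity state in `profiles` (silent state ->
#' silent, multigenic -> multigenic, monogenic_like -> monogenic), reflecting
#' the observation that multigenic expression spills into early iOSN cells.
#'
#' @param cell_meta Cell metadata tibble; every stage must be one of the seven
#'   neuronal lineage stages (cells labelled otherwise raise an error naming
#'   them).
#' @param mode `"stage"` (canonical) or `"state"`.
#' @param profiles Required for `mode = "state"`: output of [or_cell_profiles()].
#' @return A tibble (`cell_id`, `stage`, `pseudotime`, `phase`) with attribute
#'   `phase_counts`; phases are ordered silent < multigenic < monogenic.
#' @export
segment_phases <- function(cell_meta, mode = c("stage", "state"), profiles = NULL) {
  mode <- match.arg(mode)
  bad <- !(cell_meta$stage %in% neuronal_stages())
  if (any(bad)) {
    abort(sprintf("cells outside the neuronal lineage: %s",
                  paste(utils::head(cell_meta$cell_id[bad], 10), collapse = ", ")),
          class = "orselect_validation_error")
  }
  if (mode == "stage") {
    stage_to_phase <- c(qGBC = "silent", GBC = "silent", Early.INP = "silent",
                        Mid.INP = "silent", Late.INP = "multigenic",
                        iOSN = "monogenic", mOSN = "monogenic")
    phase <- stage_to_phase[cell_meta$stage]
  } else {
    if (is.null(profiles)) abort("mode = \"state\" needs profiles", class = "orselect_validation_error")
    st <- profiles$state[match(cell_meta$cell_id, profiles$cell_id)]
    phase <- c(silent = "silent", multigenic = "multigenic",
               monogenic_like = "monogenic")[as.character(st)]
  }
  seg <- tibble(cell_id = cell_meta$cell_id, stage = cell_meta$stage,
                pseudotime = cell_meta$pseudotime,
                phase = factor(phase, levels = c("silent", "multigenic", "monogenic")))
  attr(seg, "phase_counts") <- table(seg$phase)
  attr(seg, "mode") <- mode
  seg
}

#' Phase cell counts of a segmentation
#' @param segmentation Output of [segment_phases()].
#' @return A tibble (`phase`, `n_cells`).
#' @export
phase_counts <- function(segmentation) {
  tab <- table(segmentation$phase)
  tibble(phase = names(tab), n_cells = as.integer(tab))
}

#' Pseudotime expression course of one gene
#'
#' The gene's normalized expression across cells, sorted by ascending
#' pseudotime with ties broken by cell id, ready for plotting.
#'
#' @inheritParams or_cell_profiles
#' @param gene_id Gene to extract.
#' @return A tibble (`cell_id`, `stage`, `pseudotime`, `value`).
#' @export
pseudotime_course <- function(cell_meta, norm, gene_id) {
  if (!gene_id %in% rownames(norm)) {
    abort(sprintf("unknown gene id: %s", gene_id), class = "orselect_lookup_error")
  }
  out <- tibble(cell_id = cell_meta$cell_id, stage = cell_meta$stage,
                pseudotime = cell_meta$pseudotime,
                value = norm[gene_id, cell_meta$cell_id])
  out[order(out$pseudotime, out$cell_id), ]
}

#' Long table of winner and runner-up values per cell
#'
#' Reshapes [or_cell_profiles()] output into one row per (cell, rank) for the
#' violin displays of winner vs runners-up along the lineage.
#'
#' @param profiles Output of [or_cell_profiles()].
#' @return A tibble (`cell_id`, `stage`, `pseudotime`, `rank_label`, `value`).
#' @export
or_rank_long <- function(profiles) {
  value_cols <- c(winner = "winner_value",
                  stats::setNames(grep("^runnerup\\d+_value$", names(profiles), value = TRUE),
                                  sub("_value$", "", grep("^runnerup\\d+_value$",
                                                          names(profiles), value = TRUE))))
  long <- tidyr::pivot_longer(
    profiles[, c("cell_id", "stage", "pseudotime", unname(value_cols))],
    cols = dplyr::all_of(unname(value_cols)),
    names_to = "rank_label", values_to = "value")
  long$rank_label <- factor(sub("_value$", "", long$rank_label),
                            levels = sub("_value$", "", unname(value_cols)))
  long
}
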
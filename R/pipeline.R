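# End-to-end analysis runner and report assembly.

#' Assemble a pipeline configuration
#'
#' Paths to the input files plus every stage parameter, with the package's
#' documented defaults (gene retention > 40 counts, detectability 35 counts in
#' 15 cells, activity threshold 50 normalized counts, DE alpha 0.05 and
#' minimum fold 2, motif scan with up to 3 mismatches).
#'
#' @param counts_mtx,genes_tsv,cells_tsv Count matrix triplet (see
#'   [read_counts()]).
#' @param cell_metadata_tsv Cell metadata TSV.
#' @param annotation_tsv Gene annotation TSV.
#' @param clusters_bed OR cluster map BED.
#' @param fasta Optional enhancer FASTA; the motif stage runs only if given.
#' @param motif_pattern IUPAC consensus to scan for.
#' @param min_gene_count,scale_target,detect_min_level,detect_min_cells,activity_threshold,alpha,min_fold,n_perm,max_mismatch
#'   Stage parameters (see the preprocessing, profiling, permutation, DE and
#'   motif functions for their meaning).
#' @param seed Integer seed driving the permutation stage.
#' @return A named list of class `or_pipeline_config`.
#' @export
pipeline_config <- function(counts_mtx, genes_tsv, cells_tsv, cell_metadata_tsv,
                            annotation_tsv, clusters_bed, fasta = NULL,
                            motif_pattern = "TYCCYWKGGGVCTHATTARM",
                            min_gene_count = 40, scale_target = "median",
                            detect_min_level = 35, detect_min_cells = 15,
                            activity_threshold = 50, alpha = 0.05, min_fold = 2,
                            n_perm = 1000, max_mismatch = 3, seed = 1) {
  cfg <- as.list(environment())
  paths <- c(counts_mtx, genes_tsv, cells_tsv, cell_metadata_tsv,
             annotation_tsv, clusters_bed, fasta)
  missing <- paths[!file.exists(paths)]
  if (length(missing) > 0) {
    abort(sprintf("input file(s) not found: %s", paste(missing, collapse = ", ")),
          class = "orselect_validation_error")
  }
  structure(cfg, class = "or_pipeline_config")
}

#' Run the full OR selection analysis
#'
#' Executes preprocessing, per-cell OR profiling and phase segmentation, the
#' within-cluster co-activation permutation test, the phase-transition DE
#' screen, and (if a FASTA is configured) the motif scan; writes the report
#' bundle (`profiles.tsv`, `phase_summary.json`, `cocluster.json`, `de.tsv`,
#' `motif_presence.tsv`, `manifest.json`) under `out_dir` and returns the
#' results invisibly. Reruns with the same inputs and seed are byte-identical.
#'
#' @param config An `or_pipeline_config` (see [pipeline_config()]).
#' @param out_dir Output directory (created if absent).
#' @return Invisibly, a list with `profiles`, `segmentation`, `cocluster`,
#'   `de`, `motif` (NULL if skipped) and `manifest`.
#' @export
run_or_pipeline <- function(config, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  counts <- read_counts(config$counts_mtx, config$genes_tsv, config$cells_tsv)
  cell_meta <- read_cell_metadata(config$cell_metadata_tsv)
  annotation <- read_gene_annotation(config$annotation_tsv)
  cluster_map <- read_cluster_map(config$clusters_bed)
  if (!"cluster_id" %in% names(annotation) || all(is.na(annotation$cluster_id))) {
    annotation <- assign_genes_to_clusters(annotation, cluster_map)
  }

  kept <- filter_genes(counts, config$min_gene_count)
  norm <- normalize_counts(kept, config$scale_target)

  profiles <- or_cell_profiles(cell_meta, norm, annotation,
                               threshold = config$activity_threshold)
  segmentation <- segment_phases(cell_meta)
  profiles$phase <- segmentation$phase[match(profiles$cell_id, segmentation$cell_id)]

  ors <- intersect(rownames(norm), or_gene_set(annotation))
  A <- binarize_activity(norm, ors, config$activity_threshold)
  ct <- cocluster_test(A, annotation, n_perm = config$n_perm, seed = config$seed)

  detectable <- detectable_genes(norm, config$detect_min_level,
                                 config$detect_min_cells)
  de_genes <- setdiff(detectable, ors)
  de <- phase_de(segmentation, norm, de_genes, alpha = config$alpha,
                 min_fold = config$min_fold)

  motif <- NULL
  if (!is.null(config$fasta)) {
    motif <- scan_motif_set(config$fasta, config$motif_pattern, config$max_mismatch)
  }

  readr::write_tsv(profiles, file.path(out_dir, "profiles.tsv"))
  phase_summary <- list(
    phase_counts = stats::setNames(as.list(phase_counts(segmentation)$n_cells),
                                   phase_counts(segmentation)$phase),
    n_cells = nrow(cell_meta),
    distributions = summarize_phase_distributions(profiles))
  jsonlite::write_json(phase_summary, file.path(out_dir, "phase_summary.json"),
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(
    list(observed = ct$observed, observed_count = ct$observed_count,
         p_value = ct$p_value, n_perm = ct$n_perm, n_trades = ct$n_trades,
         seed = config$seed, statistic_variant = ct$variant,
         null_quantiles = stats::quantile(ct$null_values, c(0.025, 0.5, 0.975))),
    file.path(out_dir, "cocluster.json"), auto_unbox = TRUE, digits = NA)
  readr::write_tsv(de, file.path(out_dir, "de.tsv"))
  if (!is.null(motif)) {
    readr::write_tsv(motif, file.path(out_dir, "motif_presence.tsv"))
  }

  manifest <- list(
    package = "orselect",
    package_version = as.character(utils::packageVersion("orselect")),
    seed = config$seed,
    parameters = config[setdiff(names(config), c("counts_mtx", "genes_tsv",
                                                 "cells_tsv", "cell_metadata_tsv",
                                                 "annotation_tsv", "clusters_bed",
                                                 "fasta"))],
    inputs = lapply(
      config[c("counts_mtx", "genes_tsv", "cells_tsv", "cell_metadata_tsv",
               "annotation_tsv", "clusters_bed", "fasta")],
      function(p) if (is.null(p)) NULL else list(path = p, md5 = unname(tools::md5sum(p)))),
    motif_stage_run = !is.null(motif))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")

  invisible(list(profiles = profiles, segmentation = segmentation,
                 cocluster = ct, de = de, motif = motif, manifest = manifest))
}

#' Per-phase frequency distributions of active clusters and chromosomes
#'
#' Histograms of `n_active_clusters` and `n_active_chromosomes` per phase.
#' In a typical lineage the silent phase piles up at zero, the multigenic
#' phase spreads over several active clusters, and the monogenic phase
#' concentrates at one.
#'
#' @param profiles Output of [or_cell_profiles()] carrying a `phase` column
#'   (added by [run_or_pipeline()], or join a segmentation yourself).
#' @return A tibble (`phase`, `metric`, `n_active`, `n_cells`).
#' @export
summarize_phase_distributions <- function(profiles) {
  if (!"phase" %in% names(profiles)) {
    abort("profiles need a phase column; join a segmentation first",
          class = "orselect_validation_error")
  }
  long <- tidyr::pivot_longer(
    profiles[, c("phase", "n_active_clusters", "n_active_chromosomes")],
    cols = c("n_active_clusters", "n_active_chromosomes"),
    names_to = "metric", values_to = "n_active")
  out <- dplyr::count(long, .data$phase, .data$metric, .data$n_active,
                      name = "n_cells")
  dplyr::arrange(out, .data$phase, .data$metric, .data$n_active)
}
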
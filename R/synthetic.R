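# Negative-binomial synthetic data emulating OR selection along the
# seven-stage OSN lineage, with ground truth for every pipeline stage.

#' Configuration for the synthetic OSN-lineage dataset
#'
#' Defaults emulate the study conditions of the analysed lineage: 295 cells
#' over seven stages (qGBC 50, GBC 38, Early.INP 26, Mid.INP 20, Late.INP 34,
#' iOSN 95, mOSN 32), 212 OR genes spread over 68 genomic clusters on 19
#' chromosomes with a skewed cluster-size distribution, near-zero OR
#' expression in the first four stages, multigenic onset in Late.INP over 2-9
#' active clusters per cell, and winner escalation with runner-up decay
#' through iOSN/mOSN. Expression magnitudes are on the normalized-count scale
#' the thresholds (50/35/40) refer to.
#'
#' @param stage_sizes Named integer vector of cells per stage.
#' @param n_or_genes,n_clusters,n_chromosomes,n_background_genes Genome layout sizes.
#' @param multigenic_active_cluster_range Inclusive range of active clusters
#'   drawn per multigenic cell.
#' @param ors_per_cluster_range Inclusive range of active ORs contributed per
#'   drawn cluster.
#' @param or_mean_multigenic Mean expression of an active OR in the multigenic
#'   phase.
#' @param winner_mean_iosn,winner_mean_mosn Winner mean in iOSN and mOSN.
#' @param runnerup_decay Multiplier applied to runner-up means per stage after
#'   Late.INP (0 = total decay).
#' @param nb_dispersion Negative-binomial size parameter (Inf = Poisson).
#' @param library_size_lognorm Numeric `c(mu, sigma)` of the log-normal
#'   per-cell library factor.
#' @param same_cluster_bias In \[0, 1\]: 0 places each cell's active ORs
#'   uniformly over the repertoire; 1 draws them all from one focal cluster.
#' @param background_mean_lognorm `c(mu, sigma)` of the per-gene base mean of
#'   background genes (constant across stages).
#' @param tf_base_mean Peak mean of the stage-profiled regulator genes.
#' @param n_tfs_per_group Number of regulator genes per temporal group (three
#'   groups: trough at Late.INP / peak at Late.INP / rise in iOSN-mOSN).
#' @param seed Integer seed; the generator is bit-reproducible from it.
#' @return A list of class `or_sim_config`.
#' @export
synthetic_config <- function(stage_sizes = c(qGBC = 50, GBC = 38, Early.INP = 26,
                                             Mid.INP = 20, Late.INP = 34,
                                             iOSN = 95, mOSN = 32),
                             n_or_genes = 212, n_clusters = 68, n_chromosomes = 19,
                             n_background_genes = 2000,
                             multigenic_active_cluster_range = c(2, 9),
                             ors_per_cluster_range = c(1, 3),
                             or_mean_multigenic = 100,
                             winner_mean_iosn = 500, winner_mean_mosn = 2000,
                             runnerup_decay = 0.1,
                             nb_dispersion = 2,
                             library_size_lognorm = c(mu = 0, sigma = 0.3),
                             same_cluster_bias = 0,
                             background_mean_lognorm = c(mu = log(20), sigma = 1.2),
                             tf_base_mean = 200, n_tfs_per_group = 3,
                             seed = 1) {
  stopifnot(all(stage_sizes >= 0),
            setequal(names(stage_sizes), neuronal_stages()),
            multigenic_active_cluster_range[1] >= 1,
            diff(multigenic_active_cluster_range) >= 0,
            ors_per_cluster_range[1] >= 1, diff(ors_per_cluster_range) >= 0,
            same_cluster_bias >= 0, same_cluster_bias <= 1,
            runnerup_decay >= 0, runnerup_decay <= 1,
            n_clusters <= n_or_genes || n_or_genes >= 1)
  structure(as.list(environment()), class = "or_sim_config")
}

#' Generate a synthetic genome layout
#'
#' Places `n_clusters` non-overlapping OR clusters on `n_chromosomes`
#' chromosomes, distributes the OR genes over clusters with a skewed
#' (geometric-weight) size distribution so that a few clusters are large and
#' many are small, and scatters background and regulator genes outside the
#' clusters. Coordinates are 0-based half-open.
#'
#' @param config An `or_sim_config` (see [synthetic_config()]).
#' @return A list with `annotation` (gene tibble, `cluster_id` filled for ORs)
#'   and `cluster_map` (BED-style tibble).
#' @export
make_genome_layout <- function(config) {
  set.seed(config$seed)
  nC <- config$n_clusters
  nO <- config$n_or_genes
  chroms <- paste0("chr", seq_len(config$n_chromosomes))

  # skewed cluster sizes: one OR guaranteed per cluster, remainder multinomial
  # with geometric weights
  w <- 0.7^(seq_len(nC) - 1)
  extra <- if (nO > nC) as.vector(stats::rmultinom(1, nO - nC, prob = sample(w))) else 0
  sizes <- pmin(rep(1, nC) + extra, nO)

  cluster_chrom <- sort(sample(rep_len(seq_len(config$n_chromosomes), nC)))
  cluster_map <- dplyr::bind_rows(lapply(split(seq_len(nC), cluster_chrom), function(idx) {
    width <- 20000L * sizes[idx] + 10000L
    start <- cumsum(c(0L, width[-length(width)] + 50000L))
    tibble(cluster_id = sprintf("orc%02d", idx),
           chrom = chroms[cluster_chrom[idx]],
           start = start, end = start + width)
  }))
  cluster_map <- new_cluster_map(cluster_map$cluster_id, cluster_map$chrom,
                                 cluster_map$start, cluster_map$end)

  or_rows <- purrr::map_dfr(seq_len(nrow(cluster_map)), function(i) {
    k <- sizes[match(cluster_map$cluster_id[i], sprintf("orc%02d", seq_len(nC)))]
    start <- cluster_map$start[i] + 5000L + 20000L * (seq_len(k) - 1L)
    tibble(chrom = cluster_map$chrom[i], start = start, end = start + 1000L,
           cluster_id = cluster_map$cluster_id[i])
  })
  or_rows <- or_rows[seq_len(nO), ]
  or_rows$gene_id <- sprintf("Olfr%04d", seq_len(nO))

  n_tf <- 3 * config$n_tfs_per_group
  n_bg <- config$n_background_genes
  other <- tibble(
    gene_id = c(sprintf("tf_g%d_%d", rep(1:3, each = config$n_tfs_per_group),
                        rep(seq_len(config$n_tfs_per_group), 3)),
                sprintf("bg%04d", seq_len(n_bg))),
    chrom = rep_len(chroms, n_tf + n_bg),
    start = 5000000L + 2000L * seq_len(n_tf + n_bg))
  other$end <- other$start + 1000L
  other$cluster_id <- NA_character_

  annotation <- dplyr::bind_rows(
    tibble(gene_id = or_rows$gene_id, chrom = or_rows$chrom, start = or_rows$start,
           end = or_rows$end, strand = "+", is_or = TRUE, cluster_id = or_rows$cluster_id),
    tibble(gene_id = other$gene_id, chrom = other$chrom, start = other$start,
           end = other$end, strand = "+", is_or = FALSE, cluster_id = other$cluster_id))
  list(annotation = annotation, cluster_map = cluster_map)
}

# sample integers uniformly from [a, b] without base sample()'s scalar trap
sample_int_range <- function(a, b, n = 1) {
  if (a == b) rep(a, n) else sample(seq(a, b), n, replace = TRUE)
}

# stage multipliers of the three regulator time-course groups
tf_group_shapes <- function() {
  rbind(g1 = c(1, 1, 0.8, 0.5, 0.05, 0.3, 0.6),   # trough at Late.INP
        g2 = c(0.05, 0.1, 0.3, 0.6, 1, 0.3, 0.1), # peak at Late.INP
        g3 = c(0.02, 0.02, 0.05, 0.05, 0.1, 0.6, 1)) # rise in iOSN/mOSN
}

draw_active_set <- function(config, annotation_or, n_active) {
  ors <- annotation_or$gene_id
  n_active <- min(n_active, length(ors))
  bias <- config$same_cluster_bias
  if (bias <= 0) return(sample(ors, n_active))
  tab <- table(annotation_or$cluster_id)
  eligible <- names(tab)[tab >= 2]
  if (length(eligible) == 0) return(sample(ors, n_active))
  focal <- sample(eligible, 1, prob = as.integer(tab[eligible]))
  focal_genes <- ors[annotation_or$cluster_id == focal]
  n_focal <- min(sum(stats::runif(n_active) < bias), length(focal_genes))
  picked <- if (n_focal > 0) sample(focal_genes, n_focal) else character(0)
  rest <- setdiff(ors, picked)
  c(picked, if (n_active > n_focal) sample(rest, n_active - n_focal))
}

#' Simulate a synthetic OSN-lineage count matrix with ground truth
#'
#' Cells are emitted in stage order with noiseless pseudotime increasing
#' uniformly on \[0, 1\]. OR means are zero through Mid.INP; each Late.INP cell
#' activates ORs (count set by drawing 2-9 clusters x 1-3 ORs each, placement
#' controlled by `same_cluster_bias`) at the multigenic mean; each iOSN/mOSN
#' cell carries one programmed winner (drawn uniformly from its own
#' multigenic-style active set) at an escalating mean while its runners-up
#' decay geometrically per stage. Regulator genes follow the three temporal
#' group shapes; background genes are flat. Counts are negative-binomial
#' around the programmed means after a per-cell log-normal library factor.
#'
#' @param config An `or_sim_config`.
#' @param layout Optional pre-built layout from [make_genome_layout()];
#'   rebuilt from `config` if omitted.
#' @return A list of class `or_sim`: `counts` (integer matrix), `cell_meta`,
#'   `annotation`, `cluster_map`, and `truth` (per-cell tibble with phase,
#'   programmed winner and active set, plus `mean_matrix` used before noise).
#' @export
simulate_counts <- function(config, layout = NULL) {
  if (is.null(layout)) layout <- make_genome_layout(config)
  set.seed(config$seed + 1L)
  ann <- layout$annotation
  stages <- neuronal_stages()
  sizes <- config$stage_sizes[stages]
  n_cells <- sum(sizes)
  cell_stage <- rep(stages, times = sizes)
  cell_meta <- tibble(cell_id = sprintf("cell_%03d", seq_len(n_cells)),
                      stage = cell_stage,
                      pseudotime = (seq_len(n_cells) - 0.5) / n_cells)

  genes <- ann$gene_id
  mu <- matrix(0, nrow = length(genes), ncol = n_cells,
               dimnames = list(genes, cell_meta$cell_id))

  # background genes: flat per-gene base mean
  bg <- grep("^bg", genes, value = TRUE)
  bg_mean <- stats::rlnorm(length(bg), config$background_mean_lognorm[1],
                           config$background_mean_lognorm[2])
  mu[bg, ] <- matrix(bg_mean, length(bg), n_cells)

  # regulator genes: group shapes by stage
  shapes <- tf_group_shapes()
  stage_idx <- match(cell_stage, stages)
  for (g in 1:3) {
    tfs <- grep(sprintf("^tf_g%d_", g), genes, value = TRUE)
    if (length(tfs) > 0) {
      mu[tfs, ] <- matrix(rep(config$tf_base_mean * shapes[g, stage_idx],
                              each = length(tfs)), length(tfs), n_cells)
    }
  }

  # OR genes
  ann_or <- ann[ann$is_or, ]
  kr <- config$multigenic_active_cluster_range
  mr <- config$ors_per_cluster_range
  truth <- vector("list", n_cells)
  for (ci in seq_len(n_cells)) {
    st <- cell_stage[ci]
    if (!st %in% c("Late.INP", "iOSN", "mOSN")) {
      truth[[ci]] <- list(winner = NA_character_, active = character(0))
      next
    }
    k <- sample_int_range(kr[1], kr[2])
    n_active <- sum(sample_int_range(mr[1], mr[2], k))
    act <- draw_active_set(config, ann_or, n_active)
    if (st == "Late.INP") {
      mu[act, ci] <- config$or_mean_multigenic
      truth[[ci]] <- list(winner = NA_character_, active = act)
    } else {
      winner <- sample(act, 1)
      decay_pow <- if (st == "iOSN") 1 else 2
      ru_mean <- config$or_mean_multigenic * config$runnerup_decay^decay_pow
      mu[setdiff(act, winner), ci] <- ru_mean
      mu[winner, ci] <- if (st == "iOSN") config$winner_mean_iosn else config$winner_mean_mosn
      truth[[ci]] <- list(
        winner = winner,
        active = union(winner, if (ru_mean >= 50) setdiff(act, winner) else character(0)))
    }
  }

  lib <- stats::rlnorm(n_cells, config$library_size_lognorm[1],
                       config$library_size_lognorm[2])
  mu_noisy <- sweep(mu, 2, lib, `*`)
  counts <- if (is.infinite(config$nb_dispersion)) {
    stats::rpois(length(mu_noisy), lambda = mu_noisy)
  } else {
    stats::rnbinom(length(mu_noisy), mu = mu_noisy, size = config$nb_dispersion)
  }
  counts <- matrix(as.integer(counts), nrow(mu), ncol(mu), dimnames = dimnames(mu))

  cl_of <- function(act) unique(ann_or$cluster_id[ann_or$gene_id %in% act])
  truth_tbl <- tibble(
    cell_id = cell_meta$cell_id,
    stage = cell_stage,
    phase = c(qGBC = "silent", GBC = "silent", Early.INP = "silent",
              Mid.INP = "silent", Late.INP = "multigenic",
              iOSN = "monogenic", mOSN = "monogenic")[cell_stage],
    winner = purrr::map_chr(truth, "winner"),
    active_or = purrr::map(truth, "active"),
    active_clusters = purrr::map(truth, function(t) cl_of(t$active)))

  structure(list(counts = counts, cell_meta = cell_meta,
                 annotation = ann, cluster_map = layout$cluster_map,
                 truth = truth_tbl, mean_matrix = mu, config = config),
            class = "or_sim")
}

#' Simulate a dataset with null (uniform) OR placement
#'
#' Convenience wrapper: same generator with `same_cluster_bias = 0`, so each
#' cell's active ORs are placed uniformly over the repertoire given the
#' per-cell activity counts. Under this null the fixed-margin permutation
#' p-values are calibrated.
#'
#' @inheritParams simulate_counts
#' @return An `or_sim` (see [simulate_counts()]).
#' @export
plant_null_dataset <- function(config, layout = NULL) {
  config$same_cluster_bias <- 0
  simulate_counts(config, layout)
}

#' @export
print.or_sim <- function(x, ...) {
  cat(sprintf("Synthetic OSN-lineage dataset: %d genes x %d cells (%d OR genes, %d clusters)\n",
              nrow(x$counts), ncol(x$counts), sum(x$annotation$is_or),
              nrow(x$cluster_map)))
  invisible(x)
}

#' Write a simulated dataset to disk in the pipeline's input formats
#'
#' Writes `counts.mtx` + `genes.tsv` + `cells.tsv`, `cell_metadata.tsv`,
#' `annotation.tsv`, `clusters.bed` and `truth.json` under `dir`.
#'
#' @param sim An `or_sim`.
#' @param dir Output directory.
#' @return Invisibly, `dir`.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_counts(sim$counts, dir)
  readr::write_tsv(sim$cell_meta, file.path(dir, "cell_metadata.tsv"))
  readr::write_tsv(sim$annotation, file.path(dir, "annotation.tsv"))
  write_cluster_map(sim$cluster_map, file.path(dir, "clusters.bed"))
  truth <- sim$truth
  truth$active_or <- purrr::map(truth$active_or, as.character)
  truth$active_clusters <- purrr::map(truth$active_clusters, as.character)
  jsonlite::write_json(truth, file.path(dir, "truth.json"), auto_unbox = FALSE)
  invisible(dir)
}
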
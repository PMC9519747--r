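test_that("default configuration reproduces the lineage conditions", {
  cfg <- synthetic_config()
  expect_identical(sum(cfg$stage_sizes), 295)
  expect_identical(cfg$n_or_genes, 212)
  expect_identical(cfg$n_clusters, 68)
  expect_error(synthetic_config(same_cluster_bias = 2))
})

test_that("genome layout is valid and recoverable through interval assignment", {
  cfg <- synthetic_config(seed = 3)
  layout <- make_genome_layout(cfg)
  map <- layout$cluster_map
  expect_identical(nrow(map), 68L)
  # map passes its own invariants when rebuilt from a BED round-trip
  d <- withr::local_tempdir()
  write_cluster_map(map, file.path(d, "c.bed"))
  expect_identical(read_cluster_map(file.path(d, "c.bed")), map)
  ann <- layout$annotation
  expect_identical(sum(ann$is_or), 212L)
  expect_true(all(!is.na(ann$cluster_id[ann$is_or])))
  expect_true(all(is.na(ann$cluster_id[!ann$is_or])))
  # interval assignment recovers the emitted gene-to-cluster map exactly
  rec <- assign_genes_to_clusters(ann[, setdiff(names(ann), "cluster_id")], map)
  expect_identical(rec$cluster_id[rec$is_or], ann$cluster_id[ann$is_or])
  # degenerate layout: one cluster holds every OR on one chromosome
  one <- make_genome_layout(synthetic_config(n_or_genes = 10, n_clusters = 1,
                                             n_background_genes = 5, seed = 2))
  expect_identical(unique(one$annotation$cluster_id[one$annotation$is_or]), "orc01")
  expect_identical(length(unique(one$annotation$chrom[one$annotation$is_or])), 1L)
})

test_that("simulation is reproducible and satisfies the count-matrix contract", {
  cfg <- synthetic_config(seed = 5)
  s1 <- simulate_counts(cfg)
  s2 <- simulate_counts(cfg)
  expect_identical(s1$counts, s2$counts)
  expect_identical(s1$truth, s2$truth)
  expect_true(all(s1$counts >= 0))
  expect_identical(storage.mode(s1$counts), "integer")
  expect_identical(ncol(s1$counts), 295L)
  expect_identical(s1$cell_meta$stage, rep(neuronal_stages(), cfg$stage_sizes[neuronal_stages()]))
  expect_true(all(diff(s1$cell_meta$pseudotime) > 0))
  # ground truth respects the chromosome <= cluster <= active chain at mean level
  ann_or <- s1$annotation[s1$annotation$is_or, ]
  for (i in which(s1$truth$phase != "silent")) {
    act <- s1$truth$active_or[[i]]
    cls <- s1$truth$active_clusters[[i]]
    chr <- unique(ann_or$chrom[match(cls, ann_or$cluster_id)])
    chr <- unique(ann_or$chrom[ann_or$cluster_id %in% cls])
    expect_lte(length(chr), length(cls))
    expect_lte(length(cls), length(act))
  }
  # silent stages carry zero OR mean
  silent_cells <- s1$cell_meta$cell_id[s1$cell_meta$stage %in%
                                         c("qGBC", "GBC", "Early.INP", "Mid.INP")]
  expect_true(all(s1$mean_matrix[ann_or$gene_id, silent_cells] == 0))
})

test_that("the Poisson, fixed-library limit recovers the programmed means", {
  cfg <- synthetic_config(
    stage_sizes = c(qGBC = 0, GBC = 0, Early.INP = 0, Mid.INP = 0,
                    Late.INP = 0, iOSN = 0, mOSN = 400),
    n_or_genes = 10, n_clusters = 2, n_background_genes = 3,
    nb_dispersion = Inf, library_size_lognorm = c(0, 0), seed = 8)
  sim <- simulate_counts(cfg)
  bg <- grep("^bg", rownames(sim$counts), value = TRUE)
  for (g in bg) {
    mu <- sim$mean_matrix[g, 1]
    se <- sqrt(mu / ncol(sim$counts))
    expect_lt(abs(mean(sim$counts[g, ]) - mu), 3 * se + 1e-9)
  }
})

test_that("total runner-up decay leaves exactly one programmed OR per mOSN cell", {
  cfg <- synthetic_config(
    stage_sizes = c(qGBC = 0, GBC = 0, Early.INP = 0, Mid.INP = 0,
                    Late.INP = 0, iOSN = 0, mOSN = 30),
    n_or_genes = 40, n_clusters = 8, n_background_genes = 10,
    runnerup_decay = 0, seed = 13)
  sim <- simulate_counts(cfg)
  ors <- sim$annotation$gene_id[sim$annotation$is_or]
  per_cell <- colSums(sim$mean_matrix[ors, ] > 0)
  expect_true(all(per_cell == 1))
})

test_that("null placement emits activity margins matching the ground truth", {
  sim <- plant_null_dataset(experiment_config(seed = 17))
  truth_active <- sim$truth$active_or
  # programmed (pre-noise) activity at the 50-count threshold equals truth sets
  act_mean <- sim$mean_matrix[sim$annotation$gene_id[sim$annotation$is_or], ] >= 50
  for (i in seq_along(truth_active)) {
    expect_setequal(rownames(act_mean)[act_mean[, i]], truth_active[[i]])
  }
})

test_that("written simulations read back identically", {
  cfg <- synthetic_config(n_or_genes = 12, n_clusters = 4, n_background_genes = 8,
                          stage_sizes = c(qGBC = 3, GBC = 2, Early.INP = 2,
                                          Mid.INP = 2, Late.INP = 4, iOSN = 4,
                                          mOSN = 3),
                          seed = 23)
  sim <- simulate_counts(cfg)
  d <- withr::local_tempdir()
  write_simulation(sim, d)
  back <- read_counts(file.path(d, "counts.mtx"), file.path(d, "genes.tsv"),
                      file.path(d, "cells.tsv"))
  expect_identical(back, sim$counts)
  expect_identical(read_cell_metadata(file.path(d, "cell_metadata.tsv")), sim$cell_meta)
  expect_identical(read_cluster_map(file.path(d, "clusters.bed")), sim$cluster_map)
  ann <- read_gene_annotation(file.path(d, "annotation.tsv"))
  expect_identical(ann$cluster_id, sim$annotation$cluster_id)
})
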
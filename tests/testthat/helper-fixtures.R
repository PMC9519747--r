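# Small fixtures built in code.

toy_annotation <- function() {
  tibble::tibble(
    gene_id = c("OrA", "OrB", "OrC", "OrD", "OrE"),
    chrom = c("chr1", "chr1", "chr1", "chr2", "chr2"),
    start = c(150L, 180L, 400L, 100L, 5000L),
    end = c(160L, 190L, 410L, 110L, 5010L),
    strand = "+",
    is_or = TRUE,
    cluster_id = c("c1", "c1", "c2", "c3", NA))
}

toy_cluster_map <- function() {
  tibble::tibble(cluster_id = c("c1", "c2", "c3"),
                 chrom = c("chr1", "chr1", "chr2"),
                 start = c(100L, 300L, 50L),
                 end = c(200L, 500L, 150L))
}

# norm-scale matrix with known activity structure (threshold 50)
toy_norm <- function() {
  m <- rbind(OrA = c(500, 60, 0),
             OrB = c(0, 55, 0),
             OrC = c(60, 0, 0),
             OrD = c(55, 0, 49),
             OrE = c(0, 0, 0))
  colnames(m) <- c("cellX", "cellY", "cellZ")
  m
}

toy_cell_meta <- function() {
  tibble::tibble(cell_id = c("cellX", "cellY", "cellZ"),
                 stage = c("Late.INP", "Late.INP", "qGBC"),
                 pseudotime = c(0.6, 0.7, 0.1))
}

write_toy_mtx <- function(dir, values, gene_ids, cell_ids) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  nz <- which(values != 0, arr.ind = TRUE)
  lines <- c("%%MatrixMarket matrix coordinate integer general",
             paste(nrow(values), ncol(values), nrow(nz)),
             paste(nz[, 1], nz[, 2], values[nz]))
  writeLines(lines, file.path(dir, "m.mtx"))
  writeLines(gene_ids, file.path(dir, "g.tsv"))
  writeLines(cell_ids, file.path(dir, "c.tsv"))
  file.path(dir, c("m.mtx", "g.tsv", "c.tsv"))
}

# reduced-scale generator config for permutation experiments: 30 multigenic
# cells, 60 ORs in 10 clusters
experiment_config <- function(seed, bias = 0) {
  synthetic_config(
    stage_sizes = c(qGBC = 0, GBC = 0, Early.INP = 0, Mid.INP = 0,
                    Late.INP = 30, iOSN = 0, mOSN = 0),
    n_or_genes = 60, n_clusters = 10, n_chromosomes = 5,
    n_background_genes = 50, same_cluster_bias = bias, seed = seed)
}

activity_from_sim <- function(sim, threshold = 50) {
  norm <- normalize_counts(filter_genes(sim$counts))
  ors <- intersect(rownames(norm), sim$annotation$gene_id[sim$annotation$is_or])
  binarize_activity(norm, ors, threshold)
}
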
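#' @useDynLib orselect, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom rlang .data abort warn %||%
#' @import tibble
NULL

# ---- validation helpers -----------------------------------------------------

validate_ids <- function(ids, what) {
  ids <- as.character(ids)
  if (anyNA(ids) || any(ids == "")) {
    abort(sprintf("%s contains missing or empty ids", what), class = "orselect_format_error")
  }
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0) {
    abort(sprintf("duplicate %s: %s", what, paste(utils::head(dup, 5), collapse = ", ")),
          class = "orselect_validation_error")
  }
  ids
}

validate_counts <- function(values, gene_ids, cell_ids) {
  if (nrow(values) != length(gene_ids) || ncol(values) != length(cell_ids)) {
    abort(sprintf(
      "count matrix is %d x %d but %d gene ids and %d cell ids were supplied",
      nrow(values), ncol(values), length(gene_ids), length(cell_ids)),
      class = "orselect_format_error")
  }
  if (anyNA(values)) abort("count matrix contains NA", class = "orselect_validation_error")
  if (any(values < 0)) abort("count matrix contains negative entries", class = "orselect_validation_error")
  if (any(values != floor(values))) {
    abort("count matrix contains non-integer entries", class = "orselect_validation_error")
  }
  invisible(values)
}

# ---- counts -----------------------------------------------------------------

#' Read a genes x cells count matrix
#'
#' Reads raw counts either from a MatrixMarket coordinate file plus one-id-per-line
#' gene and cell name files (the 10x-style `matrix.mtx` / `genes.tsv` / `cells.tsv`
#' triplet), or from a dense TSV with gene ids in the first column and cell ids in
#' the header. Sparse zeros are materialised, so the result is always a dense
#' integer matrix with gene ids as rownames and cell ids as colnames.
#'
#' @param matrix_path Path to a `.mtx` MatrixMarket file or a dense TSV.
#' @param genes_path,cells_path Name files (one id per line); required for MTX
#'   input, ignored for dense TSV.
#' @return An integer matrix (genes x cells) with unique dimnames.
#' @export
read_counts <- function(matrix_path, genes_path = NULL, cells_path = NULL) {
  if (grepl("\\.mtx$", matrix_path, ignore.case = TRUE)) {
    if (is.null(genes_path) || is.null(cells_path)) {
      abort("MTX input needs genes_path and cells_path", class = "orselect_format_error")
    }
    m <- as.matrix(Matrix::readMM(matrix_path))
    gene_ids <- validate_ids(readLines(genes_path), "gene ids")
    cell_ids <- validate_ids(readLines(cells_path), "cell ids")
  } else {
    tab <- readr::read_tsv(matrix_path, col_types = readr::cols(), progress = FALSE)
    gene_ids <- validate_ids(tab[[1]], "gene ids")
    m <- as.matrix(tab[, -1, drop = FALSE])
    cell_ids <- validate_ids(colnames(m), "cell ids")
  }
  validate_counts(m, gene_ids, cell_ids)
  storage.mode(m) <- "integer"
  dimnames(m) <- list(gene_ids, cell_ids)
  m
}

#' Write a count matrix as MTX + name files
#'
#' Inverse of [read_counts()]: writes `counts.mtx`, `genes.tsv` and `cells.tsv`
#' into `dir`. Round-tripping through [read_counts()] reproduces the matrix
#' bit-exactly.
#'
#' @param counts Integer matrix with dimnames.
#' @param dir Output directory (created if absent).
#' @return Invisibly, the paths written.
#' @export
write_counts <- function(counts, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("counts.mtx", "genes.tsv", "cells.tsv"))
  Matrix::writeMM(methods::as(Matrix::Matrix(counts, sparse = TRUE), "generalMatrix"), paths[1])
  writeLines(rownames(counts), paths[2])
  writeLines(colnames(counts), paths[3])
  invisible(paths)
}

# ---- cluster map ------------------------------------------------------------

new_cluster_map <- function(cluster_id, chrom, start, end) {
  map <- tibble(cluster_id = as.character(cluster_id), chrom = as.character(chrom),
                start = as.integer(start), end = as.integer(end))
  validate_ids(map$cluster_id, "cluster ids")
  if (any(map$start >= map$end)) {
    abort("cluster intervals must satisfy start < end (0-based half-open)",
          class = "orselect_validation_error")
  }
  # non-overlap within chromosome
  by_chr <- split(map, map$chrom)
  for (ch in by_chr) {
    o <- order(ch$start)
    if (any(ch$start[o][-1] < ch$end[o][-nrow(ch)])) {
      abort(sprintf("overlapping cluster intervals on %s", ch$chrom[1]),
            class = "orselect_validation_error")
    }
  }
  map
}

#' Read an OR cluster map from BED
#'
#' BED3+ (chrom, start, end, name), 0-based half-open. The optional name column
#' is used as `cluster_id`; if absent, ids `cluster_1..n` are generated in file
#' order. Intervals on a chromosome must not overlap.
#'
#' @param bed_path Path to a BED file (no header).
#' @return A tibble with columns `cluster_id`, `chrom`, `start`, `end`.
#' @export
read_cluster_map <- function(bed_path) {
  bed <- readr::read_tsv(bed_path, col_names = FALSE, col_types = readr::cols(.default = "c"),
                         comment = "#")
  if (ncol(bed) < 3) abort("BED needs at least 3 columns", class = "orselect_format_error")
  ids <- if (ncol(bed) >= 4) bed[[4]] else paste0("cluster_", seq_len(nrow(bed)))
  new_cluster_map(ids, bed[[1]], as.integer(bed[[2]]), as.integer(bed[[3]]))
}

#' Write an OR cluster map as BED
#' @param map Cluster map tibble as returned by [read_cluster_map()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_cluster_map <- function(map, path) {
  readr::write_tsv(map[, c("chrom", "start", "end", "cluster_id")], path, col_names = FALSE)
  invisible(path)
}

# ---- gene annotation and cell metadata --------------------------------------

#' Read a gene annotation table
#'
#' TSV with header columns `gene_id`, `chrom`, `start`, `end`, `strand`,
#' `is_or` (and optionally `cluster_id`). Coordinates are 0-based half-open;
#' convert 1-based inputs by subtracting 1 from the start before calling.
#'
#' @param path Path to the TSV.
#' @return A tibble, one row per gene.
#' @export
read_gene_annotation <- function(path) {
  ann <- readr::read_tsv(path, col_types = readr::cols(
    gene_id = "c", chrom = "c", start = "i", end = "i", strand = "c",
    is_or = readr::col_logical(), .default = "c"))
  validate_ids(ann$gene_id, "gene ids")
  if (any(ann$start >= ann$end)) {
    abort("gene intervals must satisfy start < end", class = "orselect_validation_error")
  }
  if (!all(ann$strand %in% c("+", "-"))) {
    abort("strand must be '+' or '-'", class = "orselect_validation_error")
  }
  ann
}

#' Read per-cell metadata (stage and pseudotime)
#'
#' TSV with header columns `cell_id`, `stage`, `pseudotime`. Stages must come
#' from the closed lineage vocabulary (see [neuronal_stages()], plus `"other"`)
#' and pseudotime must lie in \[0, 1\].
#'
#' @param path Path to the TSV.
#' @return A tibble, one row per cell.
#' @export
read_cell_metadata <- function(path) {
  cm <- readr::read_tsv(path, col_types = readr::cols(
    cell_id = "c", stage = "c", pseudotime = "d", .default = "c"))
  validate_cell_metadata(cm)
}

validate_cell_metadata <- function(cm) {
  validate_ids(cm$cell_id, "cell ids")
  bad <- setdiff(unique(cm$stage), c(neuronal_stages(), "other"))
  if (length(bad) > 0) {
    abort(sprintf("unknown stage label(s): %s", paste(bad, collapse = ", ")),
          class = "orselect_validation_error")
  }
  if (anyNA(cm$pseudotime) || any(cm$pseudotime < 0 | cm$pseudotime > 1)) {
    abort("pseudotime must lie in [0, 1]", class = "orselect_validation_error")
  }
  cm
}

#' The neuronal lineage stage vocabulary, in differentiation order
#'
#' Quiescent globose basal cells through mature olfactory sensory neurons.
#' @return Character vector of the seven stage labels.
#' @export
neuronal_stages <- function() {
  c("qGBC", "GBC", "Early.INP", "Mid.INP", "Late.INP", "iOSN", "mOSN")
}

# ---- gene-to-cluster assignment ---------------------------------------------

#' Assign genes to OR clusters by start position
#'
#' A gene belongs to the cluster whose half-open interval contains the gene's
#' start coordinate; genes whose start falls in no interval (or whose
#' chromosome is absent from the map) get `cluster_id = NA`. Membership by
#' start position makes the assignment deterministic and independent of record
#' order even for genes straddling an interval edge.
#'
#' @param annotation Gene annotation tibble (see [read_gene_annotation()]).
#' @param map Cluster map tibble (see [read_cluster_map()]).
#' @return `annotation` with a `cluster_id` column filled (NA where unassigned).
#' @export
assign_genes_to_clusters <- function(annotation, map) {
  genes <- GenomicRanges::GRanges(annotation$chrom,
                                  IRanges::IRanges(annotation$start + 1L, width = 1L))
  clust <- GenomicRanges::GRanges(map$chrom, IRanges::IRanges(map$start + 1L, map$end))
  # absent chromosomes simply yield no hit; the seqlevel mismatch is expected
  hits <- suppressWarnings(GenomicRanges::findOverlaps(genes, clust))
  cluster_id <- rep(NA_character_, nrow(annotation))
  cluster_id[S4Vectors::queryHits(hits)] <- map$cluster_id[S4Vectors::subjectHits(hits)]
  annotation$cluster_id <- cluster_id
  annotation
}
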
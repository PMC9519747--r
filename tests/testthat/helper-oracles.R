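# Independent oracles: deliberately naive implementations used only to verify
# the package's vectorised/compiled code paths.

# All binary matrices with the given row and column sums, by exhaustive
# recursion over rows (feasible up to ~5x5).
enumerate_fiber <- function(row_sums, col_sums) {
  n_col <- length(col_sums)
  out <- list()
  recurse <- function(filled, remaining_cols, row_idx) {
    if (row_idx > length(row_sums)) {
      if (all(remaining_cols == 0)) out[[length(out) + 1]] <<- filled
      return(invisible(NULL))
    }
    r <- row_sums[row_idx]
    if (r == 0) {
      filled <- rbind(filled, rep(0L, n_col))
      return(recurse(filled, remaining_cols, row_idx + 1))
    }
    candidates <- which(remaining_cols > 0)
    if (length(candidates) < r) return(invisible(NULL))
    picks <- utils::combn(candidates, r, simplify = FALSE)
    for (p in picks) {
      row <- rep(0L, n_col); row[p] <- 1L
      rc <- remaining_cols; rc[p] <- rc[p] - 1L
      recurse(rbind(filled, row), rc, row_idx + 1)
    }
  }
  recurse(matrix(0L, 0, n_col), as.integer(col_sums), 1)
  out
}

# per-cell tally of the co-activation frequency statistic, plain loops
oracle_cocluster_frequency <- function(A, clusters) {
  fs <- c()
  for (j in seq_len(ncol(A))) {
    act <- which(A[, j] > 0)
    if (length(act) == 0) next
    tab <- table(clusters[act])
    fs <- c(fs, sum(tab >= 2) / sum(tab >= 1))
  }
  if (length(fs) == 0) stop("undefined")
  mean(fs)
}

# two-sided exact Wilcoxon p by enumeration over all C(n+m, n) group splits
oracle_wilcoxon_p <- function(x, y) {
  pooled <- c(x, y)
  n <- length(x)
  u_of <- function(xi) {
    xs <- pooled[xi]; ys <- pooled[-xi]
    sum(outer(xs, ys, ">")) + 0.5 * sum(outer(xs, ys, "=="))
  }
  u_obs <- u_of(seq_len(n))
  us <- apply(utils::combn(length(pooled), n), 2, u_of)
  p <- 2 * min(mean(us <= u_obs + 1e-9), mean(us >= u_obs - 1e-9))
  min(1, p)
}

# naive window-by-window IUPAC scan of one strand
IUPAC_ORACLE <- list(A = "A", C = "C", G = "G", T = "T",
                     R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
                     W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
                     B = c("C", "G", "T"), D = c("A", "G", "T"),
                     H = c("A", "C", "T"), V = c("A", "C", "G"),
                     N = c("A", "C", "G", "T", "N"))

oracle_scan_strand <- function(sequence, pattern, max_mismatch) {
  sc <- strsplit(sequence, "")[[1]]
  pc <- strsplit(pattern, "")[[1]]
  hits <- data.frame(position = integer(0), mismatches = integer(0))
  if (length(sc) < length(pc)) return(hits)
  for (start in 1:(length(sc) - length(pc) + 1)) {
    mm <- 0
    for (k in seq_along(pc)) {
      if (pc[k] == "N") next
      if (!(sc[start + k - 1] %in% IUPAC_ORACLE[[pc[k]]])) mm <- mm + 1
    }
    if (mm <= max_mismatch) {
      hits <- rbind(hits, data.frame(position = start - 1L, mismatches = mm))
    }
  }
  hits
}

oracle_scan <- function(sequence, pattern, max_mismatch) {
  fwd <- oracle_scan_strand(sequence, pattern, max_mismatch)
  rev_ <- oracle_scan_strand(sequence, reverse_complement_iupac(pattern), max_mismatch)
  out <- rbind(cbind(fwd, strand = rep("+", nrow(fwd))),
               cbind(rev_, strand = rep("-", nrow(rev_))))
  out[order(out$position, out$strand), c("position", "strand", "mismatches")]
}

random_dna <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}
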
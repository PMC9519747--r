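test_that("OR ranking sorts descending with lexicographic tie-break", {
  m <- rbind(A = 500, B = 60, C = 55, D = 10, E = 5)
  m <- cbind(m, 0); colnames(m) <- c("c1", "c2")
  r <- rank_or_genes(m, rownames(m), "c1")
  expect_identical(r$gene_id, c("A", "B", "C", "D"))
  expect_identical(attr(r, "winner"), "A")
  # winner tie at the threshold broken lexicographically
  tie <- rbind(B2 = 50, A2 = 50); colnames(tie) <- "c"
  r2 <- rank_or_genes(tie, rownames(tie), "c")
  expect_identical(attr(r2, "winner"), "A2")
  # single expressed OR: remaining ranks padded with zero genes, lexicographic
  solo <- rbind(Z = 0, M = 80, A = 0, B = 0); colnames(solo) <- "c"
  r3 <- rank_or_genes(solo, rownames(solo), "c")
  expect_identical(r3$gene_id, c("M", "A", "B", "Z"))
  expect_identical(attr(r3, "winner"), "M")
  expect_error(rank_or_genes(m, rownames(m), "nope"), class = "orselect_lookup_error")
})

test_that("aggregate OR expression matches independent summation", {
  m <- toy_norm()
  expect_equal(aggregate_or_expression(m, rownames(m), "cellX"), 500 + 60 + 55)
  expect_equal(aggregate_or_expression(m, rownames(m), "cellZ"), 49)
  set.seed(3)
  r <- matrix(runif(10) * 100, 10, 1, dimnames = list(paste0("o", 1:10), "c"))
  expect_equal(aggregate_or_expression(r, rownames(r), "c"),
               sum(sapply(1:10, function(i) r[i, 1])))
})

test_that("state calls are silent / monogenic_like / multigenic at the inclusive threshold", {
  m <- rbind(A = c(49.9, 50, 50), B = c(49.9, 0, 50)); colnames(m) <- c("s", "m1", "m2")
  n_act <- colSums(m >= 50)
  expect_identical(as.character(call_state(n_act)),
                   c("silent", "monogenic_like", "multigenic"))
})

test_that("active cluster and chromosome counting follows the annotation", {
  ann <- toy_annotation()
  m <- toy_norm()
  # cellX: active OrA (c1, chr1), OrC (c2, chr1), OrD (c3, chr2)
  expect_identical(count_active(m, ann, "cellX"),
                   c(n_active_clusters = 3L, n_active_chromosomes = 2L))
  # cellY: OrA and OrB both in c1
  expect_identical(count_active(m, ann, "cellY"),
                   c(n_active_clusters = 1L, n_active_chromosomes = 1L))
  # cellZ: 49 < 50, nothing active
  expect_identical(count_active(m, ann, "cellZ"),
                   c(n_active_clusters = 0L, n_active_chromosomes = 0L))
  # an unclustered active OR counts as its own singleton, or is dropped on request
  m2 <- m; m2["OrE", "cellZ"] <- 80
  expect_identical(unname(count_active(m2, ann, "cellZ")), c(1L, 1L))
  expect_identical(unname(count_active(m2, ann, "cellZ", unclustered = "exclude")),
                   c(0L, 0L))
})

test_that("per-cell profiles keep the chromosome <= cluster <= active-OR chain", {
  prof <- or_cell_profiles(toy_cell_meta(), toy_norm(), toy_annotation())
  expect_identical(prof$cell_id, toy_cell_meta()$cell_id)
  expect_true(all(prof$n_active_chromosomes <= prof$n_active_clusters))
  expect_true(all(prof$n_active_clusters <= prof$n_active_or))
  expect_identical(is.na(prof$winner), prof$n_active_or == 0L)
  expect_identical(as.character(prof$state), c("multigenic", "multigenic", "silent"))
  # gene-order invariance
  shuffled <- or_cell_profiles(toy_cell_meta(), toy_norm()[c(4, 2, 5, 1, 3), ],
                               toy_annotation())
  expect_equal(shuffled[, c("n_active_or", "n_active_clusters", "state")],
               prof[, c("n_active_or", "n_active_clusters", "state")])
})

test_that("same-cluster multigenic cells are counted per stage by exhaustive check", {
  ann <- toy_annotation()
  m <- toy_norm()
  meta <- toy_cell_meta()
  # cellY has OrA+OrB active, both c1; cellX actives are in 3 distinct clusters
  expect_identical(count_same_cluster_multis(meta, m, ann), 1L)
  expect_identical(count_same_cluster_multis(meta, m, ann, stage = "qGBC"), 0L)
  # brute force on a random 6-cell cohort
  set.seed(14)
  big <- matrix(sample(c(0, 60), 30, TRUE), 5, 6,
                dimnames = list(ann$gene_id, paste0("c", 1:6)))
  meta6 <- tibble::tibble(cell_id = paste0("c", 1:6), stage = "Late.INP",
                          pseudotime = seq(0.1, 0.6, 0.1))
  manual <- 0L
  for (j in 1:6) {
    act <- ann$cluster_id[match(rownames(big)[big[, j] >= 50], ann$gene_id)]
    act <- act[!is.na(act)]
    if (any(table(act) >= 2)) manual <- manual + 1L
  }
  expect_identical(count_same_cluster_multis(meta6, big, ann), manual)
})

test_that("stage-based segmentation partitions the lineage into three ordered phases", {
  sizes <- c(qGBC = 50, GBC = 38, Early.INP = 26, Mid.INP = 20,
             Late.INP = 34, iOSN = 95, mOSN = 32)
  n <- sum(sizes)
  meta <- tibble::tibble(cell_id = sprintf("c%03d", 1:n),
                         stage = rep(names(sizes), sizes),
                         pseudotime = (1:n - 0.5) / n)
  seg <- segment_phases(meta)
  pc <- phase_counts(seg)
  expect_identical(pc$n_cells[match(c("silent", "multigenic", "monogenic"), pc$phase)],
                   c(134L, 34L, 127L))
  expect_equal(sum(pc$n_cells), n)
  # phases ordered along mean pseudotime
  mp <- tapply(seg$pseudotime, seg$phase, mean)
  expect_true(mp["silent"] < mp["multigenic"] && mp["multigenic"] < mp["monogenic"])
  # unknown stage names the offending cells
  bad <- meta; bad$stage[3] <- "other"
  expect_error(segment_phases(bad), "c003", class = "orselect_validation_error")
})

test_that("state-based segmentation mode follows per-cell activity states", {
  prof <- or_cell_profiles(toy_cell_meta(), toy_norm(), toy_annotation())
  seg <- segment_phases(toy_cell_meta(), mode = "state", profiles = prof)
  expect_identical(as.character(seg$phase), c("multigenic", "multigenic", "silent"))
  expect_error(segment_phases(toy_cell_meta(), mode = "state"),
               class = "orselect_validation_error")
})

test_that("pseudotime courses are sorted by time then cell id and input-order invariant", {
  m <- matrix(1:6, 2, 3, dimnames = list(c("g1", "g2"), c("cell1", "cell2", "cell3")))
  meta <- tibble::tibble(cell_id = c("cell1", "cell2", "cell3"),
                         stage = "iOSN", pseudotime = c(0.9, 0.1, 0.5))
  pc <- pseudotime_course(meta, m, "g1")
  expect_identical(pc$cell_id, c("cell2", "cell3", "cell1"))
  # ties broken by cell id
  meta$pseudotime <- c(0.5, 0.5, 0.5)
  expect_identical(pseudotime_course(meta, m, "g1")$cell_id,
                   c("cell1", "cell2", "cell3"))
  # invariance to input row order
  set.seed(2)
  metaP <- meta[sample(3), ]
  expect_identical(pseudotime_course(metaP, m, "g1"),
                   pseudotime_course(meta, m, "g1"))
})
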
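GREEK_MOTIF <- "TYCCYWKGGGVCTHATTARM"

test_that("IUPAC mismatch counting follows the code sets", {
  expect_identical(iupac_mismatches("TY", "TC"), 0L)  # Y = {C,T}
  expect_identical(iupac_mismatches("TY", "TG"), 1L)
  expect_identical(iupac_mismatches("NN", "QX"), 0L)  # N matches anything
  expect_identical(iupac_mismatches("AA", "NA"), 1L)  # subject N only matches pattern N
  expect_identical(iupac_mismatches("RYSWKM", c("AGCTCA", "AGCTTT")), c(2L, 2L))
  # positionwise set-membership oracle on random pairs
  set.seed(6)
  codes <- c("A", "C", "G", "T", "R", "Y", "S", "W", "K", "M", "B", "D", "H", "V", "N")
  for (i in 1:50) {
    pat <- paste(sample(codes, 8, TRUE), collapse = "")
    win <- random_dna(8, c("A", "C", "G", "T", "N"))
    manual <- sum(!mapply(function(p, w) p == "N" || w %in% IUPAC_ORACLE[[p]],
                          strsplit(pat, "")[[1]], strsplit(win, "")[[1]]))
    expect_identical(iupac_mismatches(pat, win), as.integer(manual))
  }
  expect_error(iupac_mismatches("TX", "TC"), class = "orselect_validation_error")
  expect_error(iupac_mismatches("TY", "TCA"), class = "orselect_validation_error")
})

test_that("planted motifs are found at the right position and strand", {
  set.seed(19)
  flank <- random_dna(7)
  seq_fwd <- paste0(flank, "TTCCTAGGGGACTAATTAGA", random_dna(40))
  h <- scan_sequence(seq_fwd, GREEK_MOTIF, 0)
  expect_identical(h$position, 7L)
  expect_identical(h$strand, "+")
  expect_identical(h$mismatches, 0L)
  # reverse complement planted: minus-strand hit at the forward window start
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString("TTCCTAGGGGACTAATTAGA")))
  seq_rev <- paste0(random_dna(12), rc, random_dna(30))
  h2 <- scan_sequence(seq_rev, GREEK_MOTIF, 0)
  expect_identical(h2$position, 12L)
  expect_identical(h2$strand, "-")
  # sequence shorter than pattern: empty
  expect_identical(nrow(scan_sequence("ACGT", GREEK_MOTIF, 3)), 0L)
})

test_that("the scanner equals the naive window-by-window oracle", {
  set.seed(23)
  for (i in 1:6) {
    s <- random_dna(200, c("A", "C", "G", "T", "T", "A", "N"))
    got <- scan_sequence(s, GREEK_MOTIF, 2)
    want <- oracle_scan(s, GREEK_MOTIF, 2)
    expect_equal(got$position, want$position)
    expect_equal(got$strand, want$strand)
    expect_equal(got$mismatches, want$mismatches)
  }
})

test_that("scanning is strand-symmetric and monotone in the mismatch budget", {
  set.seed(29)
  s <- random_dna(400)
  # plant one near copy per strand so the comparison is not vacuous
  substr(s, 50, 69) <- "TTCCTATGGGACTAATTAGA"  # 1 mismatch to the consensus
  substr(s, 200, 219) <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString("TTCCTAGGGGACTCATTAGA")))
  L <- nchar(s); P <- nchar(GREEK_MOTIF)
  h <- scan_sequence(s, GREEK_MOTIF, 3)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  h_rc <- scan_sequence(rc, GREEK_MOTIF, 3)
  # a +-hit at p becomes a --hit at L - P - p on the reverse complement
  mirrored <- data.frame(position = L - P - h_rc$position,
                         strand = ifelse(h_rc$strand == "+", "-", "+"),
                         mismatches = h_rc$mismatches)
  mirrored <- mirrored[order(mirrored$position, mirrored$strand), ]
  expect_equal(h$position, mirrored$position)
  expect_equal(h$strand, mirrored$strand)
  expect_equal(h$mismatches, mirrored$mismatches)
  # monotonicity of the hit set
  keys <- function(x) paste(x$position, x$strand)
  for (k in 0:2) {
    expect_true(all(keys(scan_sequence(s, GREEK_MOTIF, k)) %in%
                      keys(scan_sequence(s, GREEK_MOTIF, k + 1))))
  }
})

test_that("scanner agrees with Biostrings on N-free sequences", {
  set.seed(37)
  s <- random_dna(500)
  for (mm in c(0, 2)) {
    ours <- scan_sequence(s, GREEK_MOTIF, mm, both_strands = FALSE)
    ref <- Biostrings::matchPattern(GREEK_MOTIF, Biostrings::DNAString(s),
                                    max.mismatch = mm, fixed = "subject")
    expect_identical(ours$position, BiocGenerics::start(ref) - 1L)
  }
})

test_that("presence tables count sequences containing the motif", {
  set.seed(41)
  seqs <- vapply(1:8, function(i) random_dna(120), "")
  planted <- c(1, 3, 4, 6, 8)
  seqs[planted] <- vapply(seqs[planted], function(s) {
    paste0(substr(s, 1, 40), "TTCCTAGGGGACTAATTAGA", substr(s, 61, 120))
  }, "")
  names(seqs) <- paste0("island", 1:8)
  d <- withr::local_tempdir()
  fa <- file.path(d, "islands.fa")
  writeLines(paste0(">", names(seqs), "\n", seqs), fa)
  pres <- scan_motif_set(fa, GREEK_MOTIF, 0)
  expect_identical(attr(pres, "n_present"), length(planted))
  expect_identical(pres$seq_id[pres$present], names(seqs)[planted])
  expect_true(all(pres$best_mismatch[pres$present] == 0))
  # a mismatch budget the length of the pattern matches vacuously
  all_in <- scan_motif_set(fa, GREEK_MOTIF, nchar(GREEK_MOTIF))
  expect_identical(attr(all_in, "n_present"), 8L)
  # empty input
  empty <- scan_motif_set(character(0), GREEK_MOTIF, 3)
  expect_identical(attr(empty, "n_present"), 0L)
  expect_error(scan_motif_set(c(a = "ACGT", a = "ACGT"), GREEK_MOTIF, 3),
               class = "orselect_validation_error")
})
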
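# Strict IUPAC consensus motif scanning with mismatch tolerance.

iupac_sets <- function() {
  list(A = "A", C = "C", G = "G", T = "T",
       R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
       K = c("G", "T"), M = c("A", "C"),
       B = c("C", "G", "T"), D = c("A", "G", "T"),
       H = c("A", "C", "T"), V = c("A", "C", "G"),
       N = c("A", "C", "G", "T", "N"))
}

IUPAC_COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", R = "Y", Y = "R",
                      S = "S", W = "W", K = "M", M = "K", B = "V", V = "B",
                      D = "H", H = "D", N = "N")

validate_pattern <- function(pattern) {
  pattern <- toupper(pattern)
  chars <- strsplit(pattern, "")[[1]]
  bad <- setdiff(chars, names(iupac_sets()))
  if (nchar(pattern) == 0 || length(bad) > 0) {
    abort(sprintf("invalid IUPAC pattern%s",
                  if (length(bad)) paste0(": unknown code(s) ", paste(unique(bad), collapse = ", "))
                  else " (empty)"),
          class = "orselect_validation_error")
  }
  chars
}

#' Reverse complement of an IUPAC pattern
#' @param pattern IUPAC consensus string.
#' @return The reverse-complemented pattern.
#' @export
reverse_complement_iupac <- function(pattern) {
  chars <- validate_pattern(pattern)
  paste(rev(unname(IUPAC_COMPLEMENT[chars])), collapse = "")
}

#' Mismatches between an IUPAC pattern and equal-length windows
#'
#' Counts, per window, the positions where the window base is not in the
#' pattern code's base set. `N` in the pattern matches anything; `N` (or any
#' non-ACGT character) in the window matches only pattern code `N` — ambiguous
#' genome bases are treated conservatively.
#'
#' @param pattern IUPAC consensus string.
#' @param windows Character vector of sequences, each the length of `pattern`.
#' @return Integer vector of mismatch counts, one per window.
#' @export
iupac_mismatches <- function(pattern, windows) {
  chars <- validate_pattern(pattern)
  if (any(nchar(windows) != length(chars))) {
    abort("windows must have the same length as the pattern",
          class = "orselect_validation_error")
  }
  sets <- iupac_sets()
  wmat <- matrix(unlist(strsplit(toupper(windows), "")), nrow = length(chars))
  mism <- integer(length(windows))
  for (p in seq_along(chars)) {
    if (chars[p] == "N") next  # pattern N is a true wildcard
    mism <- mism + !(wmat[p, ] %in% sets[[chars[p]]])
  }
  mism
}

scan_one_strand <- function(pat_chars, seq_chars, max_mismatch) {
  L <- length(seq_chars); P <- length(pat_chars)
  n_win <- L - P + 1
  if (n_win < 1) return(list(position = integer(0), mismatches = integer(0)))
  sets <- iupac_sets()
  mism <- integer(n_win)
  for (p in seq_len(P)) {
    if (pat_chars[p] == "N") next  # pattern N is a true wildcard
    mism <- mism + !(seq_chars[p:(p + n_win - 1)] %in% sets[[pat_chars[p]]])
  }
  hit <- which(mism <= max_mismatch)
  list(position = hit - 1L, mismatches = mism[hit])
}

#' Scan a sequence for an IUPAC consensus motif
#'
#' Reports every window (all overlaps, no masking) on the forward and,
#' optionally, reverse strand whose mismatch count against the pattern is at
#' most `max_mismatch`. Minus-strand hits are located by the forward-strand
#' coordinate of the window start, so positions are directly comparable across
#' strands. Positions are 0-based.
#'
#' @param sequence A single DNA sequence (string over A/C/G/T/N).
#' @param pattern IUPAC consensus string.
#' @param max_mismatch Maximum mismatches per hit (default 3).
#' @param both_strands Scan the reverse strand too (default TRUE).
#' @return A tibble (`position`, `strand`, `mismatches`) sorted by position
#'   then strand.
#' @export
scan_sequence <- function(sequence, pattern, max_mismatch = 3, both_strands = TRUE) {
  pat_chars <- validate_pattern(pattern)
  seq_chars <- strsplit(toupper(sequence), "")[[1]]
  fwd <- scan_one_strand(pat_chars, seq_chars, max_mismatch)
  out <- tibble(position = fwd$position, strand = "+", mismatches = fwd$mismatches)
  if (both_strands) {
    rc_chars <- validate_pattern(reverse_complement_iupac(pattern))
    rev_ <- scan_one_strand(rc_chars, seq_chars, max_mismatch)
    out <- dplyr::bind_rows(out, tibble(position = rev_$position, strand = "-",
                                        mismatches = rev_$mismatches))
  }
  out[order(out$position, out$strand), ]
}

#' Scan a set of sequences for a motif and tabulate presence
#'
#' Runs [scan_sequence()] over every sequence of a FASTA file (or an in-memory
#' named set) and summarises, per sequence, the number of hits, the best (i.e.
#' lowest) mismatch count among them, and whether the motif is present at all
#' (>= 1 hit at <= `max_mismatch` on either strand).
#'
#' @param sequences Path to a FASTA file, a named character vector, or a
#'   `Biostrings::DNAStringSet`. Sequence ids must be unique.
#' @inheritParams scan_sequence
#' @return A tibble (`seq_id`, `n_hits`, `best_mismatch`, `present`) with
#'   attributes `n_present` (number of sequences containing the motif) and
#'   `hits` (the full per-hit tibble, with a `seq_id` column).
#' @export
scan_motif_set <- function(sequences, pattern, max_mismatch = 3, both_strands = TRUE) {
  if (is.character(sequences) && length(sequences) == 1 && file.exists(sequences)) {
    ss <- Biostrings::readDNAStringSet(sequences)
    ids <- sub("\\s.*$", "", names(ss))
    sequences <- stats::setNames(as.character(ss), ids)
  } else if (methods::is(sequences, "DNAStringSet")) {
    sequences <- stats::setNames(as.character(sequences), names(sequences))
  }
  if (length(sequences) > 0 && is.null(names(sequences))) {
    abort("sequences must be a FASTA path or a named set", class = "orselect_validation_error")
  }
  validate_ids(names(sequences), "sequence ids")
  hits <- purrr::map_dfr(names(sequences), function(id) {
    h <- scan_sequence(sequences[[id]], pattern, max_mismatch, both_strands)
    if (nrow(h) > 0) dplyr::mutate(h, seq_id = id, .before = 1) else NULL
  })
  presence <- tibble(
    seq_id = names(sequences),
    n_hits = if (nrow(hits)) as.integer(table(factor(hits$seq_id, names(sequences))))
             else rep(0L, length(sequences)),
    best_mismatch = if (nrow(hits)) {
      bm <- tapply(hits$mismatches, factor(hits$seq_id, names(sequences)), min)
      as.integer(bm)
    } else rep(NA_integer_, length(sequences)))
  presence$present <- presence$n_hits > 0
  attr(presence, "n_present") <- sum(presence$present)
  attr(presence, "hits") <- hits
  presence
}
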
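# Independent oracles and small fixtures used across the suite. These are
# deliberately naive re-derivations (quadratic DP, direct counting,
# exhaustive enumeration) kept separate from the implementation paths they
# check.

# Quadratic-time affine-gap Smith-Waterman (gap of length k costs
# open + k*ext, matching the package's convention).
sw_dp_oracle <- function(a, b, mat, open = 11, ext = 1) {
  A <- strsplit(a, "")[[1]]
  B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  M <- matrix(0, n + 1, m + 1)
  Ix <- matrix(-Inf, n + 1, m + 1)
  Iy <- matrix(-Inf, n + 1, m + 1)
  best <- 0
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      Ix[i, j] <- max(M[i - 1, j] - open - ext, Ix[i - 1, j] - ext)
      Iy[i, j] <- max(M[i, j - 1] - open - ext, Iy[i, j - 1] - ext)
      M[i, j] <- max(0, max(M[i - 1, j - 1], Ix[i - 1, j - 1], Iy[i - 1, j - 1]) +
                       mat[A[i - 1], B[j - 1]])
      best <- max(best, M[i, j])
    }
  }
  best
}

# Direct per-window GC counting on character vectors.
gc_window_oracle <- function(seq, window, step) {
  starts <- seq(1, nchar(seq) - window + 1, by = step)
  vapply(starts, function(s) {
    b <- strsplit(substring(seq, s, s + window - 1), "")[[1]]
    n_n <- sum(b == "N")
    if (n_n == window) return(NA_real_)
    sum(b %in% c("G", "C")) / (window - n_n)
  }, numeric(1))
}

# Exhaustive forward word-match count between two sequences via word
# tabulation (independent of the dot-plot code path).
word_match_count_oracle <- function(a, b, word) {
  ka <- substring(a, seq_len(nchar(a) - word + 1), seq_len(nchar(a) - word + 1) + word - 1)
  kb <- substring(b, seq_len(nchar(b) - word + 1), seq_len(nchar(b) - word + 1) + word - 1)
  ta <- table(ka); tb <- table(kb)
  common <- intersect(names(ta), names(tb))
  sum(as.numeric(ta[common]) * as.numeric(tb[common]))
}

ro <- function(s1, e1, s2, e2) {
  ov <- max(0, min(e1, e2) - max(s1, s2) + 1)
  min(ov / (e1 - s1 + 1), ov / (e2 - s2 + 1))
}

mutate_dna <- emalescan:::mutate_dna
excise_intervals <- emalescan:::excise_intervals
element_similarity <- emalescan:::element_similarity

random_peptide <- function(n) {
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], n, TRUE), collapse = "")
}

# Small simulation configuration used by most pipeline-level tests.
small_config <- function(seed = 1, ...) {
  sim_config(seed = seed, n_contigs = 2, contig_lengths = c(150000, 150000),
             n_elements = 3, n_partial = 1, n_ngaros = 2,
             n_ngaro_truncated = 1, n_ngaro_in_elements = 1,
             min_spacing = 8000, ...)
}

# Reciprocal-overlap matching of detected vs truth intervals on one contig
# set; returns per-truth best overlap and boundary error.
match_features <- function(truth, detected) {
  t(vapply(seq_len(nrow(truth)), function(i) {
    d <- detected[detected$contig == truth$contig[i], , drop = FALSE]
    if (!nrow(d)) return(c(ro = 0, berr = NA_real_, idx = NA_real_))
    ro <- vapply(seq_len(nrow(d)), function(k) {
      ov <- max(0, min(d$end[k], truth$end[i]) - max(d$start[k], truth$start[i]) + 1)
      min(ov / (d$end[k] - d$start[k] + 1), ov / (truth$end[i] - truth$start[i] + 1))
    }, numeric(1))
    k <- which.max(ro)
    c(ro = ro[k],
      berr = max(abs(d$start[k] - truth$start[i]), abs(d$end[k] - truth$end[i])),
      idx = which(detected$contig == truth$contig[i])[k])
  }, numeric(3)))
}

galignments_from_placements <- function(placements, assembly) {
  aln <- GenomicAlignments::GAlignments(
    seqnames = S4Vectors::Rle(factor(placements$contig, levels = names(assembly))),
    pos = as.integer(placements$start),
    cigar = paste0(placements$end - placements$start + 1, "M"),
    strand = S4Vectors::Rle(factor(ifelse(placements$strand == "-", "-", "+"),
                                   levels = c("+", "-", "*"))))
  GenomeInfoDb::seqlengths(aln) <- Biostrings::width(assembly)
  aln
}
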
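# Six-frame ORF calling, local protein alignment against a reference
# virophage proteome, per-ORF annotation, and cumulative-bitscore type
# assignment for partial elements.

.BIT_LAMBDA <- 0.267
.BIT_K <- 0.041

bitscore <- function(raw) (.BIT_LAMBDA * raw - log(.BIT_K)) / log(2)

# BLOSUM62 with X scored 0 against everything.
.blosum62x <- function() {
  if (!is.null(.cache$blosum62x)) return(.cache$blosum62x)
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  mat <- as.matrix(e$BLOSUM62)
  mat["X", ] <- 0L
  mat[, "X"] <- 0L
  .cache$blosum62x <- mat
  mat
}

#' Call open reading frames in all six frames
#'
#' ORFs are stop-to-stop, not ATG-anchored: each reported ORF runs from the
#' previous stop codon (or the frame start) through a terminating stop
#' codon, which is included in the coordinates. Coordinates are always on
#' the forward strand, 1-based closed.
#'
#' @param sequence Character or [Biostrings::DNAString].
#' @param min_aa Minimum peptide length in amino acids (default 50,
#'   permissive enough for short virophage genes).
#' @return Data frame: `start`, `end`, `strand`, `frame` (0-2), `peptide`,
#'   `fragmented` (always `FALSE` here; set by [annotate_orfs()]).
#' @export
find_orfs_six_frame <- function(sequence, min_aa = 50L) {
  stopifnot(min_aa >= 1)
  seq_chr <- toupper(as.character(sequence))
  n <- nchar(seq_chr)
  empty <- data.frame(start = integer(0), end = integer(0), strand = character(0),
                      frame = integer(0), peptide = character(0),
                      fragmented = logical(0))
  if (n < (min_aa + 1) * 3) return(empty)
  fuzzy <- grepl("[^ACGT]", seq_chr)
  scan_strand <- function(s, strand) {
    x <- Biostrings::DNAString(s)
    out <- list()
    for (f in 0:2) {
      len <- ((length(x) - f) %/% 3) * 3
      if (len < 3) next
      sub <- Biostrings::subseq(x, f + 1, f + len)
      # the fuzzy genetic code is expensive to build; only pay for it
      # when ambiguous bases are actually present
      pep <- if (fuzzy) {
        as.character(Biostrings::translate(sub, if.fuzzy.codon = "X"))
      } else {
        as.character(Biostrings::translate(sub))
      }
      stops <- c(0L, which(strsplit(pep, "", fixed = TRUE)[[1]] == "*"))
      for (k in seq_along(stops)[-length(stops)]) {
        a <- stops[k] + 1L          # first aa of segment
        b <- stops[k + 1] - 1L      # last aa before stop
        if (b - a + 1 < min_aa) next
        nt_start <- f + (a - 1L) * 3L + 1L
        nt_end <- f + stops[k + 1] * 3L   # includes the stop codon
        peptide <- substring(pep, a, b)
        if (strand == "+") {
          out[[length(out) + 1]] <- data.frame(
            start = nt_start, end = nt_end, strand = "+", frame = f,
            peptide = peptide, fragmented = FALSE)
        } else {
          out[[length(out) + 1]] <- data.frame(
            start = n - nt_end + 1L, end = n - nt_start + 1L, strand = "-",
            frame = f, peptide = peptide, fragmented = FALSE)
        }
      }
    }
    out
  }
  res <- c(scan_strand(seq_chr, "+"), scan_strand(revcomp(seq_chr), "-"))
  if (!length(res)) return(empty)
  out <- do.call(rbind, res)
  out <- out[order(out$start, out$end), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Smith-Waterman local protein alignment
#'
#' Local alignment under BLOSUM62 (X scored 0) with affine gaps, opening 11
#' and extension 1 per residue. Bitscores use the gapped BLOSUM62 constants
#' lambda = 0.267, K = 0.041.
#'
#' @param query,reference Peptide strings over the 20-letter alphabet
#'   (X allowed).
#' @return List: `raw_score`, `bitscore`, `identity`, `query_coverage`,
#'   `ref_coverage`, and the aligned subject range `ref_start`/`ref_end`.
#' @export
local_align_protein <- function(query, reference) {
  for (nm in c(query = query, reference = reference)) {
    bad <- regexpr("[^ACDEFGHIKLMNPQRSTVWYX]", nm)
    if (bad > 0) {
      stop("illegal residue '", substring(nm, bad, bad), "' at position ", bad)
    }
  }
  if (nchar(query) == 0 || nchar(reference) == 0) {
    return(list(raw_score = 0, bitscore = bitscore(0), identity = NA_real_,
                query_coverage = 0, ref_coverage = 0,
                ref_start = NA_integer_, ref_end = NA_integer_))
  }
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(query), Biostrings::AAString(reference),
    type = "local", substitutionMatrix = .blosum62x(),
    gapOpening = 11, gapExtension = 1)
  raw <- max(0, Biostrings::score(pa))
  qr <- pa@pattern@range
  sr <- pa@subject@range
  list(raw_score = raw, bitscore = bitscore(raw),
       identity = Biostrings::pid(pa) / 100,
       query_coverage = IRanges::width(qr) / nchar(query),
       ref_coverage = IRanges::width(sr) / nchar(reference),
       ref_start = IRanges::start(sr), ref_end = IRanges::end(sr))
}

# Batch best-hit search of many peptides against a reference set, with a
# shared-6-mer prefilter so that unrelated pairs are never aligned in full.
# Returns a data.frame: query index, ref name, raw, bits, ref coverage and
# subject range of the best hit per computed pair.
.batch_align <- function(peptides, refs, word = 6L) {
  if (!length(peptides) || !length(refs)) {
    return(data.frame(q = integer(0), ref = character(0), raw = numeric(0),
                      bits = numeric(0), ref_cov = numeric(0),
                      ref_start = integer(0), ref_end = integer(0)))
  }
  ref_words <- lapply(as.character(refs), function(r) unique(kmers(r, word)))
  q_words <- lapply(peptides, function(p) unique(kmers(p, word)))
  rows <- list()
  mat <- .blosum62x()
  for (j in seq_along(refs)) {
    cand <- which(vapply(q_words, function(w) any(w %in% ref_words[[j]]), logical(1)))
    if (!length(cand)) next
    pa <- Biostrings::pairwiseAlignment(
      Biostrings::AAStringSet(peptides[cand]),
      Biostrings::AAString(as.character(refs[[j]])),
      type = "local", substitutionMatrix = mat,
      gapOpening = 11, gapExtension = 1)
    raw <- pmax(0, Biostrings::score(pa))
    sr <- pa@subject@range
    rows[[length(rows) + 1]] <- data.frame(
      q = cand, ref = names(refs)[j], raw = raw, bits = bitscore(raw),
      ref_cov = IRanges::width(sr) / nchar(as.character(refs[[j]])),
      ref_start = IRanges::start(sr), ref_end = IRanges::end(sr))
  }
  if (!length(rows)) {
    return(data.frame(q = integer(0), ref = character(0), raw = numeric(0),
                      bits = numeric(0), ref_cov = numeric(0),
                      ref_start = integer(0), ref_end = integer(0)))
  }
  do.call(rbind, rows)
}

#' Annotate ORFs by best hit against a reference proteome
#'
#' Each ORF is labeled with its best-scoring reference protein when the
#' best bitscore reaches `min_bitscore`. An ORF is flagged `fragmented`
#' when its best hit covers at most half of the reference and an
#' adjacent same-strand ORF hits a complementary region of the same
#' reference (the split-gene signature).
#'
#' @param orfs Data frame from [find_orfs_six_frame()].
#' @param reference_proteins Named [Biostrings::AAStringSet].
#' @param min_bitscore Minimum bitscore to accept a label (default 50).
#' @return `orfs` with added columns `label`, `best_bitscore`, `ref_cov`,
#'   `ref_start`, `ref_end`, and updated `fragmented`.
#' @export
annotate_orfs <- function(orfs, reference_proteins, min_bitscore = 50) {
  orfs$label <- NA_character_
  orfs$best_bitscore <- NA_real_
  orfs$ref_cov <- NA_real_
  orfs$ref_start <- NA_integer_
  orfs$ref_end <- NA_integer_
  if (!nrow(orfs)) return(orfs)
  hits <- .batch_align(orfs$peptide, reference_proteins)
  if (nrow(hits)) {
    hits <- hits[order(hits$q, -hits$bits), , drop = FALSE]
    best <- hits[!duplicated(hits$q), , drop = FALSE]
    best <- best[best$bits >= min_bitscore, , drop = FALSE]
    orfs$label[best$q] <- best$ref
    orfs$best_bitscore[best$q] <- best$bits
    orfs$ref_cov[best$q] <- best$ref_cov
    orfs$ref_start[best$q] <- best$ref_start
    orfs$ref_end[best$q] <- best$ref_end
  }
  # split-gene detection
  lab <- which(!is.na(orfs$label) & orfs$ref_cov <= 0.5)
  for (i in lab) {
    same <- which(orfs$label == orfs$label[i] & orfs$strand == orfs$strand[i] &
                  seq_len(nrow(orfs)) != i & !is.na(orfs$label))
    if (!length(same)) next
    gap <- pmax(orfs$start[same] - orfs$end[i], orfs$start[i] - orfs$end[same])
    same <- same[gap < 1000]
    for (k in same) {
      ov <- max(0, min(orfs$ref_end[i], orfs$ref_end[k]) -
                   max(orfs$ref_start[i], orfs$ref_start[k]) + 1)
      shorter <- min(orfs$ref_end[i] - orfs$ref_start[i],
                     orfs$ref_end[k] - orfs$ref_start[k]) + 1
      if (ov < 0.5 * shorter) {
        orfs$fragmented[c(i, k)] <- TRUE
      }
    }
  }
  orfs
}

#' Assign an element type by cumulative bitscore
#'
#' Every candidate ORF contributes its single best bitscore against each
#' type's protein set; scores are summed per type and the maximal type is
#' assigned. A cumulative maximum below 100 is classified "inconclusive".
#' Exact ties are broken toward the lower type id and flagged.
#'
#' @param element_seq Element nucleotide sequence (retrotransposon
#'   insertions should be excised first).
#' @param db Per-type protein sets from [type_species_db()].
#' @param min_aa Minimum ORF length passed to the ORF caller.
#' @return List: `scores` (named numeric per type), `assigned` (type id as
#'   integer, or `NA` for "inconclusive"), `label` ("type_k" or
#'   "inconclusive"), `margin`, `tie`.
#' @export
assign_type_by_cumulative_bitscore <- function(element_seq, db = type_species_db(),
                                               min_aa = 50L, orfs = NULL) {
  if (is.null(orfs)) orfs <- find_orfs_six_frame(element_seq, min_aa)
  scores <- setNames(numeric(length(db)), paste0("type_", seq_along(db)))
  if (nrow(orfs)) {
    for (t in seq_along(db)) {
      hits <- .batch_align(orfs$peptide, db[[t]])
      if (nrow(hits)) {
        per_orf <- tapply(hits$bits, hits$q, max)
        scores[t] <- sum(per_orf)
      }
    }
  }
  mx <- max(scores)
  if (mx < 100) {
    return(list(scores = scores, assigned = NA_integer_, label = "inconclusive",
                margin = NA_real_, tie = FALSE))
  }
  winners <- which(scores == mx)
  assigned <- winners[1]
  runner <- if (length(scores) > 1) max(scores[-assigned]) else -Inf
  list(scores = scores, assigned = as.integer(assigned),
       label = paste0("type_", assigned), margin = mx - runner,
       tie = length(winners) > 1)
}
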
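# Readers and writers for the standard formats. FASTA goes through
# Biostrings, GFF3/BED through rtracklayer, SAM reading through the
# htslib-backed Rsamtools/GenomicAlignments stack; SAM writing is the
# generator's own minimal emitter (@SQ header + 11 mandatory columns).

#' Read a genome assembly from FASTA
#'
#' Sequences are upper-cased; duplicate identifiers and non-IUPAC
#' characters are rejected with named errors.
#'
#' @param path FASTA file.
#' @return A [Biostrings::DNAStringSet].
#' @export
read_fasta <- function(path) {
  raw <- Biostrings::readBStringSet(path)
  if (length(raw) == 0) stop("empty FASTA file: ", path)
  ids <- sub("\\s.*", "", names(raw))
  if (anyDuplicated(ids)) {
    stop("duplicate sequence id: ", ids[duplicated(ids)][1])
  }
  seqs <- toupper(as.character(raw))
  for (i in seq_along(seqs)) {
    bad <- regexpr("[^ACGTRYSWKMBDHVN]", seqs[[i]])
    if (bad > 0) {
      stop("non-IUPAC character '", substring(seqs[[i]], bad, bad),
           "' in record '", ids[i], "' at position ", bad)
    }
  }
  Biostrings::DNAStringSet(setNames(seqs, ids))
}

#' Write sequences to FASTA
#' @param x `DNAStringSet` or named character vector.
#' @param path Output file.
#' @param wrap Line width (default 60).
#' @export
write_fasta <- function(x, path, wrap = 60L) {
  if (!is(x, "XStringSet")) x <- Biostrings::DNAStringSet(x)
  Biostrings::writeXStringSet(x, path, width = wrap)
  invisible(path)
}

# class <-> GFF3 feature type
.GFF_TYPES <- c(host = "region", element = "mobile_genetic_element",
                ngaro = "retrotransposon", tir = "terminal_inverted_repeat",
                tsd = "target_site_duplication", orf = "open_reading_frame",
                repeat_unit = "repeat_unit")

.check_bundle <- function(bundle) {
  has_parent <- !is.na(bundle$parent_id)
  dangling <- !(bundle$parent_id[has_parent] %in% bundle$feature_id)
  if (any(dangling)) {
    stop("dangling Parent: ", paste(unique(bundle$parent_id[has_parent][dangling]),
                                    collapse = ", "))
  }
  idx <- match(bundle$parent_id, bundle$feature_id)
  for (i in which(has_parent)) {
    p <- idx[i]
    if (bundle$start[i] < bundle$start[p] || bundle$end[i] > bundle$end[p]) {
      stop("child '", bundle$feature_id[i], "' extends past parent '",
           bundle$feature_id[p], "'")
    }
  }
  invisible(TRUE)
}

#' Write an annotation bundle to GFF3
#'
#' Internal records (1-based closed) are emitted as GFF3 v3 features with
#' `Parent` attributes encoding the nesting (retrotransposon in element,
#' TIR/TSD/ORF in element). Referential integrity and child containment
#' are enforced before writing.
#'
#' @param bundle Data frame with columns `feature_id`, `class`, `contig`,
#'   `start`, `end`, `strand`, and optionally `type_id`, `parent_id`,
#'   `label`.
#' @param assembly Matching assembly (for sequence lengths); optional.
#' @param path Output file.
#' @export
write_gff3 <- function(bundle, assembly = NULL, path) {
  .check_bundle(bundle)
  strand <- ifelse(bundle$strand %in% c("+", "-"), bundle$strand, "*")
  gr <- GenomicRanges::GRanges(bundle$contig,
                               IRanges::IRanges(bundle$start, bundle$end),
                               strand = strand)
  S4Vectors::mcols(gr)$source <- "emalescan"
  S4Vectors::mcols(gr)$type <- unname(.GFF_TYPES[bundle$class])
  S4Vectors::mcols(gr)$ID <- bundle$feature_id
  if (!is.null(bundle$parent_id)) {
    S4Vectors::mcols(gr)$Parent <- ifelse(is.na(bundle$parent_id), NA,
                                          bundle$parent_id)
  }
  if (!is.null(bundle$label)) S4Vectors::mcols(gr)$Name <- bundle$label
  if (!is.null(bundle$type_id)) S4Vectors::mcols(gr)$type_id <- bundle$type_id
  if (!is.null(assembly)) {
    GenomeInfoDb::seqlevels(gr) <- names(assembly)
    GenomeInfoDb::seqlengths(gr) <- Biostrings::width(assembly)
  }
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

write_truth_gff3 <- function(truth, assembly, path) {
  write_gff3(truth, assembly, path)
}

#' Read an annotation bundle from GFF3
#'
#' Inverse of [write_gff3()]: reconstructs the internal data frame with
#' 1-based closed coordinates and parent links.
#'
#' @param path GFF3 file.
#' @return Annotation bundle data frame.
#' @export
read_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  rev_map <- setNames(names(.GFF_TYPES), .GFF_TYPES)
  parent <- S4Vectors::mcols(gr)$Parent
  parent_chr <- if (is.null(parent)) NA_character_ else {
    vapply(as.list(parent), function(p) if (length(p)) p[[1]] else NA_character_,
           character(1))
  }
  md <- S4Vectors::mcols(gr)
  bundle <- data.frame(
    feature_id = md$ID,
    class = unname(rev_map[as.character(md$type)]),
    contig = as.character(GenomeInfoDb::seqnames(gr)),
    start = IRanges::start(gr), end = IRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    type_id = if (!is.null(md$type_id)) as.integer(md$type_id) else NA_integer_,
    parent_id = parent_chr,
    label = if (!is.null(md$Name)) as.character(md$Name) else NA_character_,
    stringsAsFactors = FALSE)
  bundle$strand[bundle$strand == "*"] <- "+"
  .check_bundle(bundle)
  bundle
}

#' Write simulated reads as single-end SAM alignments
#'
#' Minimal valid SAM: @HD/@SQ header plus the 11 mandatory columns; each
#' read is a single ungapped match (CIGAR `<len>M`) at its truth
#' placement, with minus-strand reads stored on the forward reference
#' strand under flag 16.
#'
#' @param reads Named character vector of read sequences (as sequenced).
#' @param placements Data frame `read_id`, `contig`, `start`, `end`,
#'   `strand`.
#' @param assembly Reference [Biostrings::DNAStringSet].
#' @param path Output file.
#' @export
write_sam <- function(reads, placements, assembly, path) {
  header <- c("@HD\tVN:1.6\tSO:unsorted",
              sprintf("@SQ\tSN:%s\tLN:%d", names(assembly),
                      Biostrings::width(assembly)))
  seqs <- unname(reads[placements$read_id])
  flip <- placements$strand == "-"
  if (any(flip)) {
    seqs[flip] <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(seqs[flip])))
  }
  rec <- sprintf("%s\t%d\t%s\t%d\t60\t%dM\t*\t0\t0\t%s\t*",
                 placements$read_id, ifelse(flip, 16L, 0L), placements$contig,
                 placements$start, nchar(seqs), seqs)
  writeLines(c(header, rec), path)
  invisible(path)
}

#' Read single-end alignments from SAM
#'
#' Converts through BAM (htslib) and returns primary mapped alignments
#' only (unmapped, secondary and supplementary records are skipped).
#'
#' @param path SAM file.
#' @return A [GenomicAlignments::GAlignments].
#' @export
read_sam <- function(path) {
  bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                          indexDestination = FALSE)
  flags <- Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                  isSecondaryAlignment = FALSE,
                                  isSupplementaryAlignment = FALSE)
  GenomicAlignments::readGAlignments(
    Rsamtools::BamFile(bam), use.names = TRUE,
    param = Rsamtools::ScanBamParam(flag = flags))
}

#' Write candidate segments as BED
#' @param segments Data frame with `contig`, `start`, `end` (1-based
#'   closed; converted to BED half-open).
#' @param path Output file.
#' @export
write_bed <- function(segments, path) {
  gr <- GenomicRanges::GRanges(segments$contig,
                               IRanges::IRanges(segments$start, segments$end))
  rtracklayer::export(gr, path, format = "bed")
  invisible(path)
}
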
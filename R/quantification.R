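# Assembly- and read-based nucleotide contribution accounting, codon usage
# vs GC, and the retrotransposon-effect gene-length comparison.

# Disjoint class ranges from annotations: retrotransposon bases count as
# "ngaro" even when nested inside an element; host is everything else.
.class_ranges <- function(annotations, assembly) {
  gr <- GenomicRanges::GRanges(annotations$contig,
                               IRanges::IRanges(annotations$start, annotations$end))
  GenomeInfoDb::seqlevels(gr) <- names(assembly)
  GenomeInfoDb::seqlengths(gr) <- Biostrings::width(assembly)
  ngaro <- GenomicRanges::reduce(gr[annotations$class == "ngaro"])
  element <- GenomicRanges::setdiff(
    GenomicRanges::reduce(gr[annotations$class == "element"]), ngaro)
  list(element = element, ngaro = ngaro)
}

#' Assembly-side nucleotide fractions
#'
#' Exact base bookkeeping over the annotation set: every base is host,
#' element, or ngaro (nested retrotransposon bases count as ngaro, not
#' element), and the three fractions sum to one.
#'
#' @param assembly [Biostrings::DNAStringSet].
#' @param annotations Data frame with `contig`, `start`, `end`, `class`
#'   (rows with class `element` / `ngaro` are used).
#' @return Data frame with one row per class: `class`, `bases`, `fraction`.
#' @export
assembly_fractions <- function(assembly, annotations) {
  total <- sum(Biostrings::width(assembly))
  ann <- annotations[annotations$class %in% c("element", "ngaro"), , drop = FALSE]
  if (nrow(ann)) {
    bad <- !(ann$contig %in% names(assembly)) |
      ann$start < 1 |
      ann$end > Biostrings::width(assembly)[match(ann$contig, names(assembly))]
    if (any(bad)) stop("annotation outside contig bounds: ",
                       paste(ann$contig[bad], collapse = ", "))
  }
  cr <- .class_ranges(ann, assembly)
  el <- sum(IRanges::width(cr$element))
  ng <- sum(IRanges::width(cr$ngaro))
  data.frame(class = c("host", "element", "ngaro"),
             bases = c(total - el - ng, el, ng),
             fraction = c(total - el - ng, el, ng) / total)
}

#' Read-side nucleotide fractions from SAM alignments
#'
#' Every aligned base is attributed to the class of its reference
#' position (CIGAR-aware: M/=/X consume both sequences; I consumes the
#' read only and is attributed to the enclosing reference class; D is not
#' counted). Unmapped, secondary and supplementary records are skipped.
#'
#' @param sam Path to a SAM file, or a `GAlignments` object.
#' @param assembly [Biostrings::DNAStringSet] (the alignment reference).
#' @param annotations Annotation data frame as in [assembly_fractions()].
#' @return Data frame: `class`, `bases`, `fraction`.
#' @export
read_fractions <- function(sam, assembly, annotations) {
  aln <- if (is(sam, "GAlignments")) sam else read_sam(sam)
  refs <- GenomeInfoDb::seqlevels(aln)
  if (!all(refs %in% names(assembly))) {
    stop("alignment to unknown reference: ",
         paste(setdiff(refs, names(assembly)), collapse = ", "))
  }
  ann <- annotations[annotations$class %in% c("element", "ngaro"), , drop = FALSE]
  cr <- .class_ranges(ann, assembly)
  blocks <- unlist(GenomicAlignments::grglist(aln, drop.D.ranges = TRUE))
  total <- sum(IRanges::width(blocks))
  count_class <- function(class_gr) {
    GenomeInfoDb::seqlevels(class_gr) <- GenomeInfoDb::seqlevels(blocks)
    hits <- GenomicRanges::findOverlaps(blocks, class_gr)
    if (!length(hits)) return(0)
    pi <- IRanges::pintersect(blocks[S4Vectors::queryHits(hits)],
                              class_gr[S4Vectors::subjectHits(hits)])
    sum(IRanges::width(pi))
  }
  el <- count_class(cr$element)
  ng <- count_class(cr$ngaro)
  # insertions (I) consume read bases only; attribute them to the class of
  # the reference position where they occur
  cig <- GenomicAlignments::cigar(aln)
  has_i <- grepl("I", cig, fixed = TRUE)
  if (any(has_i)) {
    idx <- which(has_i)
    iref <- GenomicAlignments::cigarRangesAlongReferenceSpace(
      cig[idx], ops = "I", pos = GenomicAlignments::start(aln)[idx])
    ilen <- GenomicAlignments::cigarRangesAlongQuerySpace(cig[idx], ops = "I")
    for (k in seq_along(idx)) {
      if (!length(iref[[k]])) next
      at <- GenomicRanges::GRanges(GenomeInfoDb::seqnames(aln)[idx[k]],
                                   IRanges::IRanges(IRanges::start(iref[[k]]),
                                                    width = 1))
      w <- IRanges::width(ilen[[k]])
      in_ng <- GenomicRanges::countOverlaps(at, cr$ngaro) > 0
      in_el <- GenomicRanges::countOverlaps(at, cr$element) > 0
      ng <- ng + sum(w[in_ng])
      el <- el + sum(w[in_el & !in_ng])
      total <- total + sum(w)
    }
  }
  data.frame(class = c("host", "element", "ngaro"),
             bases = c(total - el - ng, el, ng),
             fraction = c(total - el - ng, el, ng) / total)
}

#' Compare assembly- and read-based fraction estimates
#'
#' @param assembly,annotations As in [assembly_fractions()].
#' @param sam As in [read_fractions()].
#' @return Data frame per class with both estimates and their absolute
#'   deviation in percentage points.
#' @export
fraction_report <- function(assembly, annotations, sam) {
  a <- assembly_fractions(assembly, annotations)
  r <- read_fractions(sam, assembly, annotations)
  data.frame(class = a$class,
             assembly_bases = a$bases, assembly_fraction = a$fraction,
             read_bases = r$bases, read_fraction = r$fraction,
             deviation_pp = abs(a$fraction - r$fraction) * 100)
}

#' Codon usage profile of elements and its GC trend
#'
#' Counts codons over each element's ORFs, computes GC3 and per-amino-acid
#' synonymous usage, and reports the Spearman correlation of GC3 with
#' element GC across elements (the codon-level signature of GC-content
#' adaptation).
#'
#' @param elements Named list; each entry a list with `gc` (element GC,
#'   insertions excised) and `orfs` (data frame with a `peptide`-free
#'   nucleotide interface: columns `start`, `end`, `strand`) plus `seq`
#'   (element sequence). ORF-less elements are excluded.
#' @return List: `per_element` data frame (`id`, `gc`, `gc3`,
#'   `n_codons`), `codon_counts` matrix (64 columns), `usage` (per
#'   amino-acid synonymous fractions, list of matrices), `spearman_rho`
#'   (GC3 vs GC; `NA` below 3 elements).
#' @export
codon_usage_profile <- function(elements) {
  rows <- list()
  counts <- list()
  for (id in names(elements)) {
    el <- elements[[id]]
    orfs <- el$orfs
    if (is.null(orfs) || nrow(orfs) == 0) next
    cods <- integer(0)
    tab <- setNames(integer(64), names(Biostrings::GENETIC_CODE))
    gc3_num <- 0; gc3_den <- 0
    for (i in seq_len(nrow(orfs))) {
      nt <- substring(el$seq, orfs$start[i], orfs$end[i])
      if (orfs$strand[i] == "-") nt <- revcomp(nt)
      nt <- substring(nt, 1, (nchar(nt) %/% 3) * 3)
      cc <- Biostrings::oligonucleotideFrequency(Biostrings::DNAString(nt), 3,
                                                 step = 3)
      tab <- tab + cc[names(tab)]
      third <- substring(nt, seq(3, nchar(nt), by = 3), seq(3, nchar(nt), by = 3))
      gc3_num <- gc3_num + sum(third %in% c("G", "C"))
      gc3_den <- gc3_den + length(third)
    }
    rows[[id]] <- data.frame(id = id, gc = el$gc, gc3 = gc3_num / gc3_den,
                             n_codons = sum(tab))
    counts[[id]] <- tab
  }
  per_element <- do.call(rbind, rows)
  cmat <- do.call(rbind, counts)
  usage <- NULL
  if (!is.null(cmat)) {
    code <- Biostrings::GENETIC_CODE
    usage <- lapply(unique(code), function(aa) {
      cols <- names(code)[code == aa]
      sub <- cmat[, cols, drop = FALSE]
      tot <- rowSums(sub)
      sweep(sub, 1, ifelse(tot == 0, 1, tot), "/")
    })
    names(usage) <- unique(code)
  }
  rho <- if (!is.null(per_element) && nrow(per_element) >= 3) {
    cor(per_element$gc3, per_element$gc, method = "spearman")
  } else NA_real_
  list(per_element = per_element, codon_counts = cmat, usage = usage,
       spearman_rho = rho)
}

#' Compare conserved gene lengths by retrotransposon presence
#'
#' For each conserved gene label, the distribution of ORF lengths is
#' stratified by whether the containing element carries a retrotransposon
#' insertion; a Wilcoxon rank-sum statistic flags length shifts
#' (retrotransposon-triggered gene decay would shorten genes in the
#' carrier stratum).
#'
#' @param orf_table Data frame with columns `element_id`, `label`,
#'   `length_aa`, `has_ngaro` (logical).
#' @param labels Gene labels to test (default: all present).
#' @return Data frame per label: `label`, `n_with`, `n_without`,
#'   `median_with`, `median_without`, `iqr_with`, `iqr_without`, `p_value`
#'   (`NA` when a stratum is empty).
#' @export
gene_length_comparison <- function(orf_table, labels = NULL) {
  if (is.null(labels)) labels <- sort(unique(orf_table$label))
  rows <- lapply(labels, function(lab) {
    d <- orf_table[orf_table$label == lab, , drop = FALSE]
    w <- d$length_aa[d$has_ngaro]
    wo <- d$length_aa[!d$has_ngaro]
    p <- if (length(w) > 0 && length(wo) > 0) {
      suppressWarnings(wilcox.test(w, wo)$p.value)
    } else NA_real_
    data.frame(label = lab, n_with = length(w), n_without = length(wo),
               median_with = if (length(w)) median(w) else NA_real_,
               median_without = if (length(wo)) median(wo) else NA_real_,
               iqr_with = if (length(w)) stats::IQR(w) else NA_real_,
               iqr_without = if (length(wo)) stats::IQR(wo) else NA_real_,
               p_value = p)
  })
  do.call(rbind, rows)
}
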
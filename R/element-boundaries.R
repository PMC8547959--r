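# Precise delimitation of candidate elements: terminal inverted repeat
# (TIR) detection, completeness classification, target site duplication
# (TSD) calling, and cross-strain insertion-locus orthology.

.NT_GAP_OPEN <- 5
.NT_GAP_EXT <- 2

.nt_submat <- function() {
  if (is.null(.cache$nt_submat)) {
    .cache$nt_submat <- Biostrings::nucleotideSubstitutionMatrix(
      match = 1, mismatch = -2, baseOnly = FALSE)
  }
  .cache$nt_submat
}

# Local nucleotide alignment (match +1 / mismatch -2, affine gaps 5/2).
.nt_align <- function(pattern, subject) {
  Biostrings::pairwiseAlignment(
    Biostrings::DNAString(pattern), Biostrings::DNAString(subject),
    type = "local", substitutionMatrix = .nt_submat(),
    gapOpening = .NT_GAP_OPEN, gapExtension = .NT_GAP_EXT)
}

#' Delimit a candidate element via its terminal inverted repeats
#'
#' Searches the outer windows of a (boundary-refined) candidate for the
#' best local alignment between the 5' arm and the reverse complement of
#' the 3' arm. When a repeat of at least `min_tir` bp at `min_identity` is
#' found, the element boundaries snap to the outer TIR ends. Known
#' retrotransposon insertions are excised before the search and all
#' coordinates are mapped back to the contig.
#'
#' @param candidate One-row data frame (or list) with `contig`, `start`,
#'   `end` and optionally `at_contig_end` (from [scan_gc()]).
#' @param assembly [Biostrings::DNAStringSet] holding the contig.
#' @param insertions Optional data frame of contig-coordinate intervals
#'   (`start`, `end`) to excise (nested retrotransposons).
#' @param min_tir Minimum TIR arm length (bp).
#' @param min_identity Minimum TIR arm identity.
#' @param search_window How far (bp) from each candidate end to search.
#' @param slack Extra context (bp) added outside each candidate edge so
#'   TIR arms partly or wholly outside the GC-refined boundary are still
#'   recovered (mid-GC elements can leave several hundred bp of edge
#'   error to the GC changepoint).
#' @param orfs Optional annotated ORF table (from [annotate_orfs()],
#'   element-relative coordinates) used to orient the element so the
#'   primase/helicase gene is 5'.
#' @return An `element_record` list: `contig`, `start`, `end`,
#'   `orientation`, `tir` (list or `NULL`), `at_contig_end`, `gc`.
#' @export
delimit_element <- function(candidate, assembly, insertions = NULL,
                            min_tir = 100L, min_identity = 0.9,
                            search_window = 3000L, slack = 800L, orfs = NULL) {
  contig <- as.character(candidate$contig)
  seq_chr <- as.character(assembly[[contig]])
  clen <- nchar(seq_chr)
  rs <- max(1L, candidate$start - slack)
  re <- min(clen, candidate$end + slack)
  region <- substring(seq_chr, rs, re)
  rel_ins <- NULL
  if (!is.null(insertions) && nrow(insertions) > 0) {
    rel_ins <- data.frame(start = pmax(insertions$start - rs + 1L, 1L),
                          end = pmin(insertions$end - rs + 1L, re - rs + 1L))
    rel_ins <- rel_ins[rel_ins$end >= rel_ins$start, , drop = FALSE]
  }
  ex <- excise_intervals(region, rel_ins)
  n <- nchar(ex$seq)
  tir <- NULL
  start <- candidate$start
  end <- candidate$end
  if (n >= 2 * min_tir) {
    w <- min(search_window + slack, floor(n / 2))
    left <- substring(ex$seq, 1, w)
    right <- substring(ex$seq, n - w + 1, n)
    pa <- .nt_align(left, revcomp(right))
    alen <- max(IRanges::width(pa@pattern@range), IRanges::width(pa@subject@range))
    if (alen >= min_tir && Biostrings::pid(pa) / 100 >= min_identity) {
      p1 <- IRanges::start(pa@pattern@range); p2 <- IRanges::end(pa@pattern@range)
      s1 <- IRanges::start(pa@subject@range); s2 <- IRanges::end(pa@subject@range)
      roff <- n - w  # right window starts at roff + 1 in excised coords
      r_lo <- roff + w - s2 + 1L
      r_hi <- roff + w - s1 + 1L
      start <- rs + map_back(p1, ex$map) - 1L
      end <- rs + map_back(r_hi, ex$map) - 1L
      tir <- list(left_start = start,
                  left_end = rs + map_back(p2, ex$map) - 1L,
                  right_start = rs + map_back(r_lo, ex$map) - 1L,
                  right_end = end,
                  length = p2 - p1 + 1L,
                  identity = Biostrings::pid(pa) / 100)
    }
  } else {
    warning("candidate shorter than 2x minimum TIR length; returned without TIR")
  }
  orientation <- "+"
  if (!is.null(orfs) && nrow(orfs) > 0 && "label" %in% names(orfs)) {
    ph <- orfs[!is.na(orfs$label) & grepl("^PrimHel", orfs$label), , drop = FALSE]
    if (nrow(ph) > 0) {
      orientation <- ph$strand[1]
    } else {
      tab <- table(orfs$strand)
      orientation <- names(tab)[which.max(tab)]
    }
  }
  # element GC with insertions excised
  el_rel <- data.frame(start = start - rs + 1L, end = end - rs + 1L)
  el_seq <- substring(region, el_rel$start, el_rel$end)
  el_ex <- excise_intervals(el_seq, if (is.null(rel_ins)) NULL else
    data.frame(start = rel_ins$start - el_rel$start + 1L,
               end = rel_ins$end - el_rel$start + 1L))
  rec <- list(contig = contig, start = as.integer(start), end = as.integer(end),
              orientation = orientation, tir = tir,
              at_contig_end = start == 1L || end == clen,
              gc = gc_fraction(el_ex$seq))
  class(rec) <- "element_record"
  rec
}

#' Classify element completeness
#'
#' An element is complete when a TIR pair is present and both outer
#' boundaries lie strictly inside the contig (host DNA on both sides);
#' otherwise it is partial (truncated by the assembly, not by biology).
#'
#' @param element An `element_record` from [delimit_element()].
#' @param contig_length Length of the containing contig (bp).
#' @return `"complete"` or `"partial"`.
#' @export
classify_completeness <- function(element, contig_length) {
  if (!is.null(element$tir) && element$start > 1 && element$end < contig_length) {
    "complete"
  } else {
    "partial"
  }
}

#' Find the target site duplication flanking an element
#'
#' Returns the longest L <= `max_len` for which the upstream-flank suffix
#' of length L equals the downstream-flank prefix exactly. L = 0 yields
#' `NULL`: exact-match only, so any reported TSD is re-verifiable by
#' string equality.
#'
#' @param assembly [Biostrings::DNAStringSet].
#' @param element `element_record` (must have host flanks on both sides).
#' @param max_len Maximum TSD length searched (bp); capped at the
#'   available flank length.
#' @return List (`sequence`, `length`, `left_start`, `left_end`,
#'   `right_start`, `right_end`, `capped`) or `NULL`.
#' @export
find_tsd <- function(assembly, element, max_len = 15L) {
  seq_chr <- as.character(assembly[[element$contig]])
  clen <- nchar(seq_chr)
  avail <- min(max_len, element$start - 1L, clen - element$end)
  if (avail <= 0) return(NULL)
  up <- substring(seq_chr, element$start - avail, element$start - 1L)
  down <- substring(seq_chr, element$end + 1L, element$end + avail)
  for (L in rev(seq_len(avail))) {
    if (substring(up, avail - L + 1) == substring(down, 1, L)) {
      return(list(sequence = substring(down, 1, L), length = L,
                  left_start = element$start - L, left_end = element$start - 1L,
                  right_start = element$end + 1L, right_end = element$end + L,
                  capped = avail < max_len))
    }
  }
  NULL
}

# Refine the inner boundary of a contig-end partial element by aligning
# the assigned type's reference TIR arm across the junction region (the
# GC changepoint alone can be tens of bp off; the TIR outer end is exact).
.refine_partial_boundary <- function(rec, assembly, type_id,
                                     templates = element_templates(),
                                     span = 1500L, min_len = 100L,
                                     min_identity = 0.9) {
  if (is.na(type_id) || type_id > length(templates)) return(rec)
  master <- templates[[type_id]]$tir
  if (is.null(master)) return(rec)
  seq_chr <- as.character(assembly[[rec$contig]])
  clen <- nchar(seq_chr)
  if (rec$start > 1 && rec$end == clen) {
    # junction at the element start: the forward TIR arm begins there
    lo <- max(1L, rec$start - span)
    hi <- min(clen, rec$start + span)
    pa <- .nt_align(master, substring(seq_chr, lo, hi))
    if (IRanges::width(pa@subject@range) >= min_len &&
        Biostrings::pid(pa) / 100 >= min_identity) {
      p1 <- IRanges::start(pa@pattern@range)
      rec$start <- lo + IRanges::start(pa@subject@range) - 1L - (p1 - 1L)
    }
  } else if (rec$start == 1 && rec$end < clen) {
    # junction at the element end: the reverse-complement arm ends there
    lo <- max(1L, rec$end - span)
    hi <- min(clen, rec$end + span)
    rcm <- revcomp(master)
    pa <- .nt_align(rcm, substring(seq_chr, lo, hi))
    if (IRanges::width(pa@subject@range) >= min_len &&
        Biostrings::pid(pa) / 100 >= min_identity) {
      p2 <- IRanges::end(pa@pattern@range)
      rec$end <- lo + IRanges::end(pa@subject@range) - 1L + (nchar(rcm) - p2)
    }
  }
  rec
}

# Seed-and-extend search of one flank against a subject assembly: exact
# 20-mer seeds locate the target region, a local alignment then scores it.
.flank_hit <- function(flank, subject_assembly, min_len = 200L, min_identity = 0.9) {
  k <- 20L
  fw <- kmers(flank, k)
  best <- NULL
  for (ci in seq_along(subject_assembly)) {
    subj <- as.character(subject_assembly[[ci]])
    sw <- kmers(subj, k)
    m <- match(sw, fw)
    hits <- which(!is.na(m))
    if (length(hits) < 3) next
    diag <- hits - m[hits]  # subject offset of the flank origin
    dmed <- median(diag)
    core <- hits[abs(diag - dmed) < 5000]
    if (length(core) < 3) next
    lo <- max(1L, min(core) - 2000L)
    hi <- min(nchar(subj), max(core) + k - 1L + 2000L)
    pa <- .nt_align(flank, substring(subj, lo, hi))
    alen <- IRanges::width(pa@subject@range)
    if (alen >= min_len && Biostrings::pid(pa) / 100 >= min_identity) {
      score <- Biostrings::score(pa)
      if (is.null(best) || score > best$score) {
        best <- list(contig = names(subject_assembly)[ci],
                     start = lo + IRanges::start(pa@subject@range) - 1L,
                     end = lo + IRanges::end(pa@subject@range) - 1L,
                     identity = Biostrings::pid(pa) / 100, score = score)
      }
    }
  }
  best
}

#' Search other strains for an element's insertion locus
#'
#' Up to `flank` bp of host sequence on each side of the element is
#' aligned against every subject assembly. A locus is "occupied" when a
#' homologous element of the same type lies between (or immediately
#' beyond) the matched flanks, "empty" when the flanks abut directly
#' (up to a TSD-sized gap). The locus is shared when an element is present
#' with at least one matching host flank.
#'
#' @param element `element_record` with a `type_id` field or supplied
#'   `type_id`.
#' @param assembly Query assembly containing the element.
#' @param others Named list of subject assemblies.
#' @param flank Flank length (bp), truncated at contig ends (flagged).
#' @param type_id Element type used to confirm occupancy.
#' @param db Per-type protein sets for occupancy confirmation.
#' @return Data frame with one row per subject strain: `subject_strain`,
#'   `subject_contig`, `left_matched`, `right_matched`, `flank_truncated`,
#'   `occupancy`, `shared`.
#' @export
cross_strain_locus_search <- function(element, assembly, others, flank = 10000L,
                                      type_id = element$type_id,
                                      db = type_species_db()) {
  stopifnot(length(others) >= 1)
  seq_chr <- as.character(assembly[[element$contig]])
  clen <- nchar(seq_chr)
  ls <- max(1L, element$start - flank)
  le <- element$start - 1L
  rs <- element$end + 1L
  re <- min(clen, element$end + flank)
  left_flank <- if (le >= ls) substring(seq_chr, ls, le) else ""
  right_flank <- if (re >= rs) substring(seq_chr, rs, re) else ""
  truncated <- (le - ls + 1L < flank) || (re - rs + 1L < flank)
  out <- lapply(names(others), function(strain) {
    subj <- others[[strain]]
    lh <- if (nchar(left_flank) >= 200) .flank_hit(left_flank, subj) else NULL
    rh <- if (nchar(right_flank) >= 200) .flank_hit(right_flank, subj) else NULL
    occupancy <- NA_character_
    shared <- FALSE
    contig <- NA_character_
    type_confirm <- function(s) {
      if (nchar(s) < 1000) return(FALSE)
      ta <- assign_type_by_cumulative_bitscore(s, db)
      !is.na(ta$assigned) && ta$assigned == type_id
    }
    if (!is.null(lh) && !is.null(rh) && lh$contig == rh$contig) {
      contig <- lh$contig
      gap <- rh$start - lh$end - 1L
      if (gap <= 50) {
        occupancy <- "empty"
      } else {
        mid <- substring(as.character(subj[[contig]]), lh$end + 1L, rh$start - 1L)
        if (type_confirm(mid)) {
          occupancy <- "occupied"; shared <- TRUE
        } else {
          occupancy <- "empty"
        }
      }
    } else if (!is.null(lh) || !is.null(rh)) {
      h <- if (!is.null(lh)) lh else rh
      contig <- h$contig
      subj_chr <- as.character(subj[[contig]])
      win <- if (!is.null(lh)) {
        substring(subj_chr, h$end + 1L, min(nchar(subj_chr), h$end + 25000L))
      } else {
        substring(subj_chr, max(1L, h$start - 25000L), h$start - 1L)
      }
      if (type_confirm(win)) {
        occupancy <- "occupied"; shared <- TRUE
      } else {
        occupancy <- "empty"
      }
    }
    data.frame(subject_strain = strain, subject_contig = contig,
               left_matched = !is.null(lh), right_matched = !is.null(rh),
               flank_truncated = truncated, occupancy = occupancy,
               shared = shared)
  })
  do.call(rbind, out)
}
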
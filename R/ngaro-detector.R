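# Detection of GC-rich Ngaro retrotransposon insertions, split-direct-
# repeat structure resolution, typing, ORF1-truncation calling, and the
# integration-site bias test.

# High-GC interval calling within a (low-GC) element sequence. The element
# baseline is the lower quartile of window GC values, robust even when the
# insertion makes up most of the sequence. Runs at or above
# baseline + delta are merged across short gaps whose own GC stays
# elevated, so element DNA separating two adjacent insertions is never
# bridged.
.high_gc_intervals <- function(seq_chr, delta = 10, min_len = 2000L,
                               max_len = 12000L, window = 300L, step = 50L) {
  n <- nchar(seq_chr)
  if (n < min_len) return(data.frame(start = integer(0), end = integer(0)))
  prof <- compute_gc_profile(seq_chr, min(window, n), step)
  vals <- prof$values
  baseline <- stats::quantile(vals, 0.25, na.rm = TRUE, names = FALSE)
  thr <- baseline + delta / 100
  high <- !is.na(vals) & vals >= thr
  if (!any(high)) return(data.frame(start = integer(0), end = integer(0)))
  r <- rle(high)
  ends_i <- cumsum(r$lengths)
  starts_i <- ends_i - r$lengths + 1
  runs <- data.frame(first = starts_i[r$values], last = ends_i[r$values])
  runs$start <- (runs$first - 1L) * prof$step + 1L
  runs$end <- pmin((runs$last - 1L) * prof$step + prof$window, n)
  # conditional merging: only across gaps that are themselves GC-elevated
  if (nrow(runs) > 1) {
    keep <- runs[1, c("start", "end")]
    for (i in 2:nrow(runs)) {
      gap_s <- keep$end[nrow(keep)] + 1L
      gap_e <- runs$start[i] - 1L
      gap_len <- gap_e - gap_s + 1L
      gap_gc <- if (gap_e >= gap_s) gc_fraction(substring(seq_chr, gap_s, gap_e)) else 1
      # local dips shorter than ~2 windows are noise and always bridged;
      # longer gaps must themselves be GC-elevated (element DNA separating
      # two truly adjacent insertions stays low and is never bridged)
      if (gap_len <= 600 ||
          (gap_len <= 2000 && !is.na(gap_gc) && gap_gc >= baseline + delta / 200)) {
        keep$end[nrow(keep)] <- runs$end[i]
      } else {
        keep <- rbind(keep, runs[i, c("start", "end")])
      }
    }
    runs <- keep
  }
  runs <- runs[, c("start", "end")]
  # base-resolution edge refinement against the low-GC background
  for (i in seq_len(nrow(runs))) {
    if (runs$start[i] > 1) {
      cut <- .refine_edge(seq_chr, runs$start[i], window, low_side = "left")
      runs$start[i] <- cut + 1L
    }
    if (runs$end[i] < n) {
      runs$end[i] <- .refine_edge(seq_chr, runs$end[i], window, low_side = "right")
    }
  }
  len <- runs$end - runs$start + 1
  runs <- runs[len >= min_len & len <= max_len, , drop = FALSE]
  rownames(runs) <- NULL
  runs
}

#' Detect GC-rich insertions inside an element
#'
#' Scans windowed GC within a delimited element for runs at least `delta`
#' points above the element's own background GC; such runs of plausible
#' retrotransposon size are reported (contig coordinates) and should be
#' excised before element typing and GC computation.
#'
#' @param element `element_record` (or any list with `contig`, `start`,
#'   `end`).
#' @param assembly [Biostrings::DNAStringSet].
#' @param delta GC contrast in percentage points over the element
#'   background (default 10).
#' @param min_len,max_len Accepted insertion lengths (bp); defaults
#'   2000-12000 bracket the typical ~6 kb.
#' @return Data frame of intervals (`start`, `end`, contig coordinates).
#' @export
detect_high_gc_insertions <- function(element, assembly, delta = 10,
                                      min_len = 2000L, max_len = 12000L) {
  seq_chr <- substring(as.character(assembly[[element$contig]]),
                       element$start, element$end)
  iv <- .high_gc_intervals(seq_chr, delta, min_len, max_len)
  iv$start <- iv$start + element$start - 1L
  iv$end <- iv$end + element$start - 1L
  iv
}

#' Resolve the split-direct-repeat structure of a retrotransposon
#'
#' Ngaro elements carry split direct repeats A1-\[ORFs\]-B1 A2 B2: the 5'
#' arm A1 recurs near the 3' end, directly followed by the second copy of
#' B. The structure is found by same-strand local self-alignment of the
#' candidate's outer windows against its interior (arms >= `min_arm` bp at
#' >= `min_identity`, B1 A2 B2 contiguous within `tolerance` bp). A single
#' detached A+B pair with no intervening ORFs is reported as a solo
#' repeat; recognising one requires reference arms (`repeat_db`).
#'
#' @param candidate Candidate nucleotide sequence (>= 500 bp).
#' @param min_arm Minimum repeat arm length (bp).
#' @param min_identity Minimum arm identity.
#' @param tolerance Maximum gap (bp) tolerated inside the B1 A2 B2 block.
#' @param repeat_db Optional list with `A` and `B` arm sequences used to
#'   recognise solo AB pairs.
#' @param search_window How much of the candidate prefix (bp) is scanned
#'   for the recurring 5' arm; enlarged when the candidate interval is
#'   known only approximately.
#' @return List with intervals `A1`, `B1`, `A2`, `B2` (each `c(start,
#'   end)`, candidate coordinates), `identity_A`, `identity_B` and
#'   `solo = FALSE`; a solo result (`solo = TRUE`, intervals `A`, `B`); or
#'   `NULL` when no qualifying repeats exist.
#' @export
detect_split_direct_repeats <- function(candidate, min_arm = 50L,
                                        min_identity = 0.9, tolerance = 100L,
                                        repeat_db = NULL, search_window = 800L) {
  seq_chr <- toupper(as.character(candidate))
  n <- nchar(seq_chr)
  if (n < 500) stop("candidate shorter than 500 bp")
  w <- min(search_window, floor(n / 3))
  # locate A: the 5' arm (prefix window) recurs in the 3' interior
  pref <- substring(seq_chr, 1, w)
  pa_a <- .nt_align(pref, substring(seq_chr, w + 1, n))
  ok_a <- IRanges::width(pa_a@pattern@range) >= min_arm &&
    Biostrings::pid(pa_a) / 100 >= min_identity
  if (ok_a) {
    A1 <- c(IRanges::start(pa_a@pattern@range), IRanges::end(pa_a@pattern@range))
    A2 <- c(w + IRanges::start(pa_a@subject@range),
            w + IRanges::end(pa_a@subject@range))
    # B copies bracket A2: B1 immediately upstream, B2 immediately downstream
    bw <- min(1000L, max(200L, w))
    b1_lo <- max(1L, A2[1] - bw)
    b2_hi <- min(n, A2[2] + bw)
    if (A2[1] - 1 >= b1_lo && b2_hi >= A2[2] + 1) {
      pa_b <- .nt_align(substring(seq_chr, A2[2] + 1, b2_hi),
                        substring(seq_chr, b1_lo, A2[1] - 1))
      ok_b <- IRanges::width(pa_b@pattern@range) >= min_arm &&
        Biostrings::pid(pa_b) / 100 >= min_identity
      if (ok_b) {
        B2 <- c(A2[2] + IRanges::start(pa_b@pattern@range),
                A2[2] + IRanges::end(pa_b@pattern@range))
        B1 <- c(b1_lo + IRanges::start(pa_b@subject@range) - 1L,
                b1_lo + IRanges::end(pa_b@subject@range) - 1L)
        ordered <- A1[2] < B1[1] && B1[2] <= A2[1] && A2[2] < B2[1]
        contiguous <- (A2[1] - B1[2] - 1) <= tolerance &&
          (B2[1] - A2[2] - 1) <= tolerance
        if (ordered && contiguous) {
          return(list(A1 = A1, B1 = B1, A2 = A2, B2 = B2,
                      identity_A = Biostrings::pid(pa_a) / 100,
                      identity_B = Biostrings::pid(pa_b) / 100,
                      solo = FALSE))
        }
      }
    }
  }
  # solo AB pair: reference arms found once each, adjacent, no ORFs between
  if (!is.null(repeat_db)) {
    ha <- .nt_align(repeat_db$A, seq_chr)
    hb <- .nt_align(repeat_db$B, seq_chr)
    ok_a <- IRanges::width(ha@subject@range) >= min_arm &&
      Biostrings::pid(ha) / 100 >= min_identity
    ok_b <- IRanges::width(hb@subject@range) >= min_arm &&
      Biostrings::pid(hb) / 100 >= min_identity
    if (ok_a && ok_b) {
      A <- c(IRanges::start(ha@subject@range), IRanges::end(ha@subject@range))
      B <- c(IRanges::start(hb@subject@range), IRanges::end(hb@subject@range))
      gap <- B[1] - A[2] - 1
      if (A[2] < B[1] && gap <= tolerance) {
        return(list(A = A, B = B, solo = TRUE))
      }
    }
  }
  NULL
}

#' Classify a retrotransposon candidate
#'
#' Type is assigned by maximal shared-word (word length 10) coverage
#' against the bundled type templates; the variant is `orf1_truncated`
#' when no candidate ORF hits the assigned type's ORF1 (Gag-like) protein,
#' the signature of the ~2 kb 5' deletions observed in host-integrated
#' copies.
#'
#' @param candidate Candidate nucleotide sequence.
#' @param type_db Templates from [ngaro_templates()].
#' @param min_coverage Minimum word coverage to assign a type.
#' @return List: `type_id` (integer or `NA` = unassigned), `variant`
#'   (`"full"` / `"orf1_truncated"` / `NA`), `coverage`.
#' @export
classify_ngaro <- function(candidate, type_db = ngaro_templates(),
                           min_coverage = 0.15) {
  seq_chr <- toupper(as.character(candidate))
  cov <- vapply(type_db, function(t) element_similarity(seq_chr, t$seq, 10L),
                numeric(1))
  best <- which.max(cov)
  if (cov[best] < min_coverage) {
    return(list(type_id = NA_integer_, variant = NA_character_,
                coverage = max(cov)))
  }
  gag <- type_db[[best]]$orfs
  gag_pep <- gag$peptide[gag$label == "GAG"]
  orfs <- find_orfs_six_frame(seq_chr, min_aa = 100L)
  has_orf1 <- FALSE
  if (nrow(orfs) > 0 && length(gag_pep)) {
    hits <- .batch_align(orfs$peptide,
                         setNames(Biostrings::AAStringSet(gag_pep), "GAG"))
    has_orf1 <- nrow(hits) > 0 && any(hits$bits >= 50)
  }
  list(type_id = as.integer(best),
       variant = if (has_orf1) "full" else "orf1_truncated",
       coverage = cov[best])
}

#' Scan an assembly for retrotransposon copies outside elements
#'
#' Host-integrated Ngaros have near-host GC and are invisible to the GC
#' screen; they are found by exact 12-mer seeding against the bundled
#' templates (dense seed runs mark a copy), then snapped to their repeat
#' structure.
#'
#' @param assembly [Biostrings::DNAStringSet].
#' @param type_db Templates from [ngaro_templates()].
#' @param exclude Optional data frame (`contig`, `start`, `end`) of
#'   intervals (detected elements) whose hits are ignored.
#' @param bin,min_density Seed-density binning parameters.
#' @return Data frame of candidate intervals (`contig`, `start`, `end`).
#' @export
detect_ngaro_candidates <- function(assembly, type_db = ngaro_templates(),
                                    exclude = NULL, bin = 500L,
                                    min_density = 0.10) {
  k <- 12L
  words <- unique(unlist(lapply(type_db, function(t) kmers(t$seq, k))))
  pd <- Biostrings::PDict(Biostrings::DNAStringSet(words))
  out <- list()
  for (ci in seq_along(assembly)) {
    m <- Biostrings::matchPDict(pd, assembly[[ci]])
    pos <- IRanges::start(unlist(m))
    if (!length(pos)) next
    bins <- tabulate((pos - 1L) %/% bin + 1L,
                     nbins = ceiling(Biostrings::width(assembly)[ci] / bin))
    dense <- bins >= min_density * bin
    if (!any(dense)) next
    r <- rle(dense)
    ends_i <- cumsum(r$lengths); starts_i <- ends_i - r$lengths + 1
    iv <- data.frame(start = (starts_i[r$values] - 1L) * bin + 1L,
                     end = pmin(ends_i[r$values] * bin,
                                Biostrings::width(assembly)[ci]))
    iv <- IRanges::reduce(IRanges::IRanges(iv$start, iv$end), min.gapwidth = bin + 1L)
    df <- data.frame(contig = names(assembly)[ci],
                     start = pmax(1L, IRanges::start(iv) - bin),
                     end = pmin(Biostrings::width(assembly)[ci],
                                IRanges::end(iv) + bin))
    out[[length(out) + 1]] <- df
  }
  res <- if (length(out)) do.call(rbind, out) else {
    data.frame(contig = character(0), start = integer(0), end = integer(0))
  }
  if (!is.null(exclude) && nrow(exclude) > 0 && nrow(res) > 0) {
    lev <- union(res$contig, exclude$contig)
    gr_res <- GenomicRanges::GRanges(factor(res$contig, lev),
                                     IRanges::IRanges(res$start, res$end))
    gr_ex <- GenomicRanges::GRanges(factor(exclude$contig, lev),
                                    IRanges::IRanges(exclude$start, exclude$end))
    hit <- GenomicRanges::countOverlaps(gr_res, gr_ex) > 0
    res <- res[!hit, , drop = FALSE]
  }
  rownames(res) <- NULL
  res
}

# Snap a fuzzy candidate interval to the repeat structure: the outer ends
# of A1 and B2 are the element boundaries.
.snap_ngaro <- function(candidate_iv, assembly, context = 400L) {
  seq_chr <- as.character(assembly[[candidate_iv$contig]])
  lo <- max(1L, candidate_iv$start - context)
  hi <- min(nchar(seq_chr), candidate_iv$end + context)
  region <- substring(seq_chr, lo, hi)
  st <- tryCatch(detect_split_direct_repeats(region, search_window = 1800L),
                 error = function(e) NULL)
  if (is.null(st) || isTRUE(st$solo)) {
    return(list(start = candidate_iv$start, end = candidate_iv$end, structure = st))
  }
  list(start = lo + st$A1[1] - 1L, end = lo + st$B2[2] - 1L, structure = st)
}

#' Exact Fisher test for a 2x2 table by hypergeometric enumeration
#'
#' Two-sided p: the sum of hypergeometric probabilities of all tables with
#' the observed margins whose probability does not exceed that of the
#' observed table (with the customary 1 + 1e-7 relative tolerance).
#'
#' @param m 2x2 integer matrix.
#' @return List: `p` (two-sided), `odds_ratio` (sample), `table`.
#' @export
fisher_exact_2x2 <- function(m) {
  m <- as.matrix(m)
  stopifnot(all(dim(m) == c(2, 2)), all(m >= 0))
  K <- sum(m[1, ])          # white balls: row 1
  N <- sum(m)
  k <- sum(m[, 1])          # draws: column 1
  x <- m[1, 1]
  support <- max(0, k - (N - K)):min(k, K)
  probs <- dhyper(support, K, N - K, k)
  p_obs <- dhyper(x, K, N - K, k)
  p <- sum(probs[probs <= p_obs * (1 + 1e-7)])
  or <- (m[1, 1] * m[2, 2]) / (m[1, 2] * m[2, 1])
  list(p = min(1, p), odds_ratio = or, table = m)
}

#' Test for integration-site bias of retrotransposon insertions
#'
#' Each insertion site is classified by its overlap with element
#' annotations (intergenic vs genic-or-TIR element DNA); the per-class
#' base totals from the same annotations form the comparison row of a 2x2
#' table tested two-sided by exact hypergeometric enumeration. A simple
#' binomial upper tail on the intergenic count is reported as a
#' cross-check.
#'
#' @param site_classes Character vector, one per insertion, each
#'   `"intergenic"`, `"genic"` or `"tir"`.
#' @param class_bases Named numeric with per-class element base totals
#'   (same class names).
#' @return Object of class `insertion_site_stats`: list with `table`,
#'   `odds_ratio`, `p` (Fisher), `p_binomial`, `n_insertions`,
#'   `intergenic_fraction`.
#' @export
integration_bias_test <- function(site_classes, class_bases) {
  if (length(site_classes) == 0) stop("zero insertions: test undefined")
  n_inter <- sum(site_classes == "intergenic")
  n_other <- length(site_classes) - n_inter
  b_inter <- sum(class_bases[names(class_bases) == "intergenic"])
  b_other <- sum(class_bases[names(class_bases) != "intergenic"])
  tab <- matrix(c(n_inter, n_other, round(b_inter), round(b_other)), nrow = 2,
                byrow = TRUE,
                dimnames = list(c("insertions", "bases"),
                                c("intergenic", "other")))
  fe <- fisher_exact_2x2(t(tab))
  p_frac <- b_inter / (b_inter + b_other)
  p_binom <- pbinom(n_inter - 1, length(site_classes), p_frac, lower.tail = FALSE)
  structure(list(table = tab, odds_ratio = fe$odds_ratio, p = fe$p,
                 p_binomial = p_binom, n_insertions = length(site_classes),
                 intergenic_fraction = p_frac),
            class = "insertion_site_stats")
}
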
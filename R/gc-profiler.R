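# Sliding-window GC profiling and low-GC segment calling: the primary
# screen for integrated virophage elements in a high-GC host background.

#' Compute a sliding-window GC profile
#'
#' Window i (1-based) covers bases \[(i-1)*step + 1, (i-1)*step + window\].
#' Ambiguous bases (N) are excluded from both numerator and denominator;
#' an all-N window yields `NA`.
#'
#' @param sequence Character string, [Biostrings::DNAString], or a single
#'   element of a `DNAStringSet`.
#' @param window,step Window and step sizes in bp (both >= 1).
#' @return Object of class `gc_profile`: list with `window`, `step`,
#'   `values` (numeric vector of GC fractions) and `seq_length`.
#' @export
compute_gc_profile <- function(sequence, window = 500L, step = 100L) {
  stopifnot(window >= 1, step >= 1)
  x <- if (is(sequence, "DNAString")) sequence else Biostrings::DNAString(as.character(sequence))
  n <- length(x)
  if (n < window) {
    warning("sequence shorter than window; empty profile")
    values <- numeric(0)
  } else {
    starts <- seq(1L, n - window + 1L, by = step)
    v <- Biostrings::Views(x, start = starts, width = window)
    f <- Biostrings::letterFrequency(v, c("G", "C", "N"))
    denom <- window - f[, "N"]
    values <- ifelse(denom == 0, NA_real_, (f[, "G"] + f[, "C"]) / denom)
  }
  structure(list(window = as.integer(window), step = as.integer(step),
                 values = as.numeric(values), seq_length = n),
            class = "gc_profile")
}

# Base-resolution boundary refinement: within +/- window of a coarse edge,
# place the maximum-likelihood binomial changepoint (two segments with free
# GC rates; the likelihood criterion does not degenerate for tiny
# segments the way a plain mean contrast does). `low_side` says which side
# of the boundary the low-GC segment lies on; splits with the contrast in
# the wrong direction are excluded.
.refine_edge <- function(seq_chr, edge, window, low_side) {
  n <- nchar(seq_chr)
  refine_once <- function(edge) {
    lo <- max(1L, edge - window)
    hi <- min(n, edge + window)
    if (hi - lo < 10) return(edge)
    region <- substring(seq_chr, lo, hi)
    b <- strsplit(region, "", fixed = TRUE)[[1]]
    isgc <- as.numeric(b %in% c("G", "C"))
    cs <- cumsum(isgc)
    m <- length(isgc)
    k <- seq_len(m - 1)
    pl <- cs[k] / k
    pr <- (cs[m] - cs[k]) / (m - k)
    h <- function(p) ifelse(p <= 0 | p >= 1, 0, p * log(p) + (1 - p) * log(1 - p))
    ll <- k * h(pl) + (m - k) * h(pr)
    dir_ok <- if (low_side == "right") pl > pr else pr > pl
    if (!any(dir_ok)) return(edge)
    ll[!dir_ok] <- -Inf
    kbest <- which.max(ll)
    lo + kbest - 1L
  }
  # re-center when the changepoint lands at the search-window boundary
  # (the coarse edge can sit more than one window from the true boundary)
  for (it in 1:5) {
    new <- refine_once(edge)
    settled <- abs(new - edge) < window - 10L
    edge <- new
    if (settled) break
  }
  edge
}

#' Call low-GC candidate segments from a GC profile
#'
#' Maximal runs of windows at or below `baseline - delta` are merged across
#' gaps up to `merge_gap` bp, filtered to `min_len` bp, and their edges are
#' refined to the maximal-contrast changepoint at single-base resolution
#' (within one window of the coarse edge). Segments touching a contig end
#' are flagged.
#'
#' @param profile A `gc_profile` from [compute_gc_profile()].
#' @param sequence The profiled sequence (needed for edge refinement and
#'   segment GC); character or `DNAString`.
#' @param baseline Host baseline GC fraction; defaults to the median of the
#'   profile values (robust to the small planted-element content).
#' @param delta Required GC contrast in percentage points (> 0).
#' @param min_len Minimum segment length (bp).
#' @param merge_gap Maximum gap (bp) bridged between adjacent low runs.
#' @return A data frame of candidate segments: `start`, `end`, `mean_gc`,
#'   `host_baseline_gc`, `at_contig_end`.
#' @export
call_low_gc_segments <- function(profile, sequence, baseline = NULL, delta = 15,
                                 min_len = 2000L, merge_gap = 1000L) {
  stopifnot(inherits(profile, "gc_profile"))
  if (delta <= 0) stop("parameter error: delta must be > 0")
  seq_chr <- toupper(as.character(sequence))
  vals <- profile$values
  empty <- data.frame(start = integer(0), end = integer(0), mean_gc = numeric(0),
                      host_baseline_gc = numeric(0), at_contig_end = logical(0))
  if (length(vals) == 0) return(empty)
  if (is.null(baseline)) baseline <- median(vals, na.rm = TRUE)
  thr <- baseline - delta / 100
  low <- !is.na(vals) & vals <= thr
  if (!any(low)) return(empty)
  r <- rle(low)
  ends_i <- cumsum(r$lengths)
  starts_i <- ends_i - r$lengths + 1
  runs <- data.frame(first = starts_i[r$values], last = ends_i[r$values])
  # window index -> bp
  runs$start <- (runs$first - 1L) * profile$step + 1L
  runs$end <- (runs$last - 1L) * profile$step + profile$window
  ir <- IRanges::reduce(IRanges::IRanges(runs$start, runs$end),
                        min.gapwidth = merge_gap + 1L)
  seg <- data.frame(start = IRanges::start(ir), end = IRanges::end(ir))
  seg <- seg[seg$end - seg$start + 1 >= min_len, , drop = FALSE]
  if (nrow(seg) == 0) return(empty)
  n <- profile$seq_length
  seg$end <- pmin(seg$end, n)
  # within one window of a contig end there is no room for a host
  # signature; snap the segment to the end instead of refining
  seg$start[seg$start - 1 < profile$window] <- 1L
  seg$end[n - seg$end < profile$window] <- n
  for (i in seq_len(nrow(seg))) {
    if (seg$start[i] > 1) {
      cut <- .refine_edge(seq_chr, seg$start[i], profile$window, low_side = "right")
      seg$start[i] <- cut + 1L
    }
    if (seg$end[i] < n) {
      seg$end[i] <- .refine_edge(seq_chr, seg$end[i], profile$window, low_side = "left")
    }
  }
  seg$mean_gc <- vapply(seq_len(nrow(seg)), function(i) {
    gc_fraction(substring(seq_chr, seg$start[i], seg$end[i]))
  }, numeric(1))
  seg$host_baseline_gc <- baseline
  seg$at_contig_end <- seg$start == 1L | seg$end == n
  seg <- seg[seg$mean_gc < baseline, , drop = FALSE]
  rownames(seg) <- NULL
  seg
}

#' Scan a whole assembly for low-GC candidate segments
#'
#' Applies [compute_gc_profile()] and [call_low_gc_segments()] per contig,
#' with the baseline taken as the median window GC across the whole
#' assembly.
#'
#' @param assembly A [Biostrings::DNAStringSet].
#' @inheritParams call_low_gc_segments
#' @param window,step Profile parameters.
#' @return Data frame with `contig` plus the columns of
#'   [call_low_gc_segments()].
#' @export
scan_gc <- function(assembly, window = 500L, step = 100L, delta = 15,
                    min_len = 2000L, merge_gap = 1000L, baseline = NULL) {
  profiles <- lapply(seq_along(assembly), function(i) {
    compute_gc_profile(assembly[[i]], window, step)
  })
  if (is.null(baseline)) {
    baseline <- median(unlist(lapply(profiles, `[[`, "values")), na.rm = TRUE)
  }
  res <- lapply(seq_along(assembly), function(i) {
    seg <- call_low_gc_segments(profiles[[i]], assembly[[i]], baseline = baseline,
                                delta = delta, min_len = min_len,
                                merge_gap = merge_gap)
    if (nrow(seg)) cbind(contig = names(assembly)[i], seg) else NULL
  })
  out <- do.call(rbind, res)
  if (is.null(out)) {
    out <- data.frame(contig = character(0), start = integer(0), end = integer(0),
                      mean_gc = numeric(0), host_baseline_gc = numeric(0),
                      at_contig_end = logical(0))
  }
  out
}
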
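#' @importFrom methods as is
#' @importFrom stats median runif setNames cor wilcox.test dhyper pbinom
#' @importFrom utils head tail
NULL

# Run code with a private RNG stream so package-internal randomness neither
# disturbs nor depends on the caller's RNG state.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Sample a random DNA sequence at a target GC content
#'
#' Bases are drawn i.i.d. with P(G) = P(C) = gc/2 and P(A) = P(T) = (1-gc)/2.
#'
#' @param n Sequence length in bp.
#' @param gc Target GC fraction in \[0, 1\].
#' @return A single character string of length `n`.
#' @export
random_dna <- function(n, gc = 0.5) {
  stopifnot(n >= 0, gc >= 0, gc <= 1)
  if (n == 0) return("")
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = p), collapse = "")
}

# Per-base substitution (no indels). Substituted bases are drawn uniformly
# from the three alternatives.
mutate_dna <- function(seq, rate) {
  if (rate <= 0 || nchar(seq) == 0) return(seq)
  x <- strsplit(seq, "", fixed = TRUE)[[1]]
  hit <- which(runif(length(x)) < rate)
  if (length(hit)) {
    alt <- lapply(x[hit], function(b) setdiff(c("A", "C", "G", "T"), b))
    x[hit] <- vapply(alt, function(a) sample(a, 1), character(1))
  }
  paste(x, collapse = "")
}

mutate_protein <- function(pep, rate) {
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  x <- strsplit(pep, "", fixed = TRUE)[[1]]
  hit <- which(runif(length(x)) < rate)
  if (length(hit)) {
    x[hit] <- vapply(x[hit], function(b) sample(setdiff(aa, b), 1), character(1))
  }
  paste(x, collapse = "")
}

#' Reverse complement of a character sequence
#' @param seq DNA string.
#' @return Character string.
#' @export
revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

#' GC fraction of a sequence
#'
#' Ambiguous bases (N) are excluded from numerator and denominator.
#' @param seq Character or `DNAString`.
#' @return GC fraction, or `NA` for an all-N sequence.
#' @export
gc_fraction <- function(seq) {
  x <- if (is(seq, "DNAString")) seq else Biostrings::DNAString(seq)
  f <- Biostrings::letterFrequency(x, c("G", "C", "N"))
  denom <- length(x) - f[["N"]]
  if (denom == 0) return(NA_real_)
  (f[["G"]] + f[["C"]]) / denom
}

# All k-mers of a character sequence as a character vector (position i ->
# substring [i, i+k-1]). Vectorised substring keeps this fast at scan scale.
kmers <- function(seq, k) {
  n <- nchar(seq)
  if (n < k) return(character(0))
  starts <- seq_len(n - k + 1)
  substring(seq, starts, starts + k - 1)
}

# Adjusted Rand index between two label vectors.
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_i <- sum(comb2(rowSums(tab)))
  sum_j <- sum(comb2(colSums(tab)))
  n2 <- comb2(length(a))
  expected <- sum_i * sum_j / n2
  maxidx <- (sum_i + sum_j) / 2
  if (maxidx == expected) return(1)
  (sum_ij - expected) / (maxidx - expected)
}

# Excise intervals (data.frame start/end, 1-based closed) from a sequence.
# Returns the spliced sequence plus a block map for projecting coordinates
# on the excised sequence back onto the original one.
excise_intervals <- function(seq, intervals) {
  n <- nchar(seq)
  if (is.null(intervals) || nrow(intervals) == 0) {
    return(list(seq = seq, map = data.frame(orig_start = 1, orig_end = n, new_start = 1)))
  }
  ir <- IRanges::reduce(IRanges::IRanges(intervals$start, intervals$end))
  keep <- IRanges::setdiff(IRanges::IRanges(1, n), ir)
  pieces <- substring(seq, IRanges::start(keep), IRanges::end(keep))
  widths <- IRanges::width(keep)
  new_start <- cumsum(c(1, head(widths, -1)))
  list(
    seq = paste(pieces, collapse = ""),
    map = data.frame(orig_start = IRanges::start(keep), orig_end = IRanges::end(keep),
                     new_start = new_start)
  )
}

# Project an original-sequence position onto the excised sequence
# (positions inside an excised gap clamp to the end of the previous block).
map_fwd <- function(pos, map) {
  i <- findInterval(pos, map$orig_start)
  i[i < 1] <- 1
  map$new_start[i] + pmin(pos - map$orig_start[i], map$orig_end[i] - map$orig_start[i])
}

# Project a position on the excised sequence back to the original sequence.
map_back <- function(pos, map) {
  ends <- map$new_start + (map$orig_end - map$orig_start)
  i <- findInterval(pos, map$new_start)
  i[i < 1] <- 1
  map$orig_start[i] + pmin(pos - map$new_start[i], map$orig_end[i] - map$orig_start[i])
}

reciprocal_overlap <- function(s1, e1, s2, e2) {
  ov <- max(0, min(e1, e2) - max(s1, s2) + 1)
  min(ov / (e1 - s1 + 1), ov / (e2 - s2 + 1))
}
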
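# Word-match dot plots, block-similarity, single-linkage typing of complete
# elements, and GC-group labeling.

#' Exact word-match dot plot
#'
#' All exact matches of words of length `word` between every ordered pair
#' of sequences, on the forward and reverse-complement strands. A
#' computable stand-in for visual dot-plot block patterns.
#'
#' @param sequences Named character vector or `DNAStringSet`.
#' @param word Word length (>= 4; default 10). Words containing N are
#'   skipped.
#' @return Object of class `wordmatch_matrix`: list with `ids`, `lengths`,
#'   `word`, and `matches` (data frame `q`, `t`, `qpos`, `tpos`, `strand`;
#'   `tpos` is the word start on the forward strand of the target).
#' @export
wordmatch_dotplot <- function(sequences, word = 10L) {
  if (word < 4) stop("parameter error: word length must be >= 4")
  ids <- names(sequences)
  seqs <- toupper(as.character(sequences))
  if (is.null(ids)) ids <- paste0("seq", seq_along(seqs))
  word <- as.integer(word)
  km <- lapply(seqs, function(s) {
    w <- kmers(s, word)
    w[grepl("N", w, fixed = TRUE)] <- NA
    w
  })
  res <- list()
  for (i in seq_along(seqs)) {
    for (j in seq_along(seqs)) {
      for (strand in c("+", "-")) {
        tw <- if (strand == "+") km[[j]] else {
          w <- kmers(revcomp(seqs[[j]]), word)
          w[grepl("N", w, fixed = TRUE)] <- NA
          w
        }
        # positions of every shared word in both sequences
        shared <- intersect(km[[i]], tw)
        shared <- shared[!is.na(shared)]
        if (!length(shared)) next
        qp <- which(km[[i]] %in% shared)
        tp <- which(tw %in% shared)
        qs <- split(qp, km[[i]][qp])
        ts <- split(tp, tw[tp])
        common <- intersect(names(qs), names(ts))
        pairs <- lapply(common, function(wd) {
          expand.grid(qpos = qs[[wd]], tpos = ts[[wd]])
        })
        pairs <- do.call(rbind, pairs)
        if (strand == "-") {
          # map positions on the reverse strand back to forward coordinates
          pairs$tpos <- nchar(seqs[[j]]) - (pairs$tpos + word - 1L) + 1L
        }
        res[[length(res) + 1]] <- data.frame(q = ids[i], t = ids[j],
                                             qpos = pairs$qpos, tpos = pairs$tpos,
                                             strand = strand)
      }
    }
  }
  matches <- if (length(res)) do.call(rbind, res) else {
    data.frame(q = character(0), t = character(0), qpos = integer(0),
               tpos = integer(0), strand = character(0))
  }
  structure(list(ids = ids, lengths = nchar(seqs), word = word,
                 matches = matches),
            class = "wordmatch_matrix")
}

# Strand-aware block coverage of the shorter sequence: the fraction of its
# bases covered by shared words that lie on dense dot-plot diagonals
# (>= min_hits matches within one diagonal band). Chaining by diagonal is
# what makes this a proxy for visual block patterns: isolated chance
# matches - frequent between long sequences of similar skewed base
# composition - scatter across diagonals and are discarded.
element_similarity <- function(a, b, word = 10L, band = 20L, min_hits = 3L) {
  if (nchar(a) > nchar(b)) { tmp <- a; a <- b; b <- tmp }
  ka <- kmers(a, word)
  keep <- integer(0)
  for (strand in c("+", "-")) {
    kb <- if (strand == "+") kmers(b, word) else kmers(revcomp(b), word)
    shared <- intersect(ka, kb)
    if (!length(shared)) next
    qp <- which(ka %in% shared)
    tp <- which(kb %in% shared)
    ts <- split(tp, kb[tp])
    nb <- lengths(ts)[ka[qp]]
    pairs_q <- rep(qp, nb)
    pairs_t <- unlist(ts[ka[qp]], use.names = FALSE)
    bin <- (pairs_q - pairs_t) %/% band
    good <- names(which(table(bin) >= min_hits))
    keep <- c(keep, pairs_q[as.character(bin) %in% good])
  }
  if (!length(keep)) return(0)
  cov <- IRanges::reduce(IRanges::IRanges(unique(keep), unique(keep) + word - 1L))
  sum(IRanges::width(cov)) / nchar(a)
}

#' Pairwise similarity matrix of elements
#'
#' @param sequences Named character vector or `DNAStringSet` of element
#'   sequences (retrotransposon insertions excised).
#' @param word Word length (default 10).
#' @return Symmetric numeric matrix of shared-word coverages in \[0, 1\].
#' @export
similarity_matrix <- function(sequences, word = 10L) {
  ids <- names(sequences)
  seqs <- toupper(as.character(sequences))
  n <- length(seqs)
  m <- diag(1, n)
  if (is.null(ids)) ids <- paste0("seq", seq_along(seqs))
  dimnames(m) <- list(ids, ids)
  if (n < 2) return(m)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      m[i, j] <- m[j, i] <- element_similarity(seqs[[i]], seqs[[j]], word)
    }
  }
  m
}

#' Cluster complete elements into types
#'
#' Single-linkage clustering on shared-word coverage at the given linkage
#' threshold. Clusters are numbered by ascending median GC (ties by
#' descending size), mirroring the low-GC types 1-4 / mid-GC types 5-8
#' ordering, and the longest member of each cluster is designated the type
#' species.
#'
#' @param sequences Named element sequences (insertions excised first).
#' @param gc Numeric vector of element GC fractions (same order).
#' @param word Word length for the similarity statistic.
#' @param link Linkage threshold on coverage (default 0.30).
#' @return Object of class `type_clusters`: data frame `element`
#'   (`id`, `cluster`, `gc_group`, `type_species`) plus the similarity
#'   matrix as attribute `similarity`.
#' @export
cluster_elements <- function(sequences, gc, word = 10L, link = 0.30) {
  ids <- names(sequences)
  seqs <- toupper(as.character(sequences))
  if (is.null(ids)) ids <- paste0("el", seq_along(seqs))
  names(seqs) <- ids
  stopifnot(length(gc) == length(seqs))
  n <- length(seqs)
  if (n == 0) {
    return(structure(data.frame(id = character(0), cluster = integer(0),
                                gc_group = character(0), type_species = logical(0)),
                     class = c("type_clusters", "data.frame")))
  }
  if (n == 1) {
    out <- data.frame(id = ids, cluster = 1L, gc_group = assign_gc_group(gc),
                      type_species = TRUE)
    attr(out, "similarity") <- matrix(1, 1, 1, dimnames = list(ids, ids))
    class(out) <- c("type_clusters", "data.frame")
    return(out)
  }
  sim <- similarity_matrix(seqs, word)
  hc <- stats::hclust(stats::as.dist(1 - sim), method = "single")
  raw <- stats::cutree(hc, h = 1 - link)
  # renumber by ascending median GC, then descending size; ties in id order
  stats_df <- data.frame(cluster = sort(unique(raw)))
  stats_df$median_gc <- vapply(stats_df$cluster, function(k) median(gc[raw == k]), numeric(1))
  stats_df$size <- vapply(stats_df$cluster, function(k) sum(raw == k), numeric(1))
  ord <- order(stats_df$median_gc, -stats_df$size, stats_df$cluster)
  remap <- setNames(seq_along(ord), stats_df$cluster[ord])
  cl <- unname(remap[as.character(raw)])
  lens <- nchar(seqs)
  species <- logical(n)
  for (k in unique(cl)) {
    members <- which(cl == k)
    species[members[which.max(lens[members])]] <- TRUE
  }
  out <- data.frame(id = ids, cluster = as.integer(cl),
                    gc_group = assign_gc_group(gc), type_species = species)
  attr(out, "similarity") <- sim
  class(out) <- c("type_clusters", "data.frame")
  out
}

#' Assign the GC group of an element
#'
#' Elements below 43% GC (the midpoint of the observed gap between the
#' low-GC group, up to 38.5%, and the mid-GC group, from 47.2%) are "low";
#' at or above the cut they are "mid". GC must be computed after
#' retrotransposon excision.
#'
#' @param gc Numeric vector of GC fractions.
#' @return Character vector of `"low"` / `"mid"`.
#' @export
assign_gc_group <- function(gc) {
  ifelse(gc < 0.43, "low", "mid")
}
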
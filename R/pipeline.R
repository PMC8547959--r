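# End-to-end driver: GC screen -> homology confirmation -> delimitation ->
# typing -> retrotransposon resolution -> quantification -> reports.

#' Default pipeline parameters
#'
#' All stage thresholds in one place: GC screen (window 500 / step 100 /
#' delta 15 points / min 2 kb / merge 1 kb), candidate joining across
#' insertion-sized high-GC gaps (up to 12 kb, gap GC at least 3 points
#' below host), homology confirmation (one ORF at >= 50 bits), TIR calling
#' (>= 100 bp at >= 0.9 identity within 3 kb windows), TSD search (<= 15
#' bp), within-element insertion calling (10 points over the element
#' background, 2-12 kb), and word-10 typing with 0.30 single-linkage.
#'
#' @return Named list of parameters.
#' @export
default_params <- function() {
  list(gc_window = 500L, gc_step = 100L, gc_delta = 15, gc_min_len = 2000L,
       gc_prejoin_min = 500L,
       gc_merge_gap = 1000L, join_max_gap = 12000L, join_host_margin = 0.03,
       min_bitscore = 50, min_orf_aa = 50L,
       tir_min = 100L, tir_identity = 0.9, tir_window = 3000L, tsd_max = 15L,
       ngaro_delta = 10, ngaro_min = 2000L, ngaro_max = 12000L,
       ngaro_min_coverage = 0.15, word = 10L, link = 0.30)
}

# Join adjacent low-GC segments separated by an insertion-sized gap whose
# GC is clearly below the host baseline (a GC-rich retrotransposon, or an
# elevated stretch inside a mid-GC element, splits one element into two
# GC-screen segments; true host gaps stay at baseline and are never
# joined).
.join_candidates <- function(segs, assembly, params) {
  if (nrow(segs) < 2) return(segs)
  out <- list()
  for (ctg in unique(segs$contig)) {
    s <- segs[segs$contig == ctg, , drop = FALSE]
    s <- s[order(s$start), , drop = FALSE]
    seq_chr <- as.character(assembly[[ctg]])
    cur <- s[1, , drop = FALSE]
    for (i in seq_len(nrow(s))[-1]) {
      gap_s <- cur$end + 1L
      gap_e <- s$start[i] - 1L
      gap_len <- gap_e - gap_s + 1L
      gap_gc <- if (gap_len > 0) gc_fraction(substring(seq_chr, gap_s, gap_e)) else 0
      if (gap_len <= params$join_max_gap &&
          gap_gc <= s$host_baseline_gc[i] - params$join_host_margin) {
        cur$end <- s$end[i]
        cur$mean_gc <- gc_fraction(substring(seq_chr, cur$start, cur$end))
        cur$at_contig_end <- cur$at_contig_end || s$at_contig_end[i]
      } else {
        out[[length(out) + 1]] <- cur
        cur <- s[i, , drop = FALSE]
      }
    }
    out[[length(out) + 1]] <- cur
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Detect, delimit and classify elements and retrotransposons
#'
#' The detection rule mirrors the two redundant screens: a candidate must
#' show the low-GC signature and contain at least one ORF with a
#' confirmed hit to the reference virophage proteome. Candidates are then
#' delimited by their TIRs, classified complete/partial, TSD-called,
#' typed, and their retrotransposon insertions resolved; host-integrated
#' retrotransposon copies are found by template seeding.
#'
#' @param assembly [Biostrings::DNAStringSet] (or a FASTA path).
#' @param reference Reference proteome ([Biostrings::AAStringSet]).
#' @param type_db Per-type protein sets ([type_species_db()]).
#' @param ngaro_db Retrotransposon templates ([ngaro_templates()]).
#' @param params Parameter list ([default_params()]).
#' @return List: `elements`, `orfs`, `ngaros`, `clusters`, `segments`,
#'   `annotations` (feature bundle), `bias` (insertion-site stats or
#'   `NULL`), `params`.
#' @export
detect_elements <- function(assembly, reference = reference_proteome(),
                            type_db = type_species_db(),
                            ngaro_db = ngaro_templates(),
                            params = default_params()) {
  if (is.character(assembly) && length(assembly) == 1) {
    assembly <- read_fasta(assembly)
  }
  # short low-GC runs are kept until after joining, so that element tails
  # cut off by an insertion near one end are not lost
  segs <- scan_gc(assembly, params$gc_window, params$gc_step, params$gc_delta,
                  params$gc_prejoin_min, params$gc_merge_gap)
  cand <- .join_candidates(segs, assembly, params)
  cand <- cand[cand$end - cand$start + 1 >= params$gc_min_len, , drop = FALSE]
  rownames(cand) <- NULL

  elements <- list(); orf_rows <- list(); ngaro_rows <- list(); ann_rows <- list()
  cluster_input <- list()
  orphan_ngaros <- list()
  el_meta <- list()  # per-element internals for the bias test

  for (i in seq_len(nrow(cand))) {
    ctg <- cand$contig[i]
    seq_chr <- as.character(assembly[[ctg]])
    clen <- nchar(seq_chr)

    # resolve candidate-internal high-GC insertions and confirm them as
    # retrotransposons before anything else uses the excised sequence
    iv <- detect_high_gc_insertions(list(contig = ctg, start = cand$start[i],
                                         end = cand$end[i]), assembly,
                                    params$ngaro_delta, params$ngaro_min,
                                    params$ngaro_max)
    ins <- list()
    if (nrow(iv)) {
      for (k in seq_len(nrow(iv))) {
        snap <- .snap_ngaro(list(contig = ctg, start = iv$start[k], end = iv$end[k]),
                            assembly)
        cls <- classify_ngaro(substring(seq_chr, snap$start, snap$end), ngaro_db,
                              params$ngaro_min_coverage)
        if (!is.na(cls$type_id)) {
          ins[[length(ins) + 1]] <- list(start = snap$start, end = snap$end,
                                         type_id = cls$type_id,
                                         variant = cls$variant,
                                         coverage = cls$coverage,
                                         structure = snap$structure)
        }
      }
    }
    ins_df <- if (length(ins)) {
      data.frame(start = vapply(ins, `[[`, numeric(1), "start"),
                 end = vapply(ins, `[[`, numeric(1), "end"))
    } else NULL

    region <- substring(seq_chr, cand$start[i], cand$end[i])
    rel_ins <- if (!is.null(ins_df)) {
      data.frame(start = pmax(ins_df$start - cand$start[i] + 1L, 1L),
                 end = pmin(ins_df$end - cand$start[i] + 1L, nchar(region)))
    } else NULL
    ex <- excise_intervals(region, rel_ins)
    orfs <- find_orfs_six_frame(ex$seq, params$min_orf_aa)
    ann <- annotate_orfs(orfs, reference, params$min_bitscore)
    confirmed <- any(!is.na(ann$label))
    if (!confirmed) {
      # not an element; keep any confirmed retrotransposons as host copies
      for (x in ins) {
        orphan_ngaros[[length(orphan_ngaros) + 1]] <-
          data.frame(contig = ctg, start = x$start, end = x$end,
                     type_id = x$type_id, variant = x$variant,
                     coverage = x$coverage, container = "host",
                     container_id = NA_character_)
      }
      next
    }

    rec <- delimit_element(cand[i, ], assembly, insertions = ins_df,
                           min_tir = params$tir_min,
                           min_identity = params$tir_identity,
                           search_window = params$tir_window, orfs = ann)
    completeness <- classify_completeness(rec, clen)
    tsd <- if (completeness == "complete") find_tsd(assembly, rec, params$tsd_max) else NULL

    # excised element sequence and typing
    el_rel <- c(map_fwd(rec$start - cand$start[i] + 1L, ex$map),
                map_fwd(rec$end - cand$start[i] + 1L, ex$map))
    el_seq_ex <- substring(ex$seq, el_rel[1], el_rel[2])
    ta <- assign_type_by_cumulative_bitscore(el_seq_ex, type_db, params$min_orf_aa,
                                             orfs = ann)

    # contig-end partials have no TIR pair; once typed, their inner
    # junction snaps to the type's reference TIR arm
    if (completeness == "partial" && is.null(rec$tir) && rec$at_contig_end) {
      rec <- .refine_partial_boundary(rec, assembly, ta$assigned)
      el_rel <- pmin(pmax(c(map_fwd(rec$start - cand$start[i] + 1L, ex$map),
                            map_fwd(rec$end - cand$start[i] + 1L, ex$map)),
                          1L), nchar(ex$seq))
      el_seq_ex <- substring(ex$seq, el_rel[1], el_rel[2])
      rec$gc <- gc_fraction(el_seq_ex)
    }

    id <- sprintf("EM_%s_%06d", ctg, rec$start)
    n_ngaro <- length(ins)
    elements[[length(elements) + 1]] <- data.frame(
      element_id = id, contig = ctg, start = rec$start, end = rec$end,
      orientation = rec$orientation, completeness = completeness,
      gc = rec$gc, gc_group = assign_gc_group(rec$gc),
      type_id = ta$assigned, type_label = ta$label,
      tir_length = if (is.null(rec$tir)) NA_integer_ else rec$tir$length,
      tir_identity = if (is.null(rec$tir)) NA_real_ else rec$tir$identity,
      tsd_length = if (is.null(tsd)) NA_integer_ else tsd$length,
      tsd_seq = if (is.null(tsd)) NA_character_ else tsd$sequence,
      at_contig_end = rec$at_contig_end, n_ngaro = n_ngaro,
      length = rec$end - rec$start + 1L)
    if (completeness == "complete") {
      cluster_input[[id]] <- list(seq = el_seq_ex, gc = rec$gc)
    }

    # ORFs in contig coordinates
    if (nrow(ann)) {
      ann$contig_start <- map_back(ann$start, ex$map) + cand$start[i] - 1L
      ann$contig_end <- map_back(ann$end, ex$map) + cand$start[i] - 1L
      orf_rows[[length(orf_rows) + 1]] <- data.frame(
        element_id = id, contig = ctg, start = ann$contig_start,
        end = ann$contig_end, strand = ann$strand,
        length_aa = nchar(ann$peptide), label = ann$label,
        bitscore = ann$best_bitscore, fragmented = ann$fragmented)
    }

    # per-element internals for the bias test (excised coordinates
    # relative to the element start)
    genic <- ann[(!is.na(ann$label)) | nchar(ann$peptide) >= 150, , drop = FALSE]
    genic_iv <- if (nrow(genic)) {
      IRanges::reduce(IRanges::IRanges(genic$start - el_rel[1] + 1L,
                                       genic$end - el_rel[1] + 1L))
    } else IRanges::IRanges()
    tir_iv <- if (!is.null(rec$tir)) {
      IRanges::IRanges(
        c(1L, map_fwd(rec$tir$right_start - cand$start[i] + 1L, ex$map) - el_rel[1] + 1L),
        c(map_fwd(rec$tir$left_end - cand$start[i] + 1L, ex$map) - el_rel[1] + 1L,
          el_rel[2] - el_rel[1] + 1L))
    } else IRanges::IRanges()
    el_meta[[id]] <- list(len = el_rel[2] - el_rel[1] + 1L, genic = genic_iv,
                          tir = tir_iv, ex_map = ex$map,
                          cand_start = cand$start[i], el_rel = el_rel)

    for (x in ins) {
      ngaro_rows[[length(ngaro_rows) + 1]] <- data.frame(
        contig = ctg, start = x$start, end = x$end, type_id = x$type_id,
        variant = x$variant, coverage = x$coverage, container = "element",
        container_id = id)
    }
  }

  elements <- if (length(elements)) do.call(rbind, elements) else
    data.frame(element_id = character(0), contig = character(0),
               start = integer(0), end = integer(0), orientation = character(0),
               completeness = character(0), gc = numeric(0),
               gc_group = character(0), type_id = integer(0),
               type_label = character(0), tir_length = integer(0),
               tir_identity = numeric(0), tsd_length = integer(0),
               tsd_seq = character(0), at_contig_end = logical(0),
               n_ngaro = integer(0), length = integer(0))

  # clustering of complete elements
  clusters <- NULL
  if (length(cluster_input)) {
    seqs <- vapply(cluster_input, `[[`, character(1), "seq")
    gcs <- vapply(cluster_input, `[[`, numeric(1), "gc")
    clusters <- cluster_elements(seqs, gcs, params$word, params$link)
    elements$cluster <- clusters$cluster[match(elements$element_id, clusters$id)]
  } else {
    elements$cluster <- rep(NA_integer_, nrow(elements))
  }

  # host-integrated retrotransposons
  host_cand <- detect_ngaro_candidates(assembly, ngaro_db,
                                       exclude = elements[, c("contig", "start", "end")])
  if (nrow(host_cand)) {
    for (k in seq_len(nrow(host_cand))) {
      snap <- .snap_ngaro(host_cand[k, ], assembly)
      cls <- classify_ngaro(substring(as.character(assembly[[host_cand$contig[k]]]),
                                      snap$start, snap$end),
                            ngaro_db, params$ngaro_min_coverage)
      if (!is.na(cls$type_id)) {
        ngaro_rows[[length(ngaro_rows) + 1]] <- data.frame(
          contig = host_cand$contig[k], start = snap$start, end = snap$end,
          type_id = cls$type_id, variant = cls$variant, coverage = cls$coverage,
          container = "host", container_id = NA_character_)
      }
    }
  }
  ngaros <- do.call(rbind, c(ngaro_rows, orphan_ngaros))
  if (is.null(ngaros)) {
    ngaros <- data.frame(contig = character(0), start = integer(0),
                         end = integer(0), type_id = integer(0),
                         variant = character(0), coverage = numeric(0),
                         container = character(0), container_id = character(0))
  }
  if (nrow(ngaros)) {
    ngaros <- ngaros[order(ngaros$contig, ngaros$start), , drop = FALSE]
    ngaros$ngaro_id <- sprintf("NG_%s_%06d", ngaros$contig, ngaros$start)
    rownames(ngaros) <- NULL
  } else {
    ngaros$ngaro_id <- character(0)
  }

  # integration-site bias of element-contained insertions
  bias <- NULL
  in_el <- ngaros[ngaros$container == "element", , drop = FALSE]
  if (nrow(in_el) > 0 && length(el_meta)) {
    site_classes <- character(0)
    for (k in seq_len(nrow(in_el))) {
      meta <- el_meta[[in_el$container_id[k]]]
      if (is.null(meta)) next
      # insertion junction in excised element coordinates
      jx <- map_fwd(in_el$start[k] - 1L - meta$cand_start + 1L, meta$ex_map) -
        meta$el_rel[1] + 1L
      pt <- IRanges::IRanges(jx, jx)
      cls <- if (length(meta$tir) && any(IRanges::overlapsAny(pt, meta$tir))) {
        "tir"
      } else if (length(meta$genic) && any(IRanges::overlapsAny(pt, meta$genic))) {
        "genic"
      } else {
        "intergenic"
      }
      site_classes <- c(site_classes, cls)
    }
    tot_len <- sum(vapply(el_meta, `[[`, numeric(1), "len"))
    tir_b <- sum(vapply(el_meta, function(m) sum(IRanges::width(m$tir)), numeric(1)))
    gen_iv <- vapply(el_meta, function(m) {
      gen <- IRanges::setdiff(m$genic, m$tir)
      sum(IRanges::width(gen))
    }, numeric(1))
    genic_b <- sum(gen_iv)
    class_bases <- c(intergenic = tot_len - tir_b - genic_b, genic = genic_b,
                     tir = tir_b)
    if (length(site_classes)) {
      bias <- integration_bias_test(site_classes, class_bases)
    }
  }

  annotations <- .build_bundle(elements, ngaros, orf_rows)
  list(elements = elements, orfs = do.call(rbind, orf_rows), ngaros = ngaros,
       clusters = clusters, segments = cand, annotations = annotations,
       bias = bias, params = params)
}

# Assemble the coherent feature forest written to GFF3.
.build_bundle <- function(elements, ngaros, orf_rows) {
  rows <- list()
  for (i in seq_len(nrow(elements))) {
    e <- elements[i, ]
    rows[[length(rows) + 1]] <- .truth_row(e$element_id, "element", e$contig,
                                           e$start, e$end, e$orientation,
                                           type_id = e$cluster,
                                           partial = e$completeness == "partial")
    if (!is.na(e$tir_length)) {
      rows[[length(rows) + 1]] <- .truth_row(paste0(e$element_id, "_tirL"), "tir",
                                             e$contig, e$start,
                                             e$start + e$tir_length - 1L, "+",
                                             parent_id = e$element_id, label = "TIR")
      rows[[length(rows) + 1]] <- .truth_row(paste0(e$element_id, "_tirR"), "tir",
                                             e$contig, e$end - e$tir_length + 1L,
                                             e$end, "-", parent_id = e$element_id,
                                             label = "TIR")
    }
    if (!is.na(e$tsd_length)) {
      rows[[length(rows) + 1]] <- .truth_row(paste0(e$element_id, "_tsdL"), "tsd",
                                             e$contig, e$start - e$tsd_length,
                                             e$start - 1L, "+", label = e$tsd_seq)
      rows[[length(rows) + 1]] <- .truth_row(paste0(e$element_id, "_tsdR"), "tsd",
                                             e$contig, e$end + 1L,
                                             e$end + e$tsd_length, "+",
                                             label = e$tsd_seq)
    }
  }
  for (i in seq_len(nrow(ngaros))) {
    g <- ngaros[i, ]
    parent <- if (g$container == "element") g$container_id else NA_character_
    if (!is.na(parent)) {
      e <- elements[elements$element_id == parent, ]
      if (nrow(e) == 0 || g$start < e$start || g$end > e$end) parent <- NA_character_
    }
    rows[[length(rows) + 1]] <- .truth_row(g$ngaro_id, "ngaro", g$contig, g$start,
                                           g$end, "+", type_id = g$type_id,
                                           parent_id = parent,
                                           variant = g$variant,
                                           container = g$container)
  }
  if (!is.null(orf_rows) && length(orf_rows)) {
    orfs <- do.call(rbind, orf_rows)
    for (i in seq_len(nrow(orfs))) {
      o <- orfs[i, ]
      # ORFs are called on the slack-padded candidate; only those fully
      # inside the delimited element belong in its feature subtree
      e <- elements[elements$element_id == o$element_id, ]
      if (nrow(e) == 0 || o$start < e$start || o$end > e$end) next
      rows[[length(rows) + 1]] <- .truth_row(
        sprintf("%s_orf%03d", o$element_id, i), "orf", o$contig, o$start, o$end,
        o$strand, parent_id = o$element_id, label = o$label)
    }
  }
  if (!length(rows)) return(.new_truth())
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Run the full analysis pipeline
#'
#' Detection, classification and quantification over one assembly, with
#' optional read-based quantification from a SAM file and optional on-disk
#' reports. Deterministic given the same inputs and parameters.
#'
#' @param assembly `DNAStringSet` or FASTA path.
#' @param sam Optional SAM path (or `GAlignments`) for read-based
#'   fractions.
#' @param outdir Optional report directory.
#' @param params Parameter list.
#' @return List: everything from [detect_elements()], plus `fractions`
#'   (assembly side, or assembly-vs-read report when `sam` is given) and
#'   `summary` (per-type complete/partial counts).
#' @export
run_pipeline <- function(assembly, sam = NULL, outdir = NULL,
                         params = default_params()) {
  if (is.character(assembly) && length(assembly) == 1) {
    assembly <- read_fasta(assembly)
  }
  det <- detect_elements(assembly, params = params)
  ann <- rbind(
    if (nrow(det$elements)) data.frame(contig = det$elements$contig,
                                       start = det$elements$start,
                                       end = det$elements$end,
                                       class = "element") else NULL,
    if (nrow(det$ngaros)) data.frame(contig = det$ngaros$contig,
                                     start = det$ngaros$start,
                                     end = det$ngaros$end,
                                     class = "ngaro") else NULL)
  fractions <- if (is.null(ann)) {
    data.frame(class = c("host", "element", "ngaro"),
               bases = c(sum(Biostrings::width(assembly)), 0, 0),
               fraction = c(1, 0, 0))
  } else if (is.null(sam)) {
    assembly_fractions(assembly, ann)
  } else {
    fraction_report(assembly, ann, sam)
  }
  summary <- if (nrow(det$elements)) {
    stats::aggregate(list(n = det$elements$element_id),
                     by = list(type = det$elements$type_label,
                               completeness = det$elements$completeness),
                     FUN = length)
  } else {
    data.frame(type = character(0), completeness = character(0), n = integer(0))
  }
  out <- c(det, list(fractions = fractions, summary = summary))
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    utils::write.table(det$elements, file.path(outdir, "elements.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(det$ngaros, file.path(outdir, "ngaros.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(fractions, file.path(outdir, "fractions.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(summary, file.path(outdir, "summary.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (nrow(det$segments)) write_bed(det$segments, file.path(outdir, "segments.bed"))
    if (nrow(det$annotations)) {
      write_gff3(det$annotations, assembly, file.path(outdir, "annotations.gff3"))
    }
  }
  out
}
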
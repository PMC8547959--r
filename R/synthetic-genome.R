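# Synthetic genome generator: high-GC host contigs with planted endogenous
# virophage elements and Ngaro retrotransposon insertions, plus long reads.
# Every planted feature is recorded in a ground-truth table so downstream
# detection stages can be scored exactly.

#' Simulation configuration
#'
#' Collects all generator parameters. Defaults describe the study
#' conditions the package is validated under: five 1 Mb contigs at 70% GC,
#' 15 planted elements covering all eight types (three truncated at contig
#' ends), TIRs of 0.2-2.3 kb, TSDs of 1-9 bp, and six Ngaro insertions
#' (four types, two ORF1-truncated, four inside elements), with 10,000
#' error-free 8 kb reads.
#'
#' @param seed Integer seed; the whole simulation is a deterministic
#'   function of the configuration including this seed.
#' @param n_contigs,contig_lengths Number and lengths (bp) of host contigs.
#' @param host_gc Host GC fraction (default 0.70).
#' @param n_elements,n_partial Planted element count and how many of them
#'   are truncated at contig ends.
#' @param n_ngaros,n_ngaro_truncated,n_ngaro_in_elements Ngaro counts:
#'   total, ORF1-truncated, and element-contained.
#' @param tir_range,tsd_range TIR length range (bp) and TSD length range
#'   (bp) sampled per element.
#' @param mutation_rate Per-base substitution rate applied to planted
#'   element/Ngaro copies (TIR arms stay identical, as in real elements).
#' @param min_spacing Minimum distance (bp) between planted top-level
#'   features and to contig ends.
#' @param element_specs Optional explicit element plan: a data frame with
#'   columns `type_id`, `tir_length`, `tsd_length`, `contig`, `position`,
#'   `partial` (position may be NA to sample it).
#' @param ngaro_specs Optional explicit Ngaro plan: data frame with
#'   `type_id`, `truncated`, `container` ("element" or "host"), `contig`,
#'   `position` (host Ngaros).
#' @param read_params List with `n_reads`, `read_length` (bp) and
#'   `sub_rate` for the read simulator.
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       n_contigs = 5L,
                       contig_lengths = rep(1e6, n_contigs),
                       host_gc = 0.70,
                       n_elements = 15L,
                       n_partial = 3L,
                       n_ngaros = 6L,
                       n_ngaro_truncated = 2L,
                       n_ngaro_in_elements = 4L,
                       tir_range = c(200L, 2300L),
                       tsd_range = c(1L, 9L),
                       mutation_rate = 0.02,
                       min_spacing = 20000L,
                       element_specs = NULL,
                       ngaro_specs = NULL,
                       read_params = list(n_reads = 10000L, read_length = 8000L,
                                          sub_rate = 0)) {
  stopifnot(length(contig_lengths) == n_contigs,
            host_gc >= 0, host_gc <= 1,
            tsd_range[1] >= 0, tsd_range[2] <= 15,
            n_partial <= n_elements,
            n_ngaro_in_elements <= n_ngaros)
  tpl_gc <- .element_gc_targets
  if (any(tpl_gc >= host_gc - 0.10)) {
    stop("element GC targets must lie at least 10 points below host_gc for plantable detectability")
  }
  cfg <- list(seed = as.integer(seed), n_contigs = as.integer(n_contigs),
              contig_lengths = as.integer(contig_lengths), host_gc = host_gc,
              n_elements = as.integer(n_elements), n_partial = as.integer(n_partial),
              n_ngaros = as.integer(n_ngaros),
              n_ngaro_truncated = as.integer(n_ngaro_truncated),
              n_ngaro_in_elements = as.integer(n_ngaro_in_elements),
              tir_range = as.integer(tir_range), tsd_range = as.integer(tsd_range),
              mutation_rate = mutation_rate, min_spacing = as.integer(min_spacing),
              element_specs = element_specs, ngaro_specs = ngaro_specs,
              read_params = read_params)
  class(cfg) <- "sim_config"
  cfg
}

.new_truth <- function() {
  data.frame(feature_id = character(0), class = character(0), contig = character(0),
              start = integer(0), end = integer(0), strand = character(0),
              type_id = integer(0), parent_id = character(0), label = character(0),
              partial = logical(0), variant = character(0), container = character(0),
              stringsAsFactors = FALSE)
}

.truth_row <- function(feature_id, class, contig, start, end, strand = "+",
                       type_id = NA_integer_, parent_id = NA_character_,
                       label = NA_character_, partial = FALSE,
                       variant = NA_character_, container = NA_character_) {
  data.frame(feature_id = feature_id, class = class, contig = contig,
              start = as.integer(start), end = as.integer(end), strand = strand,
              type_id = as.integer(type_id), parent_id = parent_id, label = label,
              partial = partial, variant = variant, container = container,
              stringsAsFactors = FALSE)
}

#' Generate the host genome background
#'
#' Contigs are sampled i.i.d. at the configured GC content; no repeats
#' beyond the ones planted later, which keeps detection scoring
#' unambiguous.
#'
#' @param config A [sim_config()].
#' @return List with `assembly` ([Biostrings::DNAStringSet]) and `truth`
#'   (data frame with one `host` record per contig).
#' @export
generate_host_assembly <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  largest <- 21500 + 2 * max(config$tir_range)
  if (any(config$contig_lengths < 2 * largest)) {
    stop("sizing error: contig lengths must be at least twice the largest plantable feature (",
         2 * largest, " bp)")
  }
  with_seed(config$seed, {
    seqs <- vapply(config$contig_lengths, random_dna, character(1), gc = config$host_gc)
    names(seqs) <- sprintf("contig_%02d", seq_along(seqs))
    truth <- do.call(rbind, lapply(seq_along(seqs), function(i) {
      .truth_row(sprintf("host_%02d", i), "host", names(seqs)[i], 1L, nchar(seqs[i]))
    }))
    list(assembly = Biostrings::DNAStringSet(seqs), truth = truth)
  })
}

# Draw the element/ngaro plan for a seed when not given explicitly.
.draw_specs <- function(config) {
  n <- config$n_elements
  types <- c(1:8, sample(1:8, max(0, n - 8), replace = TRUE))[seq_len(n)]
  types <- sample(types)  # shuffle which instances are partial
  tpl <- element_templates()
  core_len <- vapply(tpl, function(t) nchar(t$seq), numeric(1))
  tir <- vapply(types, function(t) {
    hi <- min(config$tir_range[2], floor(core_len[t] * 0.4))
    as.integer(round(runif(1, config$tir_range[1], hi)))
  }, integer(1))
  el <- data.frame(
    element_id = sprintf("emale_%02d", seq_len(n)),
    type_id = types, tir_length = tir,
    tsd_length = sample(seq(config$tsd_range[1], config$tsd_range[2]), n, replace = TRUE),
    partial = rep(FALSE, n)
  )
  if (config$n_partial > 0) el$partial[seq_len(config$n_partial)] <- TRUE
  el <- el[sample(nrow(el)), , drop = FALSE]
  el$element_id <- sprintf("emale_%02d", seq_len(n))  # stable ids in plant order

  m <- config$n_ngaros
  ntypes <- c(1:4, sample(1:4, max(0, m - 4), replace = TRUE))[seq_len(m)]
  ng <- data.frame(
    ngaro_id = sprintf("ngaro_%02d", seq_len(m)),
    type_id = sample(ntypes),
    truncated = FALSE, container = "host", host_element = NA_character_
  )
  # ORF1-truncated copies sit in host DNA; full-length copies prefer elements.
  if (config$n_ngaro_truncated > 0) {
    idx <- which(ng$type_id %in% c(1, 2))
    if (length(idx) < config$n_ngaro_truncated) idx <- seq_len(m)
    ng$truncated[idx[seq_len(config$n_ngaro_truncated)]] <- TRUE
  }
  full <- which(!ng$truncated)
  inside <- full[seq_len(min(config$n_ngaro_in_elements, length(full)))]
  ng$container[inside] <- "element"
  # host elements that receive a ngaro: complete elements only, one each
  complete_ids <- el$element_id[!el$partial]
  ng$host_element[inside] <- sample(complete_ids, length(inside))
  list(elements = el, ngaros = ng)
}

# Build one ngaro instance; returns sequence and features relative to its
# own start.
.build_ngaro_instance <- function(type_id, truncated, mutation_rate, id) {
  tpl <- ngaro_templates()[[type_id]]
  seq <- tpl$seq
  orfs <- tpl$orfs
  reps <- tpl$repeats
  if (truncated) {
    # ~2 kb deletion covering ORF1, starting just after the A1 repeat
    del_start <- 301L
    del_end <- min(del_start + 1999L, orfs$end[orfs$label == "GAG"] + 60L)
    del_len <- del_end - del_start + 1L
    seq <- paste0(substring(seq, 1, del_start - 1), substring(seq, del_end + 1))
    shift <- function(x) ifelse(x > del_end, x - del_len, x)
    orfs <- orfs[orfs$start > del_end | orfs$end < del_start, , drop = FALSE]
    orfs$start <- shift(orfs$start); orfs$end <- shift(orfs$end)
    reps$start <- shift(reps$start); reps$end <- shift(reps$end)
  }
  seq <- mutate_dna(seq, mutation_rate)
  feats <- rbind(
    do.call(rbind, lapply(seq_len(nrow(orfs)), function(i) {
      .truth_row(paste0(id, "_", orfs$label[i]), "orf", NA, orfs$start[i], orfs$end[i],
                 orfs$strand[i], type_id, id, orfs$label[i])
    })),
    do.call(rbind, lapply(seq_len(nrow(reps)), function(i) {
      .truth_row(paste0(id, "_", reps$unit[i]), "repeat_unit", NA, reps$start[i],
                 reps$end[i], "+", type_id, id, reps$unit[i])
    }))
  )
  list(seq = seq, feats = feats,
       variant = if (truncated) "orf1_truncated" else "full")
}

# Build one element instance (optionally with nested ngaros); returns
# sequence and features relative to element start.
.build_element_instance <- function(spec, nested, mutation_rate) {
  tpl <- element_templates()[[spec$type_id]]
  core <- mutate_dna(tpl$seq, mutation_rate)
  tir <- mutate_dna(substring(tpl$tir, 1, spec$tir_length), mutation_rate)
  seq <- paste0(tir, core, revcomp(tir))
  L <- nchar(seq)
  id <- spec$element_id
  feats <- .truth_row(id, "element", NA, 1L, L, "+", spec$type_id,
                      partial = spec$partial)
  if (spec$tir_length > 0) {
    feats <- rbind(feats,
      .truth_row(paste0(id, "_tirL"), "tir", NA, 1L, spec$tir_length, "+",
                 spec$type_id, id, "TIR"),
      .truth_row(paste0(id, "_tirR"), "tir", NA, L - spec$tir_length + 1L, L, "-",
                 spec$type_id, id, "TIR"))
  }
  orfs <- tpl$orfs
  feats <- rbind(feats, do.call(rbind, lapply(seq_len(nrow(orfs)), function(i) {
    .truth_row(paste0(id, "_", orfs$label[i]), "orf", NA,
               orfs$start[i] + spec$tir_length, orfs$end[i] + spec$tir_length,
               orfs$strand[i], spec$type_id, id, orfs$label[i])
  })))
  # nested ngaro insertions go into the element core, never the TIR arms
  if (!is.null(nested) && nrow(nested) > 0) {
    for (k in seq_len(nrow(nested))) {
      ni <- .build_ngaro_instance(nested$type_id[k], nested$truncated[k],
                                  mutation_rate, nested$ngaro_id[k])
      # keep insertions >= 500 bp inside the element body so the element
      # tails on both sides of the insertion remain detectable
      lo <- spec$tir_length + 500L
      hi <- L - spec$tir_length - 500L
      p <- as.integer(round(runif(1, lo, hi)))  # insert after base p
      nlen <- nchar(ni$seq)
      seq <- paste0(substring(seq, 1, p), ni$seq, substring(seq, p + 1))
      stretch <- feats$start <= p & feats$end > p
      feats$end[feats$start > p] <- feats$end[feats$start > p] + nlen
      feats$start[feats$start > p] <- feats$start[feats$start > p] + nlen
      feats$end[stretch] <- feats$end[stretch] + nlen
      nf <- ni$feats
      nf$start <- nf$start + p; nf$end <- nf$end + p
      feats <- rbind(feats,
        .truth_row(nested$ngaro_id[k], "ngaro", NA, p + 1L, p + nlen, "+",
                   nested$type_id[k], id, variant = ni$variant,
                   container = "element"),
        nf)
      L <- nchar(seq)
      feats$end[feats$feature_id == id] <- L
    }
  }
  list(seq = seq, feats = feats)
}

#' Plant elements and retrotransposons into a host assembly
#'
#' Each planted element is TSD-left + TIR + core + inverted TIR + TSD-right
#' with both TSD copies identical (the target-site suffix is duplicated on
#' insertion, mirroring integrase biology). Partial elements are truncated
#' at a contig end. Nested Ngaro insertions carry their own split-repeat
#' structure. The ground truth is extended with all child features.
#'
#' @param host Result of [generate_host_assembly()].
#' @param config The same [sim_config()].
#' @return List with `assembly`, `truth` (data frame) and the realized
#'   `elements` / `ngaros` plan tables.
#' @export
plant_elements <- function(host, config) {
  with_seed(config$seed + 1L, {
    specs <- if (!is.null(config$element_specs)) {
      list(elements = config$element_specs, ngaros = config$ngaro_specs)
    } else {
      .draw_specs(config)
    }
    el <- specs$elements
    ng <- if (is.null(specs$ngaros)) {
      data.frame(ngaro_id = character(0), type_id = integer(0), truncated = logical(0),
                 container = character(0), host_element = character(0))
    } else specs$ngaros
    contigs <- as.character(host$assembly)
    lens <- nchar(contigs)
    cnames <- names(contigs)

    # build instances
    inst <- lapply(seq_len(nrow(el)), function(i) {
      nested <- ng[!is.na(ng$host_element) & ng$host_element == el$element_id[i], , drop = FALSE]
      .build_element_instance(el[i, ], nested, config$mutation_rate)
    })
    host_ng <- ng[ng$container == "host", , drop = FALSE]
    ng_inst <- lapply(seq_len(nrow(host_ng)), function(i) {
      .build_ngaro_instance(host_ng$type_id[i], host_ng$truncated[i],
                            config$mutation_rate, host_ng$ngaro_id[i])
    })

    # choose placements: partial elements claim contig ends, the rest are
    # interior positions with min_spacing separation
    n_top <- nrow(el) + nrow(host_ng)
    placement <- data.frame(kind = c(rep("element", nrow(el)), rep("ngaro", nrow(host_ng))),
                            idx = c(seq_len(nrow(el)), seq_len(max(0, nrow(host_ng)))),
                            contig = NA_integer_, pos = NA_real_, side = NA_character_)
    is_partial <- c(el$partial, rep(FALSE, nrow(host_ng)))
    taken <- lapply(seq_along(contigs), function(i) numeric(0))
    ends_used <- list()  # "contig:side"
    for (j in seq_len(n_top)) {
      if (is_partial[j]) {
        repeat {
          ci <- sample(seq_along(contigs), 1, prob = lens)
          side <- sample(c("left", "right"), 1)
          key <- paste0(ci, ":", side)
          if (!key %in% names(ends_used)) { ends_used[[key]] <- TRUE; break }
        }
        placement$contig[j] <- ci; placement$side[j] <- side
        next
      }
      repeat {
        ci <- sample(seq_along(contigs), 1, prob = lens)
        p <- round(runif(1, config$min_spacing, lens[ci] - config$min_spacing))
        if (all(abs(taken[[ci]] - p) >= config$min_spacing + 25000)) {
          taken[[ci]] <- c(taken[[ci]], p)
          placement$contig[j] <- ci; placement$pos[j] <- p
          break
        }
      }
    }

    truth <- host$truth
    # Splice contig by contig: left-end partials first (they prepend), then
    # interior insertions left to right with an accumulated offset, then
    # right-end partials (they append).
    clip_partial <- function(this, keep, side) {
      # keep `keep` bp of the element at a contig end; retain only fully
      # contained child features plus the clipped element record itself
      L <- nchar(this$seq)
      feats <- this$feats
      id <- feats$feature_id[feats$class == "element"][1]
      if (side == "right") {   # 5' part of the element ends the contig
        seq <- substring(this$seq, 1, keep)
        full <- feats$end <= keep
        feats <- feats[full | feats$feature_id == id, , drop = FALSE]
        feats$end <- pmin(feats$end, keep)
      } else {                 # 3' part of the element starts the contig
        cut <- L - keep
        seq <- substring(this$seq, cut + 1, L)
        full <- feats$start >= cut + 1
        feats <- feats[full | feats$feature_id == id, , drop = FALSE]
        feats$start <- pmax(feats$start - cut, 1L)
        feats$end <- feats$end - cut
      }
      feats$partial[feats$feature_id == id] <- TRUE
      list(seq = seq, feats = feats)
    }
    for (ci in seq_along(contigs)) {
      offset <- 0L
      lrows <- which(placement$contig == ci & is_partial & placement$side == "left")
      for (j in lrows) {
        idx <- placement$idx[j]
        this <- inst[[idx]]
        keep <- as.integer(round(nchar(this$seq) * runif(1, 0.45, 0.7)))
        cp <- clip_partial(this, keep, "left")
        contigs[ci] <- paste0(cp$seq, contigs[ci])
        cp$feats$contig <- cnames[ci]
        truth <- rbind(truth, cp$feats)
        offset <- offset + nchar(cp$seq)
      }
      rows <- which(placement$contig == ci & !is_partial)
      rows <- rows[order(placement$pos[rows])]
      for (j in rows) {
        kind <- placement$kind[j]; idx <- placement$idx[j]
        p <- as.integer(placement$pos[j]) + offset
        if (kind == "element") {
          this <- inst[[idx]]; tsd_len <- el$tsd_length[idx]
          id <- el$element_id[idx]
        } else {
          this <- list(seq = ng_inst[[idx]]$seq, feats = NULL)
          tsd_len <- 0L
          id <- host_ng$ngaro_id[idx]
        }
        tsd <- if (tsd_len > 0) substring(contigs[ci], p - tsd_len + 1, p) else ""
        block <- paste0(this$seq, tsd)
        # substring() must be given an explicit end: its default last is
        # only 1e6 and would silently truncate megabase contigs
        contigs[ci] <- paste0(substring(contigs[ci], 1, p), block,
                              substring(contigs[ci], p + 1, nchar(contigs[ci])))
        L <- nchar(this$seq)
        if (kind == "element") {
          # sanitise the junction so the planted truth is unambiguous: no
          # chance reverse-complement extension of the TIR alignment across
          # the junction, and the planted TSD is the unique longest match
          contigs[ci] <- .fix_junction(contigs[ci], p + 1L, p + L, tsd_len)
          tsd <- if (tsd_len > 0) substring(contigs[ci], p - tsd_len + 1, p) else ""
          feats <- this$feats
          feats$contig <- cnames[ci]
          feats$start <- feats$start + p; feats$end <- feats$end + p
          if (tsd_len > 0) {
            # TSD copies flank the element, so they are recorded as
            # siblings (the element id is recoverable from the feature id)
            feats <- rbind(feats,
              .truth_row(paste0(id, "_tsdL"), "tsd", cnames[ci],
                         p - tsd_len + 1L, p, "+", label = tsd),
              .truth_row(paste0(id, "_tsdR"), "tsd", cnames[ci],
                         p + L + 1L, p + L + tsd_len, "+", label = tsd))
          }
          truth <- rbind(truth, feats)
        } else {
          nf <- ng_inst[[idx]]$feats
          nf$contig <- cnames[ci]; nf$start <- nf$start + p; nf$end <- nf$end + p
          truth <- rbind(truth,
            .truth_row(id, "ngaro", cnames[ci], p + 1L, p + L, "+",
                       host_ng$type_id[idx], NA_character_,
                       variant = ng_inst[[idx]]$variant, container = "host"),
            nf)
        }
        offset <- offset + nchar(block)
      }
      rrows <- which(placement$contig == ci & is_partial & placement$side == "right")
      for (j in rrows) {
        idx <- placement$idx[j]
        this <- inst[[idx]]
        keep <- as.integer(round(nchar(this$seq) * runif(1, 0.45, 0.7)))
        cp <- clip_partial(this, keep, "right")
        off <- nchar(contigs[ci])
        contigs[ci] <- paste0(contigs[ci], cp$seq)
        cp$feats$contig <- cnames[ci]
        cp$feats$start <- cp$feats$start + off
        cp$feats$end <- cp$feats$end + off
        truth <- rbind(truth, cp$feats)
      }
      # refresh host record length
      truth$end[truth$class == "host" & truth$contig == cnames[ci]] <- nchar(contigs[ci])
    }
    rownames(truth) <- NULL
    list(assembly = Biostrings::DNAStringSet(setNames(contigs, cnames)),
         truth = truth, elements = el, ngaros = ng)
  })
}

# Sanitise an insertion junction so the planted truth is unambiguous.
# (a) No outward alignment extension from the element ends may score zero
#     or better under the TIR aligner (+1 reverse-complement match / -2
#     mismatch, affine gaps 5/2), checked for direct pairing and for
#     small offsets (single short gap at the junction): the aligner keeps
#     zero-gain tie extensions, and the direct-repeat symmetry of the TSD
#     makes such ties common. Offending bases are re-drawn; a TSD base is
#     always changed in both copies so the duplication stays exact.
# (b) The longest exact junction match must equal the planted TSD length,
#     so the recorded TSD is the unique parsimonious annotation.
.fix_junction <- function(contig, el_start, el_end, tsd_len,
                          max_scan = 12L, max_len = 15L) {
  comp <- c(A = "T", T = "A", G = "C", C = "G")
  n <- nchar(contig)
  found_tsd <- function() {
    avail <- min(max_len, el_start - 1L, n - el_end)
    if (avail <= 0) return(0L)
    up <- substring(contig, el_start - avail, el_start - 1L)
    down <- substring(contig, el_end + 1L, el_end + avail)
    for (L in rev(seq_len(avail))) {
      if (substring(up, avail - L + 1) == substring(down, 1, L)) return(L)
    }
    0L
  }
  # change outward base j on one side; TSD bases change in both copies
  set_right <- function(j, newb) {
    substring(contig, el_end + j, el_end + j) <<- newb
    if (j <= tsd_len) {
      pos <- el_start - tsd_len + j - 1L
      substring(contig, pos, pos) <<- newb
    }
  }
  offsets <- expand.grid(dl = 0:3, dr = 0:3)
  offsets <- offsets[offsets$dl == 0 | offsets$dr == 0, ]
  for (it in 1:200) {
    changed <- FALSE
    m <- min(max_scan, el_start - 1L - 3L, n - el_end - 3L)
    if (m >= 1) {
      l <- substring(contig, el_start - seq_len(m + 3L), el_start - seq_len(m + 3L))
      r <- substring(contig, el_end + seq_len(m + 3L), el_end + seq_len(m + 3L))
      for (o in seq_len(nrow(offsets))) {
        dl <- offsets$dl[o]; dr <- offsets$dr[o]
        penalty <- if (dl + dr > 0) 5 + 2 * (dl + dr) else 0
        k <- seq_len(m)
        score <- ifelse(l[k + dl] == comp[r[k + dr]], 1, -2)
        if (any(cumsum(score) - penalty >= 0)) {
          k0 <- which(score == 1)[1]
          j <- k0 + dr
          newb <- sample(setdiff(c("A", "C", "G", "T"),
                                 c(comp[[l[k0 + dl]]], r[j])), 1)
          set_right(j, newb)
          changed <- TRUE
          break
        }
      }
    }
    # (b) unique longest junction match
    if (!changed && tsd_len > 0 && found_tsd() != tsd_len) {
      fix_at <- el_end + tsd_len + sample.int(3, 1)
      if (fix_at <= n) {
        substring(contig, fix_at, fix_at) <- sample(c("A", "C", "G", "T"), 1)
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  contig
}

#' Simulate long reads with known placements
#'
#' Read start positions are sampled so that every reference base has equal
#' expected coverage (starts may fall partly before a contig start or run
#' past its end; reads are clipped to the contig). Reads are error-free by
#' default; an optional substitution rate adds mismatches without indels.
#'
#' @param assembly A [Biostrings::DNAStringSet].
#' @param config A [sim_config()]; `config$read_params` controls count,
#'   length and substitution rate.
#' @return List with `reads` (named character vector), `placements`
#'   (data frame `read_id`, `contig`, `start`, `end`, `strand`) and
#'   `n_skipped` (reads requested longer than any contig).
#' @export
simulate_reads <- function(assembly, config) {
  rp <- config$read_params
  with_seed(config$seed + 2L, {
    lens <- Biostrings::width(assembly)
    L <- as.integer(rp$read_length)
    if (all(L > lens)) {
      warning("requested read length exceeds all contig lengths; no reads simulated")
      return(list(reads = character(0),
                  placements = data.frame(read_id = character(0), contig = character(0),
                                          start = integer(0), end = integer(0),
                                          strand = character(0)),
                  n_skipped = as.integer(rp$n_reads)))
    }
    usable <- which(lens >= 200)
    balanced <- is.null(rp$sampling) || identical(rp$sampling, "balanced")
    if (balanced) {
      # balanced coverage: systematic start positions with a random phase
      # per contig, emulating the even genome-wide coverage of aligned
      # long-read data; every base has equal expected depth
      k <- pmax(1L, round(as.numeric(rp$n_reads) * lens[usable] / sum(as.numeric(lens[usable]))))
      ci <- rep(usable, k)
      s <- unlist(lapply(seq_along(usable), function(u) {
        span <- lens[usable[u]] + L - 1L
        stride <- span / k[u]
        floor(-L + 2 + runif(1, 0, stride) + stride * (seq_len(k[u]) - 1))
      }))
    } else {
      # i.i.d. uniform-by-position sampling
      ci <- sample(usable, rp$n_reads, replace = TRUE, prob = lens[usable])
      s <- floor(runif(rp$n_reads, -L + 2, lens[ci] + 1 - 1e-9))
    }
    start <- pmax(1, as.integer(s))
    end <- pmin(lens[ci], as.integer(s) + L - 1L)
    keep <- end - start + 1 >= 50
    ci <- ci[keep]; start <- start[keep]; end <- end[keep]
    strand <- sample(c("+", "-"), length(ci), replace = TRUE)
    ids <- sprintf("read_%06d", seq_along(ci))
    contig_chr <- as.character(assembly)
    reads <- substring(contig_chr[ci], start, end)
    if (!is.null(rp$sub_rate) && rp$sub_rate > 0) {
      reads <- vapply(reads, mutate_dna, character(1), rate = rp$sub_rate,
                      USE.NAMES = FALSE)
    }
    flip <- strand == "-"
    if (any(flip)) {
      reads[flip] <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAStringSet(reads[flip])))
    }
    list(reads = setNames(reads, ids),
         placements = data.frame(read_id = ids, contig = names(assembly)[ci],
                                 start = start, end = end, strand = strand),
         n_skipped = as.integer(sum(!keep)))
  })
}

#' Run the full simulation
#'
#' Convenience driver: host background, planted features, reads, and
#' optionally all on-disk artifacts (FASTA assembly and reads, truth GFF3 +
#' TSV, SAM alignments, resolved config JSON).
#'
#' @param config A [sim_config()].
#' @param outdir Optional output directory.
#' @return List with `assembly`, `truth`, `elements`, `ngaros`, `reads`,
#'   `placements`.
#' @export
simulate_genome <- function(config, outdir = NULL) {
  host <- generate_host_assembly(config)
  planted <- plant_elements(host, config)
  rd <- simulate_reads(planted$assembly, config)
  out <- list(assembly = planted$assembly, truth = planted$truth,
              elements = planted$elements, ngaros = planted$ngaros,
              reads = rd$reads, placements = rd$placements)
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    write_fasta(out$assembly, file.path(outdir, "assembly.fasta"))
    write_fasta(Biostrings::DNAStringSet(out$reads), file.path(outdir, "reads.fasta"))
    utils::write.table(out$truth, file.path(outdir, "truth.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    write_truth_gff3(out$truth, out$assembly, file.path(outdir, "truth.gff3"))
    write_sam(out$reads, out$placements, out$assembly, file.path(outdir, "reads.sam"))
    cfg <- config[setdiff(names(config), c("element_specs", "ngaro_specs"))]
    jsonlite::write_json(cfg, file.path(outdir, "config.json"), auto_unbox = TRUE)
  }
  out
}

#' Convert a truth table to a GRanges
#' @param truth Truth data frame from [plant_elements()].
#' @param assembly The matching assembly (for seqlengths).
#' @return A [GenomicRanges::GRanges].
#' @export
truth_granges <- function(truth, assembly = NULL) {
  gr <- GenomicRanges::GRanges(truth$contig,
                               IRanges::IRanges(truth$start, truth$end),
                               strand = truth$strand)
  S4Vectors::mcols(gr) <- truth[, c("feature_id", "class", "type_id", "parent_id",
                                    "label", "partial", "variant", "container")]
  if (!is.null(assembly)) {
    GenomeInfoDb::seqlevels(gr) <- names(assembly)
    GenomeInfoDb::seqlengths(gr) <- Biostrings::width(assembly)
  }
  gr
}
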
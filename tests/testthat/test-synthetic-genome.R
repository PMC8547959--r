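# Generator: host background, planted structure, ground truth, reads.

test_that("host background matches the requested GC and is deterministic", {
  cfg <- sim_config(seed = 11, n_contigs = 1, contig_lengths = 100000,
                    n_elements = 0, n_partial = 0, n_ngaros = 0,
                    n_ngaro_in_elements = 0, n_ngaro_truncated = 0)
  host <- generate_host_assembly(cfg)
  gc <- gc_fraction(as.character(host$assembly[[1]]))
  expect_gte(gc, 0.685)
  expect_lte(gc, 0.715)
  # realized GC equals direct base counting exactly
  b <- strsplit(as.character(host$assembly[[1]]), "")[[1]]
  expect_identical(gc, sum(b %in% c("G", "C")) / length(b))
  # byte-identical FASTA on rerun
  host2 <- generate_host_assembly(cfg)
  f1 <- tempfile(); f2 <- tempfile()
  write_fasta(host$assembly, f1); write_fasta(host2$assembly, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("undersized contigs are rejected with a sizing error", {
  cfg <- sim_config(seed = 1, n_contigs = 1, contig_lengths = 30000)
  expect_error(generate_host_assembly(cfg), "sizing")
})

test_that("full simulation is deterministic, conserved, and well nested", {
  cfg <- small_config(seed = 5)
  sim1 <- simulate_genome(cfg)
  sim2 <- simulate_genome(cfg)
  expect_identical(as.character(sim1$assembly), as.character(sim2$assembly))
  expect_identical(sim1$truth, sim2$truth)
  expect_identical(sim1$reads, sim2$reads)

  tr <- sim1$truth
  # containment: children within parents
  idx <- match(tr$parent_id, tr$feature_id)
  kids <- which(!is.na(idx))
  expect_true(all(tr$start[kids] >= tr$start[idx[kids]] &
                  tr$end[kids] <= tr$end[idx[kids]]))
  # top-level features do not overlap
  top <- tr[tr$class %in% c("element", "ngaro") & is.na(tr$parent_id), ]
  for (ctg in unique(top$contig)) {
    d <- top[top$contig == ctg, ]
    d <- d[order(d$start), ]
    if (nrow(d) > 1) expect_true(all(d$start[-1] > d$end[-nrow(d)]))
  }
  # composition conservation: host + element + ngaro = total
  total <- sum(Biostrings::width(sim1$assembly))
  fr <- assembly_fractions(sim1$assembly, tr)
  expect_equal(sum(fr$bases), total)
  expect_equal(sum(fr$fraction), 1)
})

test_that("planted TSD copies are identical and flank the element exactly", {
  sim <- simulate_genome(small_config(seed = 7))
  tr <- sim$truth
  tsd <- tr[tr$class == "tsd", ]
  tsd$element <- sub("_tsd[LR]$", "", tsd$feature_id)
  expect_gt(nrow(tsd), 0)
  for (pid in unique(tsd$element)) {
    pair <- tsd[tsd$element == pid, ]
    expect_equal(nrow(pair), 2)
    seqs <- substring(as.character(sim$assembly[[pair$contig[1]]]),
                      pair$start, pair$end)
    expect_identical(seqs[1], seqs[2])
    expect_identical(seqs[1], pair$label[1])
    # copies abut the element's outer boundaries
    el <- tr[tr$feature_id == pid, ]
    expect_equal(sort(pair$end)[1], el$start - 1L)
    expect_equal(sort(pair$start)[2], el$end + 1L)
  }
})

test_that("tsd length zero plants no junction duplication records", {
  cfg <- small_config(seed = 9, tsd_range = c(0L, 0L))
  sim <- simulate_genome(cfg)
  expect_equal(sum(sim$truth$class == "tsd"), 0)
})

test_that("realized GC of planted features stays within 2 points of spec", {
  sim <- simulate_genome(small_config(seed = 3))
  tr <- sim$truth
  tpl <- element_templates()
  el <- tr[tr$class == "element" & !tr$partial & tr$end - tr$start >= 2000, ]
  for (i in seq_len(nrow(el))) {
    s <- substring(as.character(sim$assembly[[el$contig[i]]]), el$start[i], el$end[i])
    # exclude nested retrotransposons from the element GC
    ng <- tr[tr$class == "ngaro" & !is.na(tr$parent_id) & tr$parent_id == el$feature_id[i], ]
    if (nrow(ng)) {
      rel <- data.frame(start = ng$start - el$start[i] + 1, end = ng$end - el$start[i] + 1)
      s <- excise_intervals(s, rel)$seq
    }
    expect_lt(abs(gc_fraction(s) - tpl[[el$type_id[i]]]$gc), 0.02)
  }
})

test_that("error-free reads are exact substrings at their truth placements", {
  sim <- simulate_genome(small_config(seed = 2))
  pl <- sim$placements
  pick <- seq(1, nrow(pl), length.out = 200)
  for (i in pick) {
    ref <- substring(as.character(sim$assembly[[pl$contig[i]]]), pl$start[i], pl$end[i])
    obs <- unname(sim$reads[pl$read_id[i]])
    if (pl$strand[i] == "-") obs <- revcomp(obs)
    expect_identical(obs, ref)
  }
})

test_that("reads longer than every contig are skipped with a warning", {
  cfg <- small_config(seed = 2,
                      read_params = list(n_reads = 10L, read_length = 400000L,
                                         sub_rate = 0))
  host <- generate_host_assembly(cfg)
  expect_warning(rd <- simulate_reads(host$assembly, cfg), "read length")
  expect_equal(length(rd$reads), 0)
  expect_equal(rd$n_skipped, 10L)
})

test_that("i.i.d. read sampling recovers class fractions within binomial error", {
  cfg <- small_config(seed = 13,
                      read_params = list(n_reads = 4000L, read_length = 3000L,
                                         sub_rate = 0, sampling = "uniform"))
  sim <- simulate_genome(cfg)
  ann <- sim$truth[sim$truth$class %in% c("element", "ngaro"),
                   c("contig", "start", "end", "class")]
  afr <- assembly_fractions(sim$assembly, ann)
  aln <- galignments_from_placements(sim$placements, sim$assembly)
  rfr <- read_fractions(aln, sim$assembly, ann)
  p <- afr$fraction[afr$class == "element"]
  # the per-read element fraction is a [0,1] variable with mean p, so its
  # variance is bounded by p(1-p): 3 binomial s.e. over reads bounds the
  # deviation of the mean
  se <- sqrt(p * (1 - p) / nrow(sim$placements))
  expect_lt(abs(rfr$fraction[rfr$class == "element"] - p), 3 * se)
})

test_that("template-derived copies group by template at word 10", {
  tpl <- element_templates()
  seqs <- character(0); labels <- integer(0)
  set.seed(21)
  for (t in seq_along(tpl)) {
    for (r in 1:2) {
      seqs <- c(seqs, mutate_dna(tpl[[t]]$seq, 0.025))
      labels <- c(labels, t)
    }
  }
  names(seqs) <- paste0("el", seq_along(seqs))
  sim <- similarity_matrix(seqs)
  same <- outer(labels, labels, "==") & upper.tri(sim)
  diff <- outer(labels, labels, "!=") & upper.tri(sim)
  expect_gt(min(sim[same]), max(sim[diff]))
})
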
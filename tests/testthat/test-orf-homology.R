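# Six-frame ORF calling, local protein alignment, annotation, typing.

test_that("stop-bounded ORFs are reported with forward-strand coordinates", {
  o <- find_orfs_six_frame("ATGAAATAA", min_aa = 2)
  expect_equal(nrow(o), 1)
  expect_equal(o$peptide, "MK")
  expect_equal(o$strand, "+")
  expect_equal(c(o$start, o$end), c(1L, 9L))

  o2 <- find_orfs_six_frame(revcomp("ATGAAATAA"), min_aa = 2)
  expect_equal(o2$peptide, "MK")
  expect_equal(o2$strand, "-")
  expect_equal(c(o2$start, o2$end), c(1L, 9L))
})

test_that("ORF calling is symmetric under reverse complement", {
  set.seed(41)
  s <- random_dna(6000, 0.5)
  o1 <- find_orfs_six_frame(s, 50)
  o2 <- find_orfs_six_frame(revcomp(s), 50)
  n <- nchar(s)
  # coordinates map across strands: [s, e] on rc <-> [n-e+1, n-s+1]
  key1 <- sort(paste(o1$start, o1$end))
  key2 <- sort(paste(n - o2$end + 1, n - o2$start + 1))
  expect_identical(key1, key2)
  expect_setequal(o1$peptide, o2$peptide)
})

test_that("reported ORFs satisfy the stop-codon grammar (independent scan)", {
  set.seed(43)
  s <- random_dna(10000, 0.5)
  o <- find_orfs_six_frame(s, min_aa = 100)
  stops <- c("TAA", "TAG", "TGA")
  for (i in seq_len(nrow(o))) {
    nt <- substring(s, o$start[i], o$end[i])
    if (o$strand[i] == "-") nt <- revcomp(nt)
    cods <- substring(nt, seq(1, nchar(nt) - 2, 3), seq(3, nchar(nt), 3))
    expect_equal((o$end[i] - o$start[i] + 1) %% 3, 0)
    expect_gte(length(cods) - 1, 100)             # >= min_aa before the stop
    expect_true(tail(cods, 1) %in% stops)         # stop-bounded 3'
    expect_false(any(head(cods, -1) %in% stops))  # no internal stops
  }
})

test_that("local protein alignment matches matrix lookups and handles edges", {
  h <- local_align_protein("MKT", "MKT")
  expect_equal(h$raw_score, 15)        # BLOSUM62 diagonal 5 + 5 + 5
  expect_equal(h$identity, 1)
  expect_equal(local_align_protein("MKTWL", "")$raw_score, 0)
  expect_error(local_align_protein("MK9T", "MKT"), "position 3")
})

test_that("alignment scores equal the DP oracle and are symmetric", {
  mat <- emalescan:::.blosum62x()
  set.seed(47)
  for (k in 1:50) {
    a <- random_peptide(sample(8:30, 1))
    b <- random_peptide(sample(8:30, 1))
    s <- local_align_protein(a, b)$raw_score
    expect_identical(s, sw_dp_oracle(a, b, mat))
    expect_identical(s, local_align_protein(b, a)$raw_score)
    expect_gte(s, 0)
  }
})

test_that("annotation labels best hits and flags split genes", {
  ref <- reference_proteome()
  mcp <- as.character(ref[["MCP"]])
  # intact gene
  orfs <- data.frame(start = 1, end = 3 * (nchar(mcp) + 1), strand = "+",
                     frame = 0, peptide = mcp, fragmented = FALSE)
  ann <- annotate_orfs(orfs, ref)
  expect_equal(ann$label, "MCP")
  expect_equal(ann$ref_cov, 1)
  expect_false(ann$fragmented)

  # the same gene split by an introduced stop into two adjacent ORFs
  half <- nchar(mcp) %/% 2
  split_orfs <- data.frame(
    start = c(1, half * 3 + 10), end = c(half * 3 + 3, nchar(mcp) * 3 + 9),
    strand = "+", frame = 0,
    peptide = c(substring(mcp, 1, half), substring(mcp, half + 1)),
    fragmented = FALSE)
  ann2 <- annotate_orfs(split_orfs, ref)
  expect_true(all(ann2$label == "MCP"))
  expect_true(all(ann2$fragmented))

  # unrelated peptide stays unlabeled
  set.seed(51)
  junk <- data.frame(start = 1, end = 303, strand = "+", frame = 0,
                     peptide = random_peptide(100), fragmented = FALSE)
  expect_true(is.na(annotate_orfs(junk, ref)$label))
})

test_that("cumulative-bitscore typing recovers templates and ties break low", {
  tpl <- element_templates()
  # an 8 kb slice of a template is assigned its own type with margin
  slice <- substring(tpl[[4]]$seq, 2001, 10000)
  ta <- assign_type_by_cumulative_bitscore(slice)
  expect_equal(ta$assigned, 4L)
  expect_gt(ta$margin, 0)
  expect_false(ta$tie)

  # every full template self-assigns with margin above 100 bits
  for (t in c(1, 5, 8)) {
    ta_t <- assign_type_by_cumulative_bitscore(tpl[[t]]$seq)
    expect_equal(ta_t$assigned, t)
    expect_gt(ta_t$margin, 100)
  }

  # scores below 100 are inconclusive
  set.seed(53)
  ta0 <- assign_type_by_cumulative_bitscore(random_dna(2000, 0.5))
  expect_equal(ta0$label, "inconclusive")
  expect_true(is.na(ta0$assigned))

  # an exact inter-type tie resolves to the lower type id and is flagged
  db <- type_species_db()
  dup_db <- list(db[[3]], db[[3]])
  ta_tie <- assign_type_by_cumulative_bitscore(substring(tpl[[3]]$seq, 1, 6000),
                                               dup_db)
  expect_equal(ta_tie$assigned, 1L)
  expect_true(ta_tie$tie)
})
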
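# Nucleotide contribution accounting, codon usage, gene lengths.

test_that("assembly fractions are exact bookkeeping", {
  asm <- Biostrings::DNAStringSet(c(c1 = strrep("A", 100000)))
  ann <- data.frame(contig = "c1", start = 1001, end = 3000, class = "element")
  fr <- assembly_fractions(asm, ann)
  expect_equal(fr$fraction[fr$class == "element"], 0.02)
  expect_equal(sum(fr$fraction), 1)

  # nested retrotransposon bases count as ngaro, not element
  ann2 <- rbind(ann, data.frame(contig = "c1", start = 1501, end = 2000,
                                class = "ngaro"))
  fr2 <- assembly_fractions(asm, ann2)
  expect_equal(fr2$bases[fr2$class == "element"], 1500)
  expect_equal(fr2$bases[fr2$class == "ngaro"], 500)

  # no annotations -> all host
  fr0 <- assembly_fractions(asm, ann[0, ])
  expect_equal(fr0$fraction[fr0$class == "host"], 1)

  expect_error(assembly_fractions(asm, data.frame(contig = "c1", start = 99999,
                                                  end = 101000, class = "element")),
               "bounds")
})

test_that("fractions sum to one across random annotation sets", {
  set.seed(121)
  asm <- Biostrings::DNAStringSet(c(c1 = strrep("A", 50000), c2 = strrep("C", 30000)))
  for (k in 1:20) {
    n <- sample(1:6, 1)
    ctg <- sample(c("c1", "c2"), n, TRUE)
    st <- vapply(ctg, function(cc) sample.int(ifelse(cc == "c1", 45000, 25000), 1), 1)
    ann <- data.frame(contig = ctg, start = st, end = st + sample(100:2000, n, TRUE),
                      class = sample(c("element", "ngaro"), n, TRUE))
    fr <- assembly_fractions(asm, ann)
    expect_equal(sum(fr$fraction), 1)
    expect_equal(sum(fr$bases), 80000)
  }
})

test_that("read attribution is CIGAR-aware and class-correct", {
  asm <- Biostrings::DNAStringSet(c(c1 = strrep("A", 10000)))
  ann <- data.frame(contig = "c1", start = 1001, end = 2000, class = "element")
  sam <- tempfile(fileext = ".sam")
  writeLines(c(
    "@HD\tVN:1.6\tSO:unsorted",
    "@SQ\tSN:c1\tLN:10000",
    # fully host
    sprintf("r1\t0\tc1\t3001\t60\t100M\t*\t0\t0\t%s\t*", strrep("A", 100)),
    # spans the element boundary: 50 host + 50 element
    sprintf("r2\t0\tc1\t951\t60\t100M\t*\t0\t0\t%s\t*", strrep("A", 100)),
    # insertion inside the element region: 10M 5I 10M -> 20 ref-consuming
    sprintf("r3\t0\tc1\t1101\t60\t10M5I10M\t*\t0\t0\t%s\t*", strrep("A", 25)),
    # deletion: 10M 5D 10M -> D bases not counted
    sprintf("r4\t0\tc1\t1201\t60\t10M5D10M\t*\t0\t0\t%s\t*", strrep("A", 20)),
    # secondary alignment must be skipped
    sprintf("r5\t256\tc1\t1\t60\t100M\t*\t0\t0\t%s\t*", strrep("A", 100))
  ), sam)
  fr <- read_fractions(sam, asm, ann)
  # element bases: r2 50 + r3 (20M + 5I) + r4 20 = 95
  expect_equal(fr$bases[fr$class == "element"], 50 + 25 + 20)
  expect_equal(fr$bases[fr$class == "host"], 100 + 50)
  expect_equal(sum(fr$fraction), 1)
})

test_that("balanced-coverage reads reproduce assembly fractions closely", {
  cfg <- small_config(seed = 15,
                      read_params = list(n_reads = 3000L, read_length = 4000L,
                                         sub_rate = 0))
  sim <- simulate_genome(cfg)
  ann <- sim$truth[sim$truth$class %in% c("element", "ngaro"),
                   c("contig", "start", "end", "class")]
  aln <- galignments_from_placements(sim$placements, sim$assembly)
  rep <- fraction_report(sim$assembly, ann, aln)
  expect_true(all(rep$deviation_pp <= 0.3))
})

test_that("codon counting is exact and conserved", {
  el <- list(e1 = list(seq = "ATGAAA", gc = 0.2,
                       orfs = data.frame(start = 1, end = 6, strand = "+")))
  cu <- codon_usage_profile(el)
  expect_equal(unname(cu$codon_counts["e1", "ATG"]), 1)
  expect_equal(unname(cu$codon_counts["e1", "AAA"]), 1)
  expect_equal(sum(cu$codon_counts), 2)

  # conservation: total codons = sum of ORF lengths / 3
  tpl <- element_templates()[[1]]
  el2 <- list(x = list(seq = tpl$seq, gc = tpl$gc,
                       orfs = tpl$orfs[, c("start", "end", "strand")]))
  cu2 <- codon_usage_profile(el2)
  expect_equal(unname(cu2$per_element$n_codons),
               sum((tpl$orfs$end - tpl$orfs$start + 1) / 3))
  # order invariance
  el3 <- list(x = list(seq = tpl$seq, gc = tpl$gc,
                       orfs = tpl$orfs[rev(seq_len(nrow(tpl$orfs))),
                                       c("start", "end", "strand")]))
  expect_identical(cu2$codon_counts, codon_usage_profile(el3)$codon_counts)
})

test_that("GC3 tracks element GC across the template panel", {
  tpl <- element_templates()
  els <- lapply(tpl, function(t) {
    list(seq = t$seq, gc = t$gc, orfs = t$orfs[, c("start", "end", "strand")])
  })
  names(els) <- paste0("t", seq_along(els))
  cu <- codon_usage_profile(els)
  expect_gt(cu$spearman_rho, 0.9)
  expect_equal(nrow(cu$per_element), 8)
})

test_that("gene length comparison localises deliberate truncations", {
  set.seed(127)
  base <- data.frame(
    element_id = rep(sprintf("e%02d", 1:20), each = 3),
    label = rep(c("MCP", "ATPase", "PRO"), 20),
    length_aa = rep(c(450, 250, 200), 20),
    has_ngaro = rep(c(TRUE, FALSE), each = 3, length.out = 60))
  eq <- gene_length_comparison(base)
  expect_true(all(eq$median_with == eq$median_without))
  expect_equal(eq$n_with + eq$n_without, rep(20, 3))

  # truncate MCP only in carrier elements
  hit <- base$label == "MCP" & base$has_ngaro
  base$length_aa[hit] <- 150
  sh <- gene_length_comparison(base)
  expect_lt(sh$median_with[sh$label == "MCP"], sh$median_without[sh$label == "MCP"])
  expect_lt(sh$p_value[sh$label == "MCP"], 0.01)
  expect_equal(sh$median_with[sh$label == "PRO"], sh$median_without[sh$label == "PRO"])

  # a label absent from one stratum reports n = 0 and no test
  solo <- data.frame(element_id = "e1", label = "YR", length_aa = 350,
                     has_ngaro = FALSE)
  res <- gene_length_comparison(solo)
  expect_equal(res$n_with, 0)
  expect_true(is.na(res$p_value))
})
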
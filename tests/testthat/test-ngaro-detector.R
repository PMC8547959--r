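# Retrotransposon detection: GC-rich insertions, split direct repeats,
# typing, ORF1 truncation, and the integration-site bias test.

# element with 0-2 planted retrotransposon copies at given offsets
make_host_element <- function(seed, offsets = integer(0), ngaro_type = 1,
                              truncated = FALSE) {
  set.seed(seed)
  etpl <- element_templates()[[1]]
  ntpl <- ngaro_templates()[[ngaro_type]]
  nseq <- ntpl$seq
  if (truncated) {
    nseq <- paste0(substring(nseq, 1, 300), substring(nseq, 2301, nchar(nseq)))
  }
  elem <- etpl$seq
  for (off in rev(sort(offsets))) {
    elem <- paste0(substring(elem, 1, off), nseq,
                   substring(elem, off + 1, nchar(elem)))
  }
  host <- random_dna(20000, 0.70)
  contig <- paste0(substring(host, 1, 10000), elem,
                   substring(host, 10001, 20000))
  list(assembly = Biostrings::DNAStringSet(c(ctg = contig)),
       element = list(contig = "ctg", start = 10001, end = 10000 + nchar(elem)),
       ngaro_len = nchar(nseq), offsets = sort(offsets))
}

test_that("a planted GC-rich insertion is called with tight boundaries", {
  fx <- make_host_element(101, offsets = 5000)
  iv <- detect_high_gc_insertions(fx$element, fx$assembly)
  expect_equal(nrow(iv), 1)
  truth <- c(fx$element$start + 5000, fx$element$start + 5000 + fx$ngaro_len - 1)
  expect_gte(ro(iv$start, iv$end, truth[1], truth[2]), 0.95)

  # element without insertion yields nothing
  fx0 <- make_host_element(102)
  expect_equal(nrow(detect_high_gc_insertions(fx0$element, fx0$assembly)), 0)
})

test_that("two nearby insertions are resolved separately", {
  fx <- make_host_element(103, offsets = c(3000, 8000))
  iv <- detect_high_gc_insertions(fx$element, fx$assembly)
  expect_equal(nrow(iv), 2)
})

test_that("split direct repeats are located exactly on a constructed case", {
  set.seed(105)
  A <- random_dna(300, 0.6); B <- random_dna(250, 0.6)
  mid <- random_dna(5000, 0.6)
  cand <- paste0(A, mid, B, A, B)
  st <- detect_split_direct_repeats(cand)
  expect_false(st$solo)
  expect_equal(st$A1, c(1, 300))
  expect_equal(st$B1, c(5301, 5550))
  expect_equal(st$A2, c(5551, 5850))
  expect_equal(st$B2, c(5851, 6100))
  expect_equal(st$identity_A, 1)

  # repeat-free sequence -> NULL
  expect_null(detect_split_direct_repeats(random_dna(4000, 0.6)))
  expect_error(detect_split_direct_repeats("ACGT"), "500")
})

test_that("a solo AB pair is recognised against reference arms", {
  set.seed(107)
  A <- random_dna(300, 0.6); B <- random_dna(250, 0.6)
  host <- random_dna(3000, 0.7)
  cand <- paste0(substring(host, 1, 1500), A, B, substring(host, 1501, 3000))
  st <- detect_split_direct_repeats(cand, repeat_db = list(A = A, B = B))
  expect_true(st$solo)
  expect_equal(st$A, c(1501, 1800))
  expect_equal(st$B, c(1801, 2050))
})

test_that("typing and ORF1-truncation calling recover planted variants", {
  set.seed(109)
  tpl <- ngaro_templates()
  full <- mutate_dna(tpl[[2]]$seq, 0.02)
  cls <- classify_ngaro(full)
  expect_equal(cls$type_id, 2L)
  expect_equal(cls$variant, "full")

  trunc <- paste0(substring(tpl[[2]]$seq, 1, 300),
                  substring(tpl[[2]]$seq, 2301, nchar(tpl[[2]]$seq)))
  cls2 <- classify_ngaro(mutate_dna(trunc, 0.02))
  expect_equal(cls2$type_id, 2L)
  expect_equal(cls2$variant, "orf1_truncated")

  cls3 <- classify_ngaro(random_dna(5000, 0.65))
  expect_true(is.na(cls3$type_id))
})

test_that("excision is idempotent and lowers the element GC", {
  fx <- make_host_element(111, offsets = 5000)
  s <- as.character(fx$assembly[[1]])
  iv <- detect_high_gc_insertions(fx$element, fx$assembly)
  rel <- data.frame(start = iv$start - fx$element$start + 1,
                    end = iv$end - fx$element$start + 1)
  el_seq <- substring(s, fx$element$start, fx$element$end)
  once <- excise_intervals(el_seq, rel)$seq
  expect_lt(gc_fraction(once), gc_fraction(el_seq))
  # a second detection pass on the excised element finds nothing to excise
  asm2 <- Biostrings::DNAStringSet(c(ctg = once))
  iv2 <- detect_high_gc_insertions(list(contig = "ctg", start = 1,
                                        end = nchar(once)), asm2)
  expect_equal(nrow(iv2), 0)
})

test_that("the exact Fisher test agrees with enumeration identities", {
  fe <- fisher_exact_2x2(matrix(c(5, 0, 0, 5), 2, byrow = TRUE))
  expect_equal(fe$p, 1 / 126)
  # proportional rows are uninformative
  expect_equal(fisher_exact_2x2(matrix(c(4, 8, 3, 6), 2, byrow = TRUE))$p, 1)
  # invariance under swapping both rows and both columns
  m <- matrix(c(7, 2, 3, 11), 2)
  expect_equal(fisher_exact_2x2(m)$p, fisher_exact_2x2(m[2:1, 2:1])$p)
})

test_that("Fisher p matches stats::fisher.test on random tables", {
  set.seed(113)
  for (k in 1:200) {
    m <- matrix(rpois(4, sample(c(2, 5, 12), 1)), 2)
    expect_lt(abs(fisher_exact_2x2(m)$p - fisher.test(m)$p.value), 1e-12)
  }
})

test_that("integration-site bias statistics are assembled correctly", {
  stats <- integration_bias_test(
    c("intergenic", "intergenic", "genic", "intergenic", "tir"),
    c(intergenic = 1000, genic = 12000, tir = 2000))
  expect_equal(stats$n_insertions, 5)
  expect_equal(stats$intergenic_fraction, 1000 / 15000)
  expect_equal(unname(stats$table["insertions", ]), c(3, 2))
  expect_gt(stats$p, 0); expect_lte(stats$p, 1)
  expect_lt(stats$p_binomial, 0.05)  # 3/5 hits in a 1/15 class
  expect_error(integration_bias_test(character(0), c(intergenic = 1)), "zero")
})
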
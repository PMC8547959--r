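# Element delimitation: TIRs, completeness, TSDs, cross-strain loci.

make_element_contig <- function(seed = 61, tir_len = 900, core_len = 18000,
                                host_len = 30000, tsd = "") {
  set.seed(seed)
  host <- random_dna(host_len, 0.70)
  tir <- random_dna(tir_len, 0.35)
  core <- random_dna(core_len, 0.35)
  elem <- paste0(tir, core, revcomp(tir))
  mid <- host_len %/% 2
  contig <- paste0(substring(host, 1, mid), tsd, elem, tsd,
                   substring(host, mid + 1, host_len))
  list(assembly = Biostrings::DNAStringSet(c(ctg = contig)),
       start = mid + nchar(tsd) + 1, end = mid + nchar(tsd) + nchar(elem),
       tir_len = tir_len)
}

test_that("an exact terminal inverted repeat is delimited precisely", {
  fx <- make_element_contig()
  cand <- data.frame(contig = "ctg", start = fx$start + 150, end = fx$end - 150)
  rec <- delimit_element(cand, fx$assembly)
  expect_equal(rec$start, fx$start)
  expect_equal(rec$end, fx$end)
  expect_equal(rec$tir$length, fx$tir_len)
  expect_equal(rec$tir$identity, 1)
  expect_equal(classify_completeness(rec, nchar(as.character(fx$assembly[[1]]))),
               "complete")
})

test_that("candidates without terminal self-similarity get no TIR", {
  set.seed(63)
  asm <- Biostrings::DNAStringSet(c(ctg = random_dna(30000, 0.5)))
  rec <- delimit_element(data.frame(contig = "ctg", start = 10000, end = 20000), asm)
  expect_null(rec$tir)
})

test_that("completeness requires a TIR pair and host DNA on both sides", {
  fx <- make_element_contig()
  clen <- nchar(as.character(fx$assembly[[1]]))
  rec <- delimit_element(data.frame(contig = "ctg", start = fx$start, end = fx$end),
                         fx$assembly)
  expect_equal(classify_completeness(rec, clen), "complete")
  # element starting at position 1 is partial even with a TIR
  rec1 <- rec; rec1$start <- 1L
  expect_equal(classify_completeness(rec1, clen), "partial")
  # element spanning the whole contig is partial
  rec2 <- rec; rec2$start <- 1L; rec2$end <- clen
  expect_equal(classify_completeness(rec2, clen), "partial")
})

test_that("find_tsd returns the longest exact junction duplication", {
  fx <- make_element_contig(seed = 67, tsd = "ACGTA")
  rec <- list(contig = "ctg", start = fx$start, end = fx$end)
  tsd <- find_tsd(fx$assembly, rec)
  expect_equal(tsd$sequence, "ACGTA")
  expect_equal(tsd$length, 5)
  # re-verifiable by string equality
  s <- as.character(fx$assembly[[1]])
  expect_identical(substring(s, tsd$left_start, tsd$left_end),
                   substring(s, tsd$right_start, tsd$right_end))

  # no duplication at the junction -> NULL (construct junction that differs)
  fx0 <- make_element_contig(seed = 68)
  s0 <- as.character(fx0$assembly[[1]])
  up <- substring(s0, fx0$start - 1, fx0$start - 1)
  down <- setdiff(c("A", "C", "G", "T"), up)[1]
  substring(s0, fx0$end + 1, fx0$end + 1) <- down
  tsd0 <- find_tsd(Biostrings::DNAStringSet(c(ctg = s0)),
                   list(contig = "ctg", start = fx0$start, end = fx0$end))
  expect_true(is.null(tsd0) || tsd0$length < 5)
})

test_that("planted TSDs of lengths 1-9 are recovered exactly", {
  for (seed in c(71, 72, 73)) {
    sim <- simulate_genome(small_config(seed = seed))
    tr <- sim$truth
    tsd <- tr[tr$class == "tsd", ]
    tsd$element <- sub("_tsd[LR]$", "", tsd$feature_id)
    el <- tr[tr$class == "element" & tr$feature_id %in% tsd$element, ]
    for (i in seq_len(nrow(el))) {
      rec <- list(contig = el$contig[i], start = el$start[i], end = el$end[i])
      found <- find_tsd(sim$assembly, rec)
      truth_seq <- tsd$label[tsd$element == el$feature_id[i]][1]
      expect_identical(found$sequence, truth_seq)
    }
  }
})

# A two-strain fixture: one shared insertion, one private to strain A.
make_two_strains <- function(seed = 81) {
  set.seed(seed)
  tpl <- element_templates()[[3]]
  elem <- function() {
    tir <- mutate_dna(substring(tpl$tir, 1, 600), 0.01)
    paste0(tir, mutate_dna(tpl$seq, 0.01), revcomp(tir))
  }
  hostA <- random_dna(80000, 0.70)
  hostB <- paste0(substring(hostA, 1, 60000), random_dna(20000, 0.70))
  shared <- elem(); private <- elem()
  # shared locus at 20000 in both strains; private at 50000 in A only
  splice <- function(host, pos, el) {
    paste0(substring(host, 1, pos), el, substring(host, pos + 1, nchar(host)))
  }
  a <- splice(splice(hostA, 50000, private), 20000, shared)
  b <- splice(hostB, 20000, elem())
  list(A = Biostrings::DNAStringSet(c(cA = a)),
       B = Biostrings::DNAStringSet(c(cB = b)),
       shared = c(20001, 20000 + nchar(shared)),
       private = c(50001 + nchar(shared), 50000 + nchar(shared) + nchar(private)))
}

test_that("cross-strain search separates shared and private insertion loci", {
  fx <- make_two_strains()
  shared_el <- list(contig = "cA", start = fx$shared[1], end = fx$shared[2],
                    type_id = 3L)
  res <- cross_strain_locus_search(shared_el, fx$A, list(B = fx$B), flank = 8000)
  expect_true(res$shared)
  expect_equal(res$occupancy, "occupied")

  priv_el <- list(contig = "cA", start = fx$private[1], end = fx$private[2],
                  type_id = 3L)
  res2 <- cross_strain_locus_search(priv_el, fx$A, list(B = fx$B), flank = 8000)
  expect_false(res2$shared)
  expect_equal(res2$occupancy, "empty")

  # self-search recovers the element's own locus
  res3 <- cross_strain_locus_search(shared_el, fx$A, list(A = fx$A), flank = 8000)
  expect_true(res3$shared)
})
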
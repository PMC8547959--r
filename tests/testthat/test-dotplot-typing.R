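# Word-match dot plots, block similarity, clustering, GC groups.

test_that("self-comparison has an unbroken main diagonal", {
  set.seed(91)
  s <- random_dna(2000, 0.5)
  wm <- wordmatch_dotplot(c(x = s), word = 10)
  m <- wm$matches
  self_fwd <- m[m$q == "x" & m$t == "x" & m$strand == "+", ]
  diag_hits <- self_fwd[self_fwd$qpos == self_fwd$tpos, ]
  expect_equal(nrow(diag_hits), nchar(s) - 10 + 1)
})

test_that("a sequence and its reverse complement share the full antidiagonal", {
  set.seed(92)
  s <- random_dna(1500, 0.5)
  wm <- wordmatch_dotplot(c(a = s, b = revcomp(s)), word = 10)
  m <- wm$matches
  rc <- m[m$q == "a" & m$t == "b" & m$strand == "-", ]
  # reverse-strand matches of an exact RC pair fill the antidiagonal
  # qpos + tpos = n - word + 2 in forward coordinates
  expect_gte(sum(rc$qpos + rc$tpos == nchar(s) - 10 + 2), nchar(s) - 10 + 1)
  expect_error(wordmatch_dotplot(c(a = s), word = 3), "word")
})

test_that("match counts equal exhaustive enumeration and Poisson expectation", {
  set.seed(93)
  a <- random_dna(10000, 0.5)
  b <- random_dna(10000, 0.5)
  wm <- wordmatch_dotplot(c(a = a, b = b), word = 10)
  fwd <- sum(wm$matches$q == "a" & wm$matches$t == "b" & wm$matches$strand == "+")
  expect_identical(fwd, as.integer(word_match_count_oracle(a, b, 10)))
  lambda <- (1e4)^2 / 4^10  # ~95 expected forward matches
  expect_lt(abs(fwd - lambda), 3 * sqrt(lambda))
})

test_that("dot-plot matches are invariant under sequence order permutation", {
  set.seed(94)
  a <- random_dna(3000, 0.45); b <- random_dna(3000, 0.45)
  m1 <- wordmatch_dotplot(c(a = a, b = b))$matches
  m2 <- wordmatch_dotplot(c(b = b, a = a))$matches
  k1 <- m1[m1$q == "a" & m1$t == "b", c("qpos", "tpos", "strand")]
  k2 <- m2[m2$q == "a" & m2$t == "b", c("qpos", "tpos", "strand")]
  k1 <- k1[order(k1$qpos, k1$tpos), ]; rownames(k1) <- NULL
  k2 <- k2[order(k2$qpos, k2$tpos), ]; rownames(k2) <- NULL
  expect_identical(k1, k2)
})

test_that("block similarity is 1 for identical sequences and their RC", {
  tpl <- element_templates()[[2]]$seq
  expect_equal(element_similarity(tpl, tpl), 1)
  expect_equal(element_similarity(tpl, revcomp(tpl)), 1)
})

test_that("single-linkage typing recovers the template partition exactly", {
  tpl <- element_templates()
  set.seed(95)
  seqs <- character(0); truth <- integer(0); gcs <- numeric(0)
  for (t in seq_along(tpl)) {
    for (r in seq_len(ifelse(t %% 2 == 0, 2, 1))) {
      seqs <- c(seqs, mutate_dna(tpl[[t]]$seq, 0.03))
      truth <- c(truth, t)
      gcs <- c(gcs, tpl[[t]]$gc)
    }
  }
  names(seqs) <- sprintf("el%02d", seq_along(seqs))
  cl <- cluster_elements(seqs, gcs)
  expect_equal(emalescan:::adjusted_rand_index(cl$cluster, truth), 1)
  if (requireNamespace("mclust", quietly = TRUE)) {
    expect_equal(emalescan:::adjusted_rand_index(cl$cluster, truth),
                 mclust::adjustedRandIndex(cl$cluster, truth))
  }
  # numbering follows ascending median GC: low-GC clusters come first
  expect_true(all(diff(tapply(gcs, cl$cluster, median)) > 0))
  # the longest member of each cluster is the type species
  for (k in unique(cl$cluster)) {
    members <- which(cl$cluster == k)
    sp <- members[cl$type_species[members]]
    expect_equal(unname(nchar(seqs[sp])), max(nchar(seqs[members])))
  }
  # determinism under rerun
  cl2 <- cluster_elements(seqs, gcs)
  expect_identical(cl$cluster, cl2$cluster)
})

test_that("a single element forms one cluster", {
  cl <- cluster_elements(c(only = element_templates()[[1]]$seq), gc = 0.31)
  expect_equal(nrow(cl), 1)
  expect_equal(cl$cluster, 1L)
  expect_true(cl$type_species)
})

test_that("GC groups split at 43 percent", {
  expect_equal(assign_gc_group(0.353), "low")   # low-GC group median
  expect_equal(assign_gc_group(0.493), "mid")   # mid-GC group median
  expect_equal(assign_gc_group(0.430), "mid")   # boundary goes to mid
})
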
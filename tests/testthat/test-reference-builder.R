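test_that("fragment_sequences produces half-overlapping 400 bp windows", {
  fr <- fragment_sequences(c(g = 400L))
  expect_equal(nrow(fr), 1L)
  expect_equal(c(fr$start, fr$end), c(0L, 400L))

  fr2 <- fragment_sequences(c(g = 1000L), fragment_length = 400, step = 200)
  expect_equal(fr2$start, c(0L, 200L, 400L, 600L))
  expect_equal(fr2$end, c(400L, 600L, 800L, 1000L))
})

test_that("short sequences and tails follow the stated rules", {
  # below min_tail: no fragment, with a warning
  expect_warning(fr <- fragment_sequences(c(g = 150L), min_tail = 200),
                 "skipped")
  expect_equal(nrow(fr), 0L)
  # between min_tail and fragment_length: one whole-sequence fragment
  fr2 <- fragment_sequences(c(g = 250L))
  expect_equal(c(fr2$start, fr2$end), c(0L, 250L))
  # anchored tail fragment fires when >= min_tail bp would stay uncovered
  fr3 <- fragment_sequences(c(g = 1399L), min_tail = 100)
  expect_equal(fr3$start[nrow(fr3)], 1399L - 400L)
  expect_equal(fr3$end[nrow(fr3)], 1399L)
  # ... and stays silent below min_tail
  fr4 <- fragment_sequences(c(g = 1399L))
  expect_equal(fr4$end[nrow(fr4)], 1200L)
  # odd fragment length with default (half) step is undefined
  expect_error(fragment_sequences(c(g = 1000L), fragment_length = 401),
               "even")
})

test_that("fragment enumeration matches a naive independent loop", {
  set.seed(31)
  lens <- sample(1:5000, 200)
  for (L in lens) {
    got <- suppressWarnings(fragment_sequences(c(g = L)))
    want <- oracle_fragments(L)
    expect_equal(nrow(got), nrow(want), info = paste("L =", L))
    if (nrow(want)) {
      expect_equal(got$start, unname(want[, 1]), info = paste("L =", L))
      expect_equal(got$end, unname(want[, 2]), info = paste("L =", L))
    }
  }
})

test_that("half-overlap covers every base at most twice for aligned lengths", {
  set.seed(32)
  for (L in sample(2:25, 10) * 200L) {
    fr <- fragment_sequences(c(g = L))
    cov <- integer(L)
    for (i in seq_len(nrow(fr)))
      cov[(fr$start[i] + 1):fr$end[i]] <- cov[(fr$start[i] + 1):fr$end[i]] + 1L
    if (L >= 400L) {
      expect_true(all(cov >= 1L), info = paste("L =", L))
      expect_true(all(cov <= 2L), info = paste("L =", L))
    }
  }
})

test_that("extract_fragments cuts the right subsequences with coordinate ids", {
  seqs <- Biostrings::DNAStringSet(c(g = paste(rep(c("A", "C", "G", "T"),
                                                   150), collapse = "")))
  fr <- fragment_sequences(seqs)
  out <- extract_fragments(seqs, fr)
  expect_identical(names(out)[1], "g:0-400")
  expect_identical(as.character(out[[1]]),
                   substr(as.character(seqs[[1]]), 1, 400))
})

test_that("filter_min_length keeps strictly longer sequences, order preserved", {
  seqs <- setNames(strrep("A", c(99999, 100000, 100001)),
                   c("a", "b", "c"))
  kept <- filter_min_length(seqs)
  expect_identical(names(kept), "c")
  expect_identical(filter_min_length(character(0)), character(0))
  all_long <- setNames(strrep("A", c(100002, 100003)), c("x", "y"))
  expect_identical(names(filter_min_length(all_long)), c("x", "y"))
})

test_that("profile_from_hits counts per hit, not per read", {
  h <- domain_hit_table(c("r1", "r2", "r3"), c("PF_A", "PF_A", "PF_B"),
                        total_reads = 3)
  p <- profile_from_hits(h)
  expect_equal(unname(p$values[c("PF_A", "PF_B")]), c(2 / 3, 1 / 3))
  expect_identical(p$total_hits, 3L)

  # a read with two hits contributes both
  h2 <- domain_hit_table(c("r1", "r1"), c("PF_A", "PF_B"), total_reads = 1)
  p2 <- profile_from_hits(h2)
  expect_equal(unname(p2$values), c(0.5, 0.5))

  empty <- domain_hit_table(character(), character(), total_reads = 5)
  expect_error(profile_from_hits(empty), "no hits")
})

test_that("fsu is the fraction of reads without any hit", {
  none <- domain_hit_table(character(), character(), total_reads = 10)
  expect_equal(fsu(none), 1.0)
  some <- domain_hit_table(c("r1", "r2", "r3"), rep("PF_A", 3),
                           total_reads = 4)
  expect_equal(fsu(some), 0.25)
  multi <- domain_hit_table(c("r1", "r1", "r2"), rep("PF_A", 3),
                            total_reads = 2)
  expect_equal(fsu(multi), 0.0)
})

test_that("build_signature_matrix aligns per-reference profiles", {
  tax <- toy_taxonomy(c("ref1", "ref2"), c("Bacteria", "Archaea"))
  tables <- list(
    ref1 = domain_hit_table(c("a1", "a2"), c("PF_A", "PF_A"), 2),
    ref2 = domain_hit_table(c("b1", "b2"), c("PF_B", "PF_C"), 2))
  m <- build_signature_matrix(tables, tax)
  expect_identical(rownames(m), c("PF_A", "PF_B", "PF_C"))
  expect_equal(unname(unclass(m)[, "ref1"]), c(1, 0, 0))
  expect_equal(unname(unclass(m)[, "ref2"]), c(0, 0.5, 0.5))

  # single reference: the matrix is its profile
  one <- build_signature_matrix(tables["ref1"], tax)
  expect_equal(ncol(one), 1L)
  expect_equal(unname(unclass(one)[, 1]), 1)
})

test_that("build_signature_matrix skips hitless references and demands taxonomy", {
  tax <- toy_taxonomy(c("ref1", "ref2"), c("Bacteria", "Bacteria"))
  tables <- list(
    ref1 = domain_hit_table(c("a1"), "PF_A", 1),
    ref2 = domain_hit_table(character(), character(), 5))
  expect_warning(m <- build_signature_matrix(tables, tax), "ref2")
  expect_identical(colnames(m), "ref1")
  expect_error(
    build_signature_matrix(list(ghost = tables$ref1), tax), "ghost")
})

test_that("signature matrices built from random hit tables are column-stochastic", {
  set.seed(33)
  for (i in 1:5) {
    K <- sample(2:6, 1)
    ids <- sprintf("ref%d", seq_len(K))
    tables <- setNames(lapply(seq_len(K), function(k) {
      n <- sample(5:50, 1)
      domain_hit_table(sprintf("r%03d", sample(100, n, TRUE)),
                       sprintf("PF%02d", sample(12, n, TRUE)),
                       total_reads = 100)
    }), ids)
    tax <- toy_taxonomy(ids, "Bacteria")
    m <- build_signature_matrix(tables, tax)
    expect_equal(unname(colSums(unclass(m))), rep(1, K), tolerance = 1e-9)
  }
})
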
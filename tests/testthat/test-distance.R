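test_that("edit distance matches classic worked examples", {
  expect_equal(edit_distance(strsplit("kitten", "")[[1]],
                             strsplit("sitting", "")[[1]]), 3)
  x <- c("12", "34", "56")
  expect_equal(edit_distance(x, x), 0)
  expect_equal(edit_distance(c("A", "B", "C"), c("A", "C", "B")), 2)
  expect_equal(edit_distance(character(0), c("A", "B")), 2)
})

test_that("edit distance agrees with the recursive oracle and is a metric", {
  # exhaustive over all distinct-symbol sequences on a 4-letter alphabet
  seqs <- all_distinct_sequences(c("a", "b", "c", "d"))
  for (i in seq_along(seqs)) {
    for (j in i:length(seqs)) {
      d <- edit_distance(seqs[[i]], seqs[[j]])
      expect_identical(d, oracle_levenshtein(seqs[[i]], seqs[[j]]))
      expect_lte(d, max(length(seqs[[i]]), length(seqs[[j]])))
    }
  }
  # random sequences with repeats, lengths up to 6
  set.seed(7)
  ab <- c("a", "b", "c", "d")
  for (case in 1:300) {
    a <- sample(ab, sample(0:6, 1), replace = TRUE)
    b <- sample(ab, sample(0:6, 1), replace = TRUE)
    expect_identical(edit_distance(a, b), oracle_levenshtein(a, b))
  }
  # metric axioms on random triples
  for (case in 1:1000) {
    a <- sample(ab, sample(0:6, 1), replace = TRUE)
    b <- sample(ab, sample(0:6, 1), replace = TRUE)
    cc <- sample(ab, sample(0:6, 1), replace = TRUE)
    dab <- edit_distance(a, b)
    expect_identical(dab, edit_distance(b, a))
    expect_identical(edit_distance(a, a), 0L)
    expect_lte(edit_distance(a, cc), dab + edit_distance(b, cc))
  }
})

test_that("null distributions have the exactly enumerable supports", {
  # a = b of length 1: every null distance 0
  expect_true(all(pair_null_distribution(c("A"), c("A"), 50, seed = 1) == 0))
  # two-symbol swap: support {0, 2} with equal probability
  nulls <- pair_null_distribution(c("A", "B"), c("B", "A"), 4000, seed = 2)
  expect_setequal(unique(nulls), c(0L, 2L))
  expect_equal(mean(nulls == 0), 0.5, tolerance = 0.05)
  # disjoint symbol sets of equal length: all null distances = n
  nulls2 <- pair_null_distribution(c("A", "B", "C"), c("X", "Y", "Z"), 200,
                                   seed = 3)
  expect_true(all(nulls2 == 3))
})

test_that("normalized distances behave at the enumerable extremes", {
  x <- sample(recording_electrodes(mea_layout()), 20)
  # identical patterns are at normalized distance 0
  nd <- normalized_distance(x, x, 200, seed = 4)
  expect_equal(nd$raw, 0L)
  expect_equal(nd$normalized, 0)
  # strict tie counting reproduces the enumerated two-symbol case
  nd2 <- normalized_distance(c("A", "B"), c("B", "A"), 4000, seed = 5,
                             tie_counting = "strict")
  expect_equal(nd2$raw, 2L)
  expect_equal(nd2$normalized, 0.5, tolerance = 0.05)
  # inclusive counting makes the same pair chance-level, not similar
  nd3 <- normalized_distance(c("A", "B"), c("B", "A"), 4000, seed = 5)
  expect_equal(nd3$normalized, 1)
})

test_that("null distributions depend only on lengths and shared-symbol count", {
  set.seed(11)
  rec <- recording_electrodes(mea_layout())
  # two pairs with identical (len, len, shared) keys but different symbols
  a1 <- sample(rec, 20); b1 <- c(sample(a1, 12), sample(setdiff(rec, a1), 8))
  a2 <- sample(rec, 20); b2 <- c(sample(a2, 12), sample(setdiff(rec, a2), 8))
  n1 <- pair_null_distribution(a1, b1, 3000, seed = 6)
  n2 <- pair_null_distribution(a2, b2, 3000, seed = 7)
  expect_gt(suppressWarnings(ks.test(n1, n2)$p.value), 0.001)
})

test_that("distance matrices are symmetric, zero-diagonal and truncated", {
  cfg <- analysis_config(n_shuffles = 60)
  rec <- recording_electrodes(mea_layout())
  x <- sample(rec, 15)
  # identical patterns: all off-diagonal zero
  dm <- distance_matrix(list(p1 = x, p2 = x, p3 = x), cfg, seed = 8)
  expect_equal(unname(dm$D), matrix(0, 3, 3))
  # noise-free patterns from two templates separate cleanly
  set.seed(9)
  t1 <- sample(rec, 30); t2 <- sample(rec, 30)
  pats <- c(replicate(5, t1, simplify = FALSE),
            replicate(5, t2, simplify = FALSE))
  names(pats) <- sprintf("p%02d", 1:10)
  dm2 <- distance_matrix(pats, cfg, seed = 10)
  within <- dm2$D[1:5, 1:5][upper.tri(matrix(0, 5, 5))]
  between <- dm2$D[1:5, 6:10]
  expect_true(all(within == 0))
  expect_true(all(between > cfg$distance_alpha))
  # truncation keeps the earliest patterns
  dm3 <- suppressMessages(
    distance_matrix(pats, cfg, seed = 10, max_patterns = 8))
  expect_equal(dm3$ids, sprintf("p%02d", 1:8))
  expect_error(distance_matrix(pats[1], cfg), "at least 2")
})

test_that("matrix entries are reproducible and order-independent", {
  cfg <- analysis_config(n_shuffles = 60)
  rec <- recording_electrodes(mea_layout())
  set.seed(12)
  pats <- lapply(1:6, function(i) sample(rec, 25))
  names(pats) <- sprintf("p%d", 1:6)
  dm_a <- distance_matrix(pats, cfg, seed = 13)
  dm_b <- distance_matrix(pats, cfg, seed = 13)
  expect_identical(dm_a$D, dm_b$D)
  # cached and per-pair nulls give statistically compatible matrices
  cfg_nc <- analysis_config(n_shuffles = 200, cache_nulls = FALSE)
  cfg_c <- analysis_config(n_shuffles = 200, cache_nulls = TRUE)
  d_nc <- distance_matrix(pats, cfg_nc, seed = 14)$D
  d_c <- distance_matrix(pats, cfg_c, seed = 14)$D
  expect_lt(max(abs(d_nc - d_c)), 0.15)
})

test_that("edit distance agrees with utils::adist on character strings", {
  set.seed(20)
  letters4 <- c("g", "h", "i", "j", "k", "l")
  for (case in 1:200) {
    a <- sample(letters4, sample(0:12, 1), replace = TRUE)
    b <- sample(letters4, sample(0:12, 1), replace = TRUE)
    expect_equal(edit_distance(a, b),
                 as.integer(utils::adist(paste(a, collapse = ""),
                                         paste(b, collapse = ""))[1, 1]))
  }
})
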
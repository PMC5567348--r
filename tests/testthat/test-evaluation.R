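test_that("similar-pair ratios count significant pairs correctly", {
  D <- matrix(c(0, 0.01, 0.5,
                0.01, 0, 0.9,
                0.5, 0.9, 0), 3, 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  expect_equal(similar_pair_ratio(D, c("a", "b", "c")), 1 / 3)
  expect_equal(similar_pair_ratio(D, c("a", "b"), "c"), 0)
  expect_equal(similar_pair_ratio(D, c("a"), c("b")), 1)
  expect_error(similar_pair_ratio(D, "a"), ">= 2")

  # identical patterns: within-ratio 1; shifted groups separate
  cfg <- analysis_config(n_shuffles = 60)
  lay <- mea_layout()
  x <- sample(recording_electrodes(lay), 25)
  tpls <- generate_templates(lay, k = 2, n_members = 30, seed = 60)
  mk <- make_template_patterns(tpls, 8, jitter_sd = 3, seed = 61)
  dm <- distance_matrix(mk$patterns, cfg, seed = 62)
  g1 <- names(mk$patterns)[mk$labels == "T1"]
  g2 <- names(mk$patterns)[mk$labels == "T2"]
  expect_gt(similar_pair_ratio(dm, g1), 0.9)
  expect_lt(similar_pair_ratio(dm, g1, g2), 0.2)
})

test_that("shuffle controls estimate the chance ratio deterministically", {
  cfg <- analysis_config(n_shuffles = 60, shuffle_control_repeats = 10)
  lay <- mea_layout()
  x <- sample(recording_electrodes(lay), 25)
  same <- stats::setNames(replicate(8, x, simplify = FALSE),
                          sprintf("p%d", 1:8))
  obs <- 1.0  # identical patterns are fully similar
  ctrl <- shuffle_control(same, config = cfg, seed = 63)
  expect_length(ctrl$ratios, 10)
  expect_lt(ctrl$q95, obs)
  # seeded rerun is identical
  ctrl2 <- shuffle_control(same, config = cfg, seed = 63)
  expect_identical(ctrl$ratios, ctrl2$ratios)
  # single repeat gives a single value
  cfg1 <- analysis_config(n_shuffles = 60, shuffle_control_repeats = 1)
  expect_length(shuffle_control(same, config = cfg1, seed = 64)$ratios, 1)
})

test_that("spontaneous-evoked similarity classifies by the strict 10% rule", {
  cfg <- analysis_config()
  sc <- data.frame(id = c("s1", "s2", "s3", "s4"),
                   cluster = c("C1", "C1", "C2", "C2"))
  ec <- data.frame(id = c("e1", "e2", "e3", "e4"),
                   cluster = c("x.C1", "x.C1", "y.C1", "y.C1"),
                   stim = c("x", "x", "y", "y"))
  D <- matrix(0.5, 4, 4, dimnames = list(sc$id, ec$id))
  D[c("s1", "s2"), c("e1", "e2")] <- 0.01   # x matches C1 fully
  D["s3", "e3"] <- 0.01                     # y similar on 1/4 pairs = 0.25
  sim <- spont_evoked_similarity(D, sc, ec, cfg)
  x <- sim[sim$stim == "x", ]
  expect_equal(x$max_ratio, 1)
  expect_equal(x$class, "similar")
  expect_equal(x$matched_spont_cluster, "C1")
  y <- sim[sim$stim == "y", ]
  expect_equal(y$max_ratio, 0.25)
  expect_equal(y$class, "similar")
  # exactly at the threshold the class is "different" (strict >)
  D2 <- matrix(0.5, 4, 4, dimnames = list(sc$id, ec$id))
  D2["s1", "e1"] <- 0.01  # 1 of 4 C1-x pairs, wait: ratio 0.25
  D2[] <- 0.5
  sim2 <- spont_evoked_similarity(D2, sc, ec, cfg)
  expect_true(all(sim2$class == "different"))
  expect_true(all(sim2$max_ratio == 0))
})

test_that("reliability correlation recovers exact and null relationships", {
  x <- c(0.1, 0.4, 0.7, 0.9)
  fit <- reliability_correlation(x, x)
  expect_equal(fit$r, 1)
  expect_equal(fit$slope, 1)
  expect_error(reliability_correlation(c(1, 1, 1), c(1, 2, 3)), "variance")
  expect_error(reliability_correlation(1:2, 1:2), "at least 3")
  # independent vectors: |r| small, p rarely below 0.01
  set.seed(65)
  sig <- replicate(40, {
    a <- runif(50); b <- runif(50)
    reliability_correlation(a, b)$p < 0.01
  })
  expect_lte(mean(sig), 0.05)
})

test_that("group tests pick rank-based methods and detect planted shifts", {
  set.seed(66)
  same <- list(a = runif(40), b = runif(40))
  gt <- group_tests(same)
  expect_gt(gt$p, 0.01)
  # strong location shift is detected at 0.001
  hits <- replicate(20, {
    g <- list(a = rnorm(100), b = rnorm(100, 1))
    group_tests(g)$p < 0.001
  })
  expect_gte(mean(hits), 0.95)
  # three groups, one shifted: omnibus significant, correct pair flagged
  g3 <- list(a = rnorm(60), b = rnorm(60), c = rnorm(60, 1.2))
  gt3 <- group_tests(g3)
  expect_equal(gt3$test, "kruskal-wallis")
  expect_lt(gt3$p, 0.001)
  pw <- gt3$pairwise
  expect_lt(min(pw["c", "a"], na.rm = TRUE), 0.01)
  expect_error(group_tests(list(a = 1, b = 1:3)), ">= 2 values")
})

test_that("MDS embeddings reproduce simple geometries", {
  # three equidistant patterns embed as an equilateral triangle
  D <- matrix(0.6, 3, 3); diag(D) <- 0
  rownames(D) <- colnames(D) <- c("a", "b", "c")
  emb <- mds_embedding(D, dims = 2)
  d <- dist(emb$points)
  expect_equal(max(d) / min(d), 1, tolerance = 1e-6)
  # identical patterns coincide
  D0 <- matrix(0, 3, 3, dimnames = dimnames(D))
  emb0 <- mds_embedding(D0, dims = 2)
  expect_equal(max(dist(emb0$points)), 0)
  # two tight groups are visibly separated (silhouette-like margin)
  cfg <- analysis_config(n_shuffles = 60)
  lay <- mea_layout()
  tpls <- generate_templates(lay, k = 2, n_members = 30, seed = 67)
  mk <- make_template_patterns(tpls, 8, jitter_sd = 3, seed = 68)
  dm <- distance_matrix(mk$patterns, cfg, seed = 69)
  emb2 <- mds_embedding(dm, dims = 2)
  pts <- emb2$points
  g1 <- mk$labels == "T1"
  within <- c(dist(pts[g1, ]), dist(pts[!g1, ]))
  between <- as.matrix(dist(pts))[g1, !g1]
  expect_gt(mean(between), 2 * mean(within))
})
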
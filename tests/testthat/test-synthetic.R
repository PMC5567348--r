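test_that("templates have distinct leader pools and the requested structure", {
  lay <- mea_layout()
  tpls <- generate_templates(lay, k = 4, spread = 60, seed = 3)
  expect_length(tpls, 4)
  pools <- lapply(tpls, `[[`, "leader_pool")
  for (i in 1:3) for (j in (i + 1):4) {
    expect_false(setequal(pools[[i]], pools[[j]]))
  }
  for (t in tpls) {
    expect_true(all(t$leader_pool %in% t$electrodes))
    expect_equal(sum(t$leader_probs), 1)
    expect_equal(unname(t$delays[1]), 0)
    expect_true(all(diff(sort(t$delays)) >= 0))
    expect_lte(max(t$delays), 60)
  }
  # single template is fine
  expect_length(generate_templates(lay, k = 1, seed = 1), 1)
  # disjoint-support mode: pairwise overlap at most 20% of members
  dj <- generate_templates(lay, k = 2, disjoint = TRUE, seed = 4)
  ov <- length(intersect(dj[[1]]$electrodes, dj[[2]]$electrodes))
  expect_lte(ov, 0.2 * min(lengths(lapply(dj, `[[`, "electrodes"))))
  expect_error(generate_templates(lay, k = 3, n_members = 100), "exceeds")
})

test_that("spontaneous simulation matches its configured rates", {
  lay <- mea_layout()
  tpls <- generate_templates(lay, k = 2, seed = 5)
  sim <- simulate_spontaneous(tpls, duration_ms = 600e3, nb_rate_per_min = 20,
                              seed = 6)
  n_nb <- length(sim$truth$nbs)
  # renewal expectation: 200 +- sampling error at 20/min over 10 min
  expect_gt(n_nb, 200 - 4 * sqrt(200))
  expect_lt(n_nb, 200 + 4 * sqrt(200))

  # background spike counts match configured base rates within 10%
  base <- unlist(sim$truth$base_rates)
  nb_spike_count <- sum(vapply(sim$truth$nbs, function(n) length(n$order),
                               numeric(1))) * 9  # ~9 spikes/burst on average
  total <- sum(lengths(sim$sts$spikes))
  expected_bg <- sum(base) * 600
  expect_lt(abs((total - nb_spike_count) - expected_bg) / expected_bg, 0.15)

  # pseudo-lognormal base rates: log rates pass a normality check at n = 59
  expect_gt(stats::shapiro.test(log(base))$p.value, 0.01)

  expect_error(simulate_spontaneous(tpls, duration_ms = 4000,
                                    nb_rate_per_min = 10), "too short")
})

test_that("noise-free bursts reproduce their template order exactly", {
  lay <- mea_layout()
  tpls <- generate_templates(lay, k = 2, jitter_sd = 0,
                             participation_prob = 1, n_leaders = 1, seed = 7)
  sim <- simulate_spontaneous(tpls, duration_ms = 120e3, nb_rate_per_min = 10,
                              base_rates = uniform_base_rates(lay, 0),
                              seed = 8)
  by_id <- split(tpls, vapply(tpls, `[[`, character(1), "id"))
  for (nb in sim$truth$nbs) {
    tpl <- by_id[[nb$template]][[1]]
    expect_equal(nb$order, tpl$electrodes)
    expect_equal(nb$leader, tpl$leader_pool[1])
  }
})

test_that("stimulated sessions respect the pulse protocol and response model", {
  lay <- mea_layout()
  tpls <- generate_templates(lay, k = 2, n_leaders = 1, seed = 9)
  # degenerate probability: every pulse responds with the nearest template
  ses <- simulate_stimulated_session(tpls, stim_electrode = tpls[[1]]$leader_pool[1],
                                     n_pulses = 30, response_prob = 1, seed = 10)
  expect_length(ses$log$sessions, 1)
  expect_true(ses$log$sessions[[1]]$conformant)
  resp <- Filter(function(s) s$responded, ses$truth$stimuli)
  expect_length(resp, 30)
  expect_equal(unique(vapply(resp, `[[`, character(1), "template")), "T1")
  for (s in resp) {
    if (length(s$early) > 0) {
      expect_true(all(unlist(s$early) < s$late_onset_ms - s$onset_ms))
    }
  }

  # binomial response count at response_prob 0.6
  ses2 <- simulate_stimulated_session(tpls, stim_electrode = "44",
                                      n_pulses = 100, response_prob = 0.6,
                                      seed = 11)
  n_resp <- sum(vapply(ses2$truth$stimuli, `[[`, logical(1), "responded"))
  expect_gt(n_resp, 60 - 4 * sqrt(100 * 0.6 * 0.4))
  expect_lt(n_resp, 60 + 4 * sqrt(100 * 0.6 * 0.4))

  expect_error(simulate_stimulated_session(tpls, "44", n_pulses = 10,
                                           duration_ms = 1000), "too short")
})

test_that("identical seeds give identical spike sets", {
  lay <- mea_layout()
  tpls <- generate_templates(lay, k = 2, seed = 12)
  a <- simulate_spontaneous(tpls, duration_ms = 60e3, nb_rate_per_min = 10,
                            seed = 13)
  b <- simulate_spontaneous(tpls, duration_ms = 60e3, nb_rate_per_min = 10,
                            seed = 13)
  expect_identical(a$sts$spikes, b$sts$spikes)
  c <- simulate_spontaneous(tpls, duration_ms = 60e3, nb_rate_per_min = 10,
                            seed = 14)
  expect_false(identical(a$sts$spikes, c$sts$spikes))
})

test_that("ground truth round-trips through JSON", {
  lay <- mea_layout()
  tpls <- generate_templates(lay, k = 2, seed = 15)
  sim <- simulate_spontaneous(tpls, duration_ms = 120e3, nb_rate_per_min = 20,
                              seed = 16)
  path <- withr::local_tempfile(fileext = ".json")
  export_ground_truth(sim$truth, path)
  gt <- read_ground_truth(path)
  expect_equal(length(gt$nbs), length(sim$truth$nbs))
  expect_equal(gt$nbs[[1]]$order, sim$truth$nbs[[1]]$order)
  expect_equal(gt$templates[[2]]$delays, sim$truth$templates[[2]]$delays)
  expect_equal(gt$base_rates, sim$truth$base_rates)

  # empty truth still writes a valid file
  empty <- structure(list(templates = list(), nbs = list(), stimuli = list(),
                          base_rates = list()), class = "ground_truth")
  export_ground_truth(empty, path)
  gt2 <- read_ground_truth(path)
  expect_length(gt2$nbs, 0)
})
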
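test_that("PSTH areas are mean in-window spike counts per stimulus", {
  lay <- mea_layout()
  cfg <- analysis_config()
  onsets <- seq(0, by = 5000, length.out = 10)
  # channel 12: exactly 2 spikes in-window on every trial
  # channel 13: silent; channel 14: one spike at 11 ms each trial
  sts <- spike_train_set(
    list("12" = sort(c(onsets + 50, onsets + 260)),
         "14" = onsets + 11),
    duration_ms = 50000, layout = lay)
  ses <- list(electrode = "32", onsets_ms = onsets)
  ps <- compute_psth(sts, ses, cfg)
  expect_equal(unname(ps$area["12"]), 2.0)
  expect_equal(unname(ps$area["13"]), 0)
  expect_length(ps$latencies[["13"]], 0)
  expect_equal(unname(ps$area["14"]), 1.0)
  # the single spike occupies one bin: the one covering (10, 12] ms
  occ <- which(ps$counts["14", ] > 0)
  expect_length(occ, 1)
  expect_equal(ps$bin_centers[occ], 11)
  expect_equal(ps$latencies[["14"]], rep(11, 10))
  # area equals the bin sum by construction
  expect_equal(unname(ps$area), unname(rowSums(ps$counts)))
  expect_error(compute_psth(sts, list(electrode = "32",
                                      onsets_ms = numeric(0)), cfg),
               "zero pulses")
})

test_that("responding-channel selection excludes areas strictly below 1", {
  cfg <- analysis_config()
  ps <- structure(list(stim = "32",
                       area = c(a = 1.0, b = 0.99, c = 3)),
                  class = "psth_set")
  expect_equal(select_responding_channels(ps, cfg), c("a", "c"))
  ps0 <- structure(list(stim = "32", area = c(a = 0, b = 0.2)),
                   class = "psth_set")
  expect_warning(keep <- select_responding_channels(ps0, cfg), "no responding")
  expect_length(keep, 0)
})

test_that("the two PSTH normalizations divide by the correct maxima", {
  df <- data.frame(stim = c("s1", "s2", "s1", "s2"),
                   electrode = c("e1", "e1", "e2", "e2"),
                   area = c(2, 4, 1, 8),
                   latency = c(10, 20, 40, 20))
  out <- normalize_psth_metrics(df)
  # view A: per recording channel across stimulating sites
  expect_equal(out$area_by_channel, c(0.5, 1, 0.125, 1))
  # view B: per stimulating site across channels
  expect_equal(out$area_by_stim, c(1, 0.5, 0.5, 1))
  expect_equal(out$latency_by_channel, c(0.5, 1, 1, 0.5))
  # single channel in a view normalizes to 1
  one <- normalize_psth_metrics(data.frame(stim = "s1", electrode = "e9",
                                           area = 7, latency = 3))
  expect_equal(one$area_by_stim, 1)
  # zero maximum drops the group from the view
  z <- suppressMessages(normalize_psth_metrics(
    data.frame(stim = "s1", electrode = c("e1", "e2"), area = c(0, 0),
               latency = c(NA, NA))))
  expect_true(all(is.na(z$area_by_stim)))
})

test_that("the separation index follows its analytic form", {
  expect_equal(separation_index(8, 18, 0), 1)      # empty valley
  expect_equal(separation_index(4, 9, 6), 0)       # valley at geometric mean
  expect_equal(separation_index(4, 9, 3), 0.5)     # 1 - 3/6
  expect_error(separation_index(0, 9, 1))
})

test_that("early/late separation finds peaks and the inter-peak minimum", {
  cfg <- analysis_config()
  centers <- (seq_len(250) - 0.5) * 2
  profile <- function(x, y) approx(x, y, xout = centers, rule = 2)$y
  ps <- structure(list(stim = "32", bin_centers = centers, bin_ms = 2),
                  class = "psth_set")
  # early peak 8 at 15 ms, late peak 18 at 120 ms, zero valley between
  net <- profile(c(0, 15, 60, 80, 120, 200, 500),
                 c(0, 8, 0, 0, 18, 0, 0))
  sp <- split_early_late(ps, config = cfg, smooth = FALSE, network = net)
  expect_true(sp$accepted)
  expect_equal(sp$x_peak1, 15)
  expect_lte(abs(sp$x_peak2 - 120), 1)
  expect_equal(sp$s, 1)
  expect_gt(sp$x_min, 15)
  expect_lt(sp$x_min, 120)

  # shallow valley (7 between peaks 8 and 9): s < 0.3, split rejected
  net2 <- profile(c(0, 15, 30, 100, 120, 200, 500),
                  c(0, 8, 7, 7, 9, 0, 0))
  sp2 <- split_early_late(ps, config = cfg, smooth = FALSE, network = net2)
  expect_false(sp2$accepted)
  expect_equal(sp2$s, 1 - 7 / sqrt(8 * max(net2)), tolerance = 1e-6)

  # no late peak: rejected with a reason, not an error
  sp3 <- split_early_late(ps, config = cfg, smooth = FALSE,
                          network = profile(c(0, 15, 60, 500), c(0, 8, 0, 0)))
  expect_false(sp3$accepted)
  expect_match(sp3$reason, "peak")
})

test_that("accepted split thresholds recover the planted early/late gap", {
  lay <- mea_layout()
  cfg <- analysis_config()
  tpls <- generate_templates(lay, k = 2, n_leaders = 1, seed = 30)
  ok <- 0
  n_runs <- 8
  for (i in seq_len(n_runs)) {
    ses <- simulate_stimulated_session(
      tpls, stim_electrode = "44", n_pulses = 30, response_prob = 0.9,
      late_onset_range = c(60, 120), base_rates = uniform_base_rates(lay),
      seed = 300 + i)
    ps <- compute_psth(ses$sts, ses$log$sessions[[1]], cfg)
    sp <- split_early_late(ps, config = cfg)
    if (isTRUE(sp$accepted) && sp$x_min > 20 && sp$x_min < 60) ok <- ok + 1
  }
  expect_gte(ok, n_runs - 1)
})

test_that("evoked patterns obey the 20% participation rule and the late window", {
  lay <- mea_layout()
  cfg <- analysis_config()
  tpls <- generate_templates(lay, k = 2, n_leaders = 1, jitter_sd = 0,
                             participation_prob = 1, seed = 31)
  ses <- simulate_stimulated_session(
    tpls, stim_electrode = tpls[[1]]$leader_pool[1], n_pulses = 20,
    response_prob = 1, base_rates = uniform_base_rates(lay, 0),
    early_reliability = 1, seed = 32)
  det <- detect_all_bursts(ses$sts, cfg)
  ps <- compute_psth(ses$sts, ses$log$sessions[[1]], cfg)
  sp <- split_early_late(ps, config = cfg)
  expect_true(sp$accepted)
  active <- recording_electrodes(lay)[1:50]
  pats <- extract_evoked_patterns(ses$sts, ses$log$sessions[[1]], sp,
                                  active, det$thresholds, cfg)
  expect_length(pats, 20)
  for (p in pats[1:3]) {
    expect_true(all(p$delays > sp$x_min))
    expect_lte(max(p$delays), cfg$psth_window_ms)
    # noise-free: activation order equals the template order
    expect_equal(p$order, tpls[[1]]$electrodes)
  }
  # spikes only in the early window yield no pattern
  early_only <- spike_train_set(
    stats::setNames(lapply(1:12, function(i) c(5, 10, 15) + (i - 1) * 0.01),
                    recording_electrodes(lay)[1:12]),
    duration_ms = 5000, layout = lay)
  none <- extract_evoked_patterns(
    early_only, list(electrode = "44", onsets_ms = 0), sp, active,
    NULL, cfg)
  expect_length(none, 0)
})

test_that("response reliability keeps channels at or above 50% of trials", {
  cfg <- analysis_config()
  pats50 <- vector("list", 50)
  expect_true(response_reliability(pats50, 100, cfg)$keep)    # boundary
  expect_equal(response_reliability(pats50, 100, cfg)$fraction, 0.5)
  expect_false(response_reliability(vector("list", 49), 100, cfg)$keep)
})
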
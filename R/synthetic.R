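# Synthetic MEA activity with planted propagation structure. The generator
# emulates the statistics the analysis chain assumes -- a pseudo-lognormal
# firing-rate distribution, network bursts at 5-43 NB/min led by a small
# leader pool, a few recurring propagation templates, and stimulation
# sessions of 100 pulses at 0.2 Hz with early (<~35 ms) and late network
# response components -- and returns full ground truth for every event.

with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(code)
}

#' Generate propagation templates
#'
#' Each template is a recurring spatiotemporal activation motif: an ordered
#' set of electrodes with nominal first-spike delays relative to the leader
#' (delay 0), a small pool of candidate leader electrodes, a per-electrode
#' participation probability and a timing jitter. Leader pools are pairwise
#' distinct across templates, mirroring the association of different
#' propagation patterns with different pools of burst leaders.
#'
#' @param layout An [mea_layout()].
#' @param k Number of templates (1-10).
#' @param spread Largest nominal delay (ms); delays span `[0, spread]`.
#' @param n_members Electrodes per template.
#' @param n_leaders Leaders per pool (1-3 drawn uniformly when length 2).
#' @param participation_prob Probability a member electrode joins a given
#'   burst.
#' @param jitter_sd Gaussian jitter (ms) on non-leader activation delays.
#' @param disjoint If `TRUE`, template electrode supports are drawn from
#'   disjoint partitions of the array (negative-control mode).
#' @param seed Integer seed.
#' @return List of `propagation_template` objects with fields `id`,
#'   `electrodes`, `delays` (named, ms), `leader_pool`, `leader_probs`,
#'   `participation_prob`, `jitter_sd`.
#' @export
generate_templates <- function(layout = mea_layout(), k = 4, spread = 60,
                               n_members = 35, n_leaders = c(1, 3),
                               participation_prob = 0.9, jitter_sd = 2,
                               disjoint = FALSE, seed = 1L) {
  stopifnot(k >= 1, k <= 10)
  rec <- recording_electrodes(layout)
  if (disjoint) n_members <- min(n_members, floor(length(rec) / k))
  if (n_members > length(rec)) {
    stop("n_members exceeds the ", length(rec), " available electrodes")
  }
  with_seed(seed, {
    pool_src <- if (disjoint) split(sample(rec), rep(1:k, length.out = length(rec))) else NULL
    used_leaders <- character(0)
    prev_orders <- list()
    lapply(seq_len(k), function(i) {
      members <- if (disjoint) {
        sort(pool_src[[i]][seq_len(min(n_members, length(pool_src[[i]])))])
      } else sort(sample(rec, n_members))
      nl <- if (length(n_leaders) == 2) sample(n_leaders[1]:n_leaders[2], 1) else n_leaders
      avail <- setdiff(members, used_leaders)
      if (length(avail) < nl) avail <- members
      leaders <- sample(avail, nl)
      used_leaders <<- union(used_leaders, leaders)
      # the leader pool opens the motif with near-zero delays so that the
      # realized order barely depends on which pool member fires first
      others <- setdiff(members, leaders)
      lead_delays <- (seq_len(nl) - 1) * 1.5
      # redraw the propagation order until it is clearly dissimilar from
      # every earlier template (templates must be separable motifs, not
      # chance-similar ones)
      # non-leader delays start well above the jitter scale so the planted
      # leader is also the realized first-firing electrode
      delay_grid <- seq(15, max(spread, 15 + 0.1 * length(others)), by = 0.1)
      for (attempt in 1:100) {
        # distinct delays on the 0.1 ms acquisition grid
        other_delays <- sort(sample(delay_grid, length(others)))
        delays <- c(lead_delays, other_delays)
        names(delays) <- c(leaders, others[sample(length(others))])
        ord <- names(delays)
        sep <- vapply(prev_orders, function(po) {
          ea <- match(ord, union(ord, po))
          eb <- match(po, union(ord, po))
          mean(.lev_null(ea, eb, 200L, TRUE) <= .lev_int(ea, eb))
        }, numeric(1))
        if (all(sep >= 0.5)) break
      }
      prev_orders[[length(prev_orders) + 1]] <<- names(delays)
      probs <- runif(nl, 0.5, 1)
      structure(list(
        id = paste0("T", i),
        electrodes = names(delays),
        delays = delays,
        leader_pool = leaders,
        leader_probs = probs / sum(probs),
        participation_prob = participation_prob,
        jitter_sd = jitter_sd
      ), class = "propagation_template")
    })
  })
}

# One realized network burst from a template. Returns per-electrode burst
# spike times (list) plus the realized activation order.
realize_nb <- function(tpl, leader, t_leader, jitter_sd = tpl$jitter_sd,
                       participation_prob = tpl$participation_prob) {
  members <- tpl$electrodes
  keep <- runif(length(members)) < participation_prob
  keep[members == leader] <- TRUE
  members <- members[keep]
  delays <- tpl$delays[members]
  # the chosen leader starts the burst regardless of its nominal delay
  delays <- delays - delays[leader]
  delays[delays < 0] <- 0
  jit <- rnorm(length(members), 0, jitter_sd)
  jit[members == leader] <- 0
  act <- t_leader + delays + jit
  act[act < t_leader] <- t_leader
  act <- round(act, 1)  # activation lives on the 0.1 ms acquisition grid
  spikes <- lapply(seq_along(members), function(i) {
    n <- sample(3:15, 1)
    # intra-burst ISIs in the 5-20 ms range (~10 ms mean)
    isis <- pmin(5 + rexp(n - 1, rate = 1 / 5), 20)
    act[i] + cumsum(c(0, isis))
  })
  names(spikes) <- members
  ord <- members[order(act, members)]
  list(spikes = spikes, order = ord, activation = sort(act),
       onset = min(act))
}

default_base_rates <- function(layout, mean_rate = 1.5, sdlog = 1.0) {
  rec <- recording_electrodes(layout)
  mu <- log(mean_rate) - sdlog^2 / 2
  r <- rlnorm(length(rec), meanlog = mu, sdlog = sdlog)
  names(r) <- rec
  r
}

merge_spikes <- function(lists, duration_ms, layout) {
  rec <- recording_electrodes(layout)
  out <- lapply(rec, function(el) {
    tt <- unlist(lapply(lists, function(l) l[[el]]), use.names = FALSE)
    tt <- round(tt, 1)                       # 0.1 ms grid (10 kHz)
    tt <- sort(unique(tt[tt >= 0 & tt <= duration_ms]))
    tt
  })
  names(out) <- rec
  out
}

#' Simulate spontaneous MEA activity
#'
#' Network-burst onsets follow a gamma renewal process (shape 2) with a
#' 300 ms refractory floor so consecutive bursts never overlap. Each burst
#' instantiates one template: a leader is drawn from the template's pool,
#' member electrodes emit a short spike burst (3-15 spikes, ~10 ms mean
#' intra-burst ISI) at leader time + nominal delay + Gaussian jitter, and
#' members drop out independently with 1 - participation probability.
#' Background activity is per-electrode Poisson at pseudo-lognormal base
#' rates. Ground truth records every burst's template, leader and realized
#' activation order.
#'
#' @param templates Output of [generate_templates()].
#' @param duration_ms Recording length (ms); must allow at least two mean
#'   inter-burst intervals.
#' @param nb_rate_per_min Network-burst rate (1-60 per minute).
#' @param base_rates Named per-electrode background rates (spikes/s); drawn
#'   pseudo-lognormal (mean `base_rate_mean`) when `NULL`.
#' @param base_rate_mean Mean of the lognormal background-rate distribution.
#' @param layout An [mea_layout()].
#' @param seed Integer seed.
#' @return List with `sts` (a [spike_train_set()]) and `truth` (a
#'   `ground_truth` list: `templates`, `nbs`, `base_rates`).
#' @export
simulate_spontaneous <- function(templates, duration_ms = 600e3,
                                 nb_rate_per_min = 19.3, base_rates = NULL,
                                 base_rate_mean = 1.5,
                                 layout = mea_layout(), seed = 1L) {
  stopifnot(nb_rate_per_min >= 1, nb_rate_per_min <= 60)
  mean_int <- 60e3 / nb_rate_per_min
  if (duration_ms < 2 * mean_int) {
    stop("duration too short for one network burst at ", nb_rate_per_min,
         " NB/min")
  }
  with_seed(seed, {
    if (is.null(base_rates)) {
      base_rates <- default_base_rates(layout, mean_rate = base_rate_mean)
    }
    # renewal onsets: 300 ms refractory floor + gamma(2) tail
    floor_ms <- 300
    scale <- (mean_int - floor_ms) / 2
    onsets <- c()
    t <- 0
    repeat {
      t <- t + floor_ms + rgamma(1, shape = 2, scale = scale)
      if (t > duration_ms - 1500) break
      onsets <- c(onsets, t)
    }
    nb_lists <- list()
    nb_truth <- list()
    for (i in seq_along(onsets)) {
      tpl <- templates[[sample(length(templates), 1)]]
      leader <- sample(tpl$leader_pool, 1, prob = tpl$leader_probs)
      nb <- realize_nb(tpl, leader, onsets[i])
      nb_lists[[i]] <- nb$spikes
      nb_truth[[i]] <- list(onset_ms = nb$onset, template = tpl$id,
                            leader = leader, order = nb$order)
    }
    bg <- lapply(base_rates, function(r) {
      n <- rpois(1, r * duration_ms / 1000)
      runif(n, 0, duration_ms)
    })
    spikes <- merge_spikes(c(nb_lists, list(bg)), duration_ms, layout)
    sts <- spike_train_set(spikes, duration_ms = duration_ms, layout = layout,
                           meta = list(phase = "spontaneous"))
    truth <- structure(list(templates = templates, nbs = nb_truth,
                            stimuli = list(),
                            base_rates = as.list(base_rates)),
                       class = "ground_truth")
    list(sts = sts, truth = truth)
  })
}

#' Simulate a stimulation session
#'
#' Emulates a test stimulus of `n_pulses` voltage pulses at 0.2 Hz (5 s
#' inter-pulse interval). Each pulse responds with probability
#' `response_prob`: responding pulses emit highly reliable early spikes on
#' the early-response channels at latencies ~U(2, 20) ms, followed by a late
#' network burst (onset ~U(40, 150) ms after the pulse) instantiated from
#' the template whose leader pool is geometrically closest to the stimulated
#' electrode. Non-responding pulses leave background activity only.
#'
#' @param templates Output of [generate_templates()].
#' @param stim_electrode Stimulated electrode label.
#' @param n_pulses Number of pulses (>= 1).
#' @param response_prob Per-pulse probability of a network response.
#' @param early_channels Labels receiving the early (directly evoked)
#'   response; defaults to the stimulated electrode's 8-neighbourhood plus
#'   the geometrically nearest template leader.
#' @param early_reliability Per-channel per-pulse probability of an early
#'   spike.
#' @param late_onset_range Range (ms after the pulse) of the late
#'   network-burst onset, drawn uniformly.
#' @param base_rates Named background rates (spikes/s); default lognormal
#'   with mean `base_rate_mean`.
#' @param base_rate_mean Mean background rate (spikes/s).
#' @param duration_ms Session length; defaults to `n_pulses * 5000`.
#' @param layout An [mea_layout()].
#' @param seed Integer seed.
#' @return List with `sts`, `log` (a [stimulation_log()]) and `truth`
#'   (per-pulse records: `onset_ms`, `responded`, `template`,
#'   `late_onset_ms`, `early` latencies).
#' @export
simulate_stimulated_session <- function(templates, stim_electrode,
                                        n_pulses = 100, response_prob = 0.8,
                                        early_channels = NULL,
                                        early_reliability = 0.95,
                                        late_onset_range = c(40, 150),
                                        base_rates = NULL,
                                        base_rate_mean = 0.25,
                                        duration_ms = NULL,
                                        layout = mea_layout(), seed = 1L) {
  stopifnot(n_pulses >= 1)
  assert_labels(stim_electrode, layout, what = "stimulated electrode")
  onsets <- 2500 + (seq_len(n_pulses) - 1) * 5000
  if (is.null(duration_ms)) duration_ms <- n_pulses * 5000
  if (duration_ms < max(onsets) + 600) {
    stop("duration_ms too short for ", n_pulses, " pulses at 0.2 Hz")
  }
  # template whose leader pool is closest to the stimulation site
  lead_dist <- vapply(templates, function(tpl) {
    min(vapply(tpl$leader_pool, function(l) {
      electrode_distance(layout, stim_electrode, l)
    }, numeric(1)))
  }, numeric(1))
  tpl <- templates[[which.min(lead_dist)]]
  with_seed(seed, {
    if (is.null(base_rates)) {
      base_rates <- default_base_rates(layout, mean_rate = base_rate_mean)
    }
    if (is.null(early_channels)) {
      early_channels <- default_early_channels(layout, stim_electrode,
                                               templates)
    }
    pulse_lists <- list()
    pulse_truth <- list()
    for (i in seq_along(onsets)) {
      responded <- runif(1) < response_prob
      rec <- list(onset_ms = onsets[i], responded = responded,
                  template = NA_character_, late_onset_ms = NA_real_,
                  early = list())
      if (responded) {
        early <- list()
        for (ch in early_channels) {
          if (runif(1) < early_reliability) {
            lat <- runif(1, 2, 20)
            early[[ch]] <- lat
          }
        }
        late_on <- onsets[i] + runif(1, late_onset_range[1],
                                     late_onset_range[2])
        leader <- sample(tpl$leader_pool, 1, prob = tpl$leader_probs)
        nb <- realize_nb(tpl, leader, late_on)
        ev <- lapply(early, function(l) onsets[i] + l)
        sp <- nb$spikes
        for (ch in names(ev)) sp[[ch]] <- c(ev[[ch]], sp[[ch]])
        pulse_lists[[length(pulse_lists) + 1]] <- sp
        rec$template <- tpl$id
        rec$late_onset_ms <- late_on
        rec$early <- early
        rec$order <- nb$order
        rec$leader <- leader
      }
      pulse_truth[[i]] <- rec
    }
    bg <- lapply(base_rates, function(r) {
      n <- rpois(1, r * duration_ms / 1000)
      runif(n, 0, duration_ms)
    })
    spikes <- merge_spikes(c(pulse_lists, list(bg)), duration_ms, layout)
    sts <- spike_train_set(spikes, duration_ms = duration_ms, layout = layout,
                           meta = list(phase = "stimulated"))
    log <- stimulation_log(list(list(electrode = stim_electrode,
                                     onsets_ms = onsets)), layout)
    truth <- structure(list(templates = templates, nbs = list(),
                            stimuli = pulse_truth,
                            base_rates = as.list(base_rates)),
                       class = "ground_truth")
    list(sts = sts, log = log, truth = truth)
  })
}

default_early_channels <- function(layout, stim_electrode, templates) {
  d <- vapply(layout$label, function(l) {
    electrode_distance(layout, stim_electrode, l)
  }, numeric(1))
  neigh <- layout$label[d > 0 & d <= sqrt(2) * attr(layout, "pitch_um")]
  leaders <- unique(unlist(lapply(templates, `[[`, "leader_pool")))
  dl <- vapply(leaders, function(l) {
    electrode_distance(layout, stim_electrode, l)
  }, numeric(1))
  sort(unique(c(intersect(neigh, recording_electrodes(layout)),
                leaders[which.min(dl)])))
}

#' Write or read generator ground truth
#'
#' JSON serialization of a `ground_truth` object; write-then-read is
#' lossless up to numeric precision.
#'
#' @param gt A `ground_truth` object.
#' @param path File path.
#' @return `export_ground_truth()` returns `path` invisibly;
#'   `read_ground_truth()` returns the reconstructed object.
#' @export
export_ground_truth <- function(gt, path) {
  ser <- list(
    templates = lapply(gt$templates, function(t) {
      list(id = t$id, electrodes = t$electrodes,
           delays = as.list(t$delays), leader_pool = t$leader_pool,
           leader_probs = t$leader_probs,
           participation_prob = t$participation_prob,
           jitter_sd = t$jitter_sd)
    }),
    nbs = gt$nbs,
    stimuli = gt$stimuli,
    base_rates = gt$base_rates
  )
  jsonlite::write_json(ser, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  invisible(path)
}

#' @rdname export_ground_truth
#' @export
read_ground_truth <- function(path) {
  ser <- jsonlite::read_json(path, simplifyVector = FALSE)
  templates <- lapply(ser$templates, function(t) {
    structure(list(
      id = t$id,
      electrodes = unlist(t$electrodes),
      delays = unlist(t$delays),
      leader_pool = unlist(t$leader_pool),
      leader_probs = unlist(t$leader_probs),
      participation_prob = t$participation_prob,
      jitter_sd = t$jitter_sd
    ), class = "propagation_template")
  })
  nbs <- lapply(ser$nbs, function(n) {
    list(onset_ms = n$onset_ms, template = n$template, leader = n$leader,
         order = unlist(n$order))
  })
  stimuli <- lapply(ser$stimuli, function(s) {
    s$early <- lapply(s$early, function(x) x)
    if (!is.null(s$order)) s$order <- unlist(s$order)
    s
  })
  structure(list(templates = templates, nbs = nbs, stimuli = stimuli,
                 base_rates = ser$base_rates),
            class = "ground_truth")
}
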
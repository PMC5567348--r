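# Independent oracles and shared fixtures for the test suite.

# Plain recursive Levenshtein distance (memoised), kept independent of the
# package's dynamic-programming implementation.
oracle_levenshtein <- function(a, b) {
  memo <- new.env(parent = emptyenv())
  rec <- function(i, j) {
    if (i == 0) return(j)
    if (j == 0) return(i)
    key <- paste(i, j)
    hit <- memo[[key]]
    if (!is.null(hit)) return(hit)
    cost <- if (a[i] == b[j]) 0L else 1L
    v <- min(rec(i - 1, j - 1) + cost, rec(i - 1, j) + 1L, rec(i, j - 1) + 1L)
    memo[[key]] <- v
    v
  }
  as.integer(rec(length(a), length(b)))
}

# Brute-force burst scan: walk the train, cut wherever the gap exceeds the
# threshold, keep runs of at least min_spikes.
oracle_burst_scan <- function(train, threshold, min_spikes = 3) {
  out <- list()
  run <- c()
  for (t in train) {
    if (length(run) == 0 || t - run[length(run)] <= threshold) {
      run <- c(run, t)
    } else {
      if (length(run) >= min_spikes) out[[length(out) + 1]] <- run
      run <- t
    }
  }
  if (length(run) >= min_spikes) out[[length(out) + 1]] <- run
  out
}

# One-to-one greedy matching of detected network bursts to ground truth by
# onset proximity; returns the truth index per detection (NA = unmatched).
match_nbs <- function(detected_onsets, truth_onsets, tol_ms = 100) {
  used <- rep(FALSE, length(truth_onsets))
  idx <- rep(NA_integer_, length(detected_onsets))
  for (i in order(detected_onsets)) {
    d <- abs(truth_onsets - detected_onsets[i])
    d[used] <- Inf
    j <- which.min(d)
    if (length(j) == 1 && d[j] <= tol_ms) {
      idx[i] <- j
      used[j] <- TRUE
    }
  }
  idx
}

# Uniform background rates used by the recovery tests (0.5 spikes/s).
uniform_base_rates <- function(layout = mea_layout(), rate = 0.5) {
  rec <- recording_electrodes(layout)
  stats::setNames(rep(rate, length(rec)), rec)
}

# All sequences of distinct symbols (permutations of subsets) over an
# alphabet, used for exhaustive edit-distance checks.
all_distinct_sequences <- function(alphabet) {
  out <- list(character(0))
  grow <- function(prefix) {
    rest <- setdiff(alphabet, prefix)
    for (s in rest) {
      seq <- c(prefix, s)
      out[[length(out) + 1]] <<- seq
      grow(seq)
    }
  }
  grow(character(0))
  out
}

# Realized activation patterns straight from template definitions (jitter +
# dropout, no spike-level simulation), with their template labels.
make_template_patterns <- function(templates, n_each, jitter_sd = 0,
                                   participation = 1, seed = 1) {
  set.seed(seed)
  pats <- list()
  labels <- c()
  for (t in seq_along(templates)) {
    tpl <- templates[[t]]
    for (i in seq_len(n_each)) {
      keep <- runif(length(tpl$electrodes)) < participation
      keep[1] <- TRUE
      el <- tpl$electrodes[keep]
      d <- tpl$delays[keep] + rnorm(sum(keep), 0, jitter_sd)
      pats[[length(pats) + 1]] <- el[order(d, el)]
      labels <- c(labels, tpl$id)
    }
  }
  names(pats) <- sprintf("p%03d", seq_along(pats))
  list(patterns = pats, labels = labels)
}
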
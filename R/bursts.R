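# Single-channel burst detection (logISI method), network-burst assembly,
# activation patterns and burst-leadership statistics.

#' logISI intra-burst threshold for one channel
#'
#' Computes a histogram of log10 inter-spike intervals (fixed binning, 10
#' bins per decade by default, smoothed by a short moving average) and looks
#' for the valley separating the intra-burst peak (largest peak at ISIs
#' below `logisi_max_intraburst_ms`) from the next peak at longer intervals.
#' The valley qualifies only if its void parameter
#' `1 - h_min / sqrt(h_peak1 * h_peak2)` is at least `void_min`. Returns the
#' ISI (ms) at the deepest qualifying valley, or `NULL` when the histogram
#' is unimodal, has no sub-`logisi_max_intraburst_ms` peak, or no valley is
#' deep enough.
#'
#' @param isis Inter-spike intervals (ms); at least 10 required.
#' @param config An [analysis_config()].
#' @return Threshold in ms, or `NULL`.
#' @export
logisi_threshold <- function(isis, config = analysis_config()) {
  if (length(isis) == 0) stop("empty ISI vector")
  if (length(isis) < 10) return(NULL)
  isis <- isis[isis > 0]
  lx <- log10(isis)
  bw <- 1 / config$logisi_bins_per_decade
  lo <- floor(min(lx) / bw) * bw
  hi <- ceiling(max(lx) / bw) * bw
  if (hi <= lo) hi <- lo + bw
  breaks <- seq(lo, hi, by = bw)
  h <- graphics::hist(lx, breaks = breaks, plot = FALSE)
  counts <- smooth_ma(h$counts, config$logisi_smooth_bins)
  centers <- h$mids
  pk <- local_peaks(counts)
  if (length(pk) < 2) return(NULL)
  intra <- pk[10^centers[pk] < config$logisi_max_intraburst_ms]
  if (length(intra) == 0) return(NULL)
  p1 <- intra[which.max(counts[intra])]
  later <- pk[pk > p1]
  if (length(later) == 0) return(NULL)
  # scan subsequent peaks in increasing ISI; the first valley deep enough
  # (void >= void_min) defines the threshold, keeping it tight to the
  # intra-burst peak
  for (p2 in later) {
    seg <- (p1 + 1):(p2 - 1)
    if (length(seg) == 0) next
    vidx <- seg[which.min(counts[seg])]
    void <- 1 - counts[vidx] / sqrt(counts[p1] * counts[p2])
    if (void >= config$void_min) return(10^centers[vidx])
  }
  NULL
}

# centered moving average with truncated edges; width w bins
smooth_ma <- function(x, w) {
  if (w <= 1) return(x)
  n <- length(x)
  left <- floor((w - 1) / 2)
  right <- w - 1 - left
  vapply(seq_len(n), function(i) {
    mean(x[max(1, i - left):min(n, i + right)])
  }, numeric(1))
}

# indices of local maxima; plateaus report their first index
local_peaks <- function(x, min_height = 0) {
  n <- length(x)
  if (n < 3) return(integer(0))
  out <- integer(0)
  i <- 2
  while (i <= n - 1) {
    if (x[i] > x[i - 1]) {
      j <- i
      while (j < n && x[j + 1] == x[i]) j <- j + 1
      if (j <= n - 1 && x[j + 1] < x[i] && x[i] > min_height) {
        out <- c(out, i)
      }
      i <- j + 1
    } else i <- i + 1
  }
  out
}

#' Detect single-channel bursts
#'
#' A burst is a maximal run of spikes whose consecutive inter-spike
#' intervals are all at most `threshold_ms`, containing at least
#' `min_spikes` spikes.
#'
#' @param train Sorted spike times (ms) of one channel.
#' @param threshold_ms Intra-burst ISI threshold (ms, > 0).
#' @param min_spikes Minimum spikes per burst.
#' @return Data frame with columns `start_ms`, `end_ms`, `n_spikes`, ordered
#'   by start; zero rows when no burst exists.
#' @export
detect_bursts <- function(train, threshold_ms, min_spikes = 3) {
  stopifnot(threshold_ms > 0)
  empty <- data.frame(start_ms = numeric(0), end_ms = numeric(0),
                      n_spikes = integer(0))
  n <- length(train)
  if (n < min_spikes) return(empty)
  gap <- c(Inf, diff(train))
  run_id <- cumsum(gap > threshold_ms)
  runs <- split(train, run_id)
  runs <- runs[lengths(runs) >= min_spikes]
  if (length(runs) == 0) return(empty)
  out <- data.frame(
    start_ms = vapply(runs, min, numeric(1)),
    end_ms = vapply(runs, max, numeric(1)),
    n_spikes = lengths(runs)
  )
  rownames(out) <- NULL
  out[order(out$start_ms), , drop = FALSE]
}

#' Detect bursts on every channel of a recording
#'
#' Applies [logisi_threshold()] channel by channel; channels without a
#' bimodal logISI histogram fall back to `logisi_max_intraburst_ms`.
#'
#' @param sts A [spike_train_set()].
#' @param config An [analysis_config()].
#' @return List with `bursts` (data frame `electrode`, `start_ms`, `end_ms`,
#'   `n_spikes`) and `thresholds` (named vector, ms).
#' @export
detect_all_bursts <- function(sts, config = analysis_config()) {
  electrodes <- names(sts$spikes)
  thresholds <- numeric(0)
  rows <- list()
  for (el in electrodes) {
    train <- sts$spikes[[el]]
    thr <- NULL
    if (length(train) >= 11) {
      thr <- logisi_threshold(diff(train), config)
    }
    if (is.null(thr)) thr <- config$logisi_max_intraburst_ms
    thr <- min(thr, config$logisi_max_intraburst_ms)
    thresholds[el] <- thr
    b <- detect_bursts(train, thr, config$min_spikes_per_burst)
    if (nrow(b) > 0) {
      b$electrode <- el
      rows[[el]] <- b[, c("electrode", "start_ms", "end_ms", "n_spikes")]
    }
  }
  bursts <- if (length(rows) > 0) do.call(rbind, rows) else
    data.frame(electrode = character(0), start_ms = numeric(0),
               end_ms = numeric(0), n_spikes = integer(0))
  rownames(bursts) <- NULL
  bursts <- bursts[order(bursts$start_ms, bursts$electrode), , drop = FALSE]
  list(bursts = bursts, thresholds = thresholds)
}

#' Assemble network bursts from single-channel bursts
#'
#' Single-channel bursts are chained when they overlap in time or are
#' separated by a gap of at most `nb_chain_ms`. A chain qualifies as a
#' network burst when the number of distinct participating channels is at
#' least `ceiling(nb_participation_frac * active_channels)`. Each
#' participant's activation time is the first spike of its earliest burst in
#' the chain; the leader is the first-activated electrode and delays are
#' measured from it. Ties in activation time are broken by lexicographic
#' label order and flagged.
#'
#' @param bursts Data frame as returned by [detect_all_bursts()].
#' @param active_channels Number of active channels (> 0).
#' @param config An [analysis_config()].
#' @return List of `network_burst` objects: `id`, `onset_ms`, `offset_ms`,
#'   `participants`, `leader`, `order`, `delays` (named, ms), `tie`.
#' @export
detect_network_bursts <- function(bursts, active_channels,
                                  config = analysis_config()) {
  stopifnot(active_channels > 0)
  min_chan <- ceiling(config$nb_participation_frac * active_channels)
  if (nrow(bursts) == 0) return(list())
  b <- bursts[order(bursts$start_ms, bursts$electrode), , drop = FALSE]
  chain_end <- b$start_ms[1]
  chain_id <- integer(nrow(b))
  cur <- 1L
  chain_id[1] <- cur
  chain_end <- b$end_ms[1]
  if (nrow(b) > 1) {
    for (i in 2:nrow(b)) {
      if (b$start_ms[i] <= chain_end + config$nb_chain_ms) {
        chain_id[i] <- cur
        chain_end <- max(chain_end, b$end_ms[i])
      } else {
        cur <- cur + 1L
        chain_id[i] <- cur
        chain_end <- b$end_ms[i]
      }
    }
  }
  chains <- split(b, chain_id)
  nbs <- list()
  for (ch in chains) {
    if (length(unique(ch$electrode)) < min_chan) next
    act <- tapply(ch$start_ms, ch$electrode, min)
    act <- act[order(act, names(act))]
    tie <- anyDuplicated(unname(act)) > 0
    leader <- names(act)[1]
    delays <- act - act[1]
    nbs[[length(nbs) + 1]] <- structure(list(
      id = length(nbs) + 1L,
      onset_ms = min(ch$start_ms),
      offset_ms = max(ch$end_ms),
      participants = names(act),
      leader = leader,
      order = names(act),
      delays = delays,
      tie = tie
    ), class = "network_burst")
  }
  nbs
}

#' Activation pattern of a network burst
#'
#' The ordered string of electrode symbols: participants sorted by
#' first-spike delay from the leader, ties broken by label order (flagged
#' with a message).
#'
#' @param nb A `network_burst`.
#' @return Character vector of distinct electrode labels.
#' @export
extract_activation_pattern <- function(nb) {
  if (isTRUE(nb$tie)) {
    message("tie in activation delays of network burst ", nb$id,
            "; broken by label order")
  }
  nb$order
}

#' Burst-leadership table
#'
#' For each electrode, counts the network bursts it led. The leadership
#' score LS is that count as a percentage of all network bursts; electrodes
#' with LS at or above `100 * ml_leadership_frac` (default 4%, inclusive)
#' are flagged as major leaders.
#'
#' @param nbs List of `network_burst` objects (non-empty).
#' @param electrodes Electrode labels to tabulate (default: all leaders
#'   observed).
#' @param config An [analysis_config()].
#' @return Data frame `electrode`, `n_led`, `ls` (percent),
#'   `is_major_leader`, sorted by decreasing LS.
#' @export
leadership_scores <- function(nbs, electrodes = NULL,
                              config = analysis_config()) {
  if (length(nbs) == 0) stop("no network bursts; cannot compute leadership")
  leaders <- vapply(nbs, `[[`, character(1), "leader")
  if (is.null(electrodes)) electrodes <- sort(unique(leaders))
  n_led <- vapply(electrodes, function(e) sum(leaders == e), numeric(1))
  ls <- 100 * n_led / length(nbs)
  out <- data.frame(electrode = electrodes, n_led = as.integer(n_led),
                    ls = ls,
                    is_major_leader = ls >= 100 * config$ml_leadership_frac)
  rownames(out) <- NULL
  out[order(-out$ls, out$electrode), , drop = FALSE]
}

#' Per-channel activity statistics and the active set
#'
#' Firing rate, fraction of spikes falling inside detected bursts, and mean
#' burst duration per electrode. A channel is active when its firing rate
#' strictly exceeds `active_rate_min` (default 0.1 spikes/s).
#'
#' @param sts A [spike_train_set()] with positive duration.
#' @param bursts Data frame from [detect_all_bursts()].
#' @param config An [analysis_config()].
#' @return List with `stats` (data frame `electrode`, `rate`,
#'   `in_burst_frac`, `mean_burst_ms`, `active`) and `active` (labels).
#' @export
channel_activity_stats <- function(sts, bursts, config = analysis_config()) {
  stopifnot(sts$duration_ms > 0)
  dur_s <- sts$duration_ms / 1000
  rows <- lapply(names(sts$spikes), function(el) {
    train <- sts$spikes[[el]]
    eb <- bursts[bursts$electrode == el, , drop = FALSE]
    inb <- 0L
    if (nrow(eb) > 0 && length(train) > 0) {
      for (k in seq_len(nrow(eb))) {
        inb <- inb + sum(train >= eb$start_ms[k] & train <= eb$end_ms[k])
      }
    }
    data.frame(
      electrode = el,
      rate = length(train) / dur_s,
      in_burst_frac = if (length(train) > 0) inb / length(train) else NA_real_,
      mean_burst_ms = if (nrow(eb) > 0) mean(eb$end_ms - eb$start_ms)
                      else NA_real_
    )
  })
  stats <- do.call(rbind, rows)
  stats$active <- stats$rate > config$active_rate_min
  rownames(stats) <- NULL
  list(stats = stats, active = stats$electrode[stats$active])
}
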
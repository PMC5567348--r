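# Post-stimulus time histograms, responding-channel selection, the two
# normalizations, early/late response separation, and evoked-pattern
# extraction.

#' Compute post-stimulus time histograms for one stimulation session
#'
#' For every recording electrode, spike counts in bins of `psth_bin_ms`
#' over a `psth_window_ms` window after each pulse, averaged over trials.
#' The PSTH area (sum of mean bin counts) equals the mean number of
#' in-window spikes per stimulus. Per-trial first-spike latencies are kept.
#'
#' @param sts A [spike_train_set()] from the stimulation phase.
#' @param session One session of a [stimulation_log()] (fields `electrode`,
#'   `onsets_ms`, non-empty).
#' @param config An [analysis_config()].
#' @return A `psth_set`: `stim`, `n_trials`, `bin_ms`, `window_ms`,
#'   `bin_centers` (ms), `counts` (electrodes x bins matrix of mean counts),
#'   `area` (named), `latencies` (list of per-trial first-spike latencies).
#' @export
compute_psth <- function(sts, session, config = analysis_config()) {
  onsets <- session$onsets_ms
  if (length(onsets) == 0) stop("session has zero pulses")
  win <- config$psth_window_ms
  bin <- config$psth_bin_ms
  nbin <- win / bin
  electrodes <- union(names(sts$spikes), recording_electrodes(sts$layout))
  counts <- matrix(0, nrow = length(electrodes), ncol = nbin,
                   dimnames = list(electrodes, NULL))
  latencies <- vector("list", length(electrodes))
  names(latencies) <- electrodes
  for (el in electrodes) {
    train <- sts$spikes[[el]] %||% numeric(0)
    lat <- numeric(0)
    for (on in onsets) {
      rel <- train[train > on & train <= on + win] - on
      if (length(rel) > 0) {
        idx <- pmin(ceiling(rel / bin), nbin)
        tab <- tabulate(idx, nbins = nbin)
        counts[el, ] <- counts[el, ] + tab
        lat <- c(lat, min(rel))
      }
    }
    latencies[[el]] <- lat
  }
  counts <- counts / length(onsets)
  structure(list(
    stim = session$electrode,
    n_trials = length(onsets),
    bin_ms = bin,
    window_ms = win,
    bin_centers = (seq_len(nbin) - 0.5) * bin,
    counts = counts,
    area = rowSums(counts),
    latencies = latencies
  ), class = "psth_set")
}

#' Responding channels of a PSTH set
#'
#' Channels whose PSTH area is strictly lower than `psth_area_min` (default
#' 1 spike per stimulus on average) are excluded; the boundary value is
#' retained.
#'
#' @param psths A `psth_set` from [compute_psth()].
#' @param config An [analysis_config()].
#' @return Character vector of responding-electrode labels (may be empty,
#'   with a warning).
#' @export
select_responding_channels <- function(psths, config = analysis_config()) {
  keep <- names(psths$area)[psths$area >= config$psth_area_min]
  if (length(keep) == 0) warning("no responding channels for stimulation of ",
                                 psths$stim)
  keep
}

#' Normalize PSTH areas and first-spike latencies
#'
#' Two complementary views of the same measurements:
#' view A divides each recording channel's values across stimulating sites
#' by that channel's maximum (used to compare stimulation from leaders vs
#' followers); view B divides, for each stimulating site, every channel's
#' value by the site maximum (used to compare responses of leaders vs
#' followers). The identical procedure is applied to first-spike latency
#' summaries.
#'
#' @param df Data frame with columns `stim`, `electrode`, `area`, `latency`
#'   (one row per stimulating site x responding channel; `latency` is a
#'   per-channel summary, e.g. the median first-spike latency, `NA`
#'   allowed).
#' @return `df` with columns `area_by_channel`, `area_by_stim`,
#'   `latency_by_channel`, `latency_by_stim` appended; rows whose group
#'   maximum is 0 get `NA` (logged).
#' @export
normalize_psth_metrics <- function(df) {
  stopifnot(all(c("stim", "electrode", "area") %in% names(df)))
  if (!"latency" %in% names(df)) df$latency <- NA_real_
  norm_by <- function(vals, group) {
    out <- rep(NA_real_, length(vals))
    for (g in unique(group)) {
      i <- which(group == g)
      m <- suppressWarnings(max(vals[i], na.rm = TRUE))
      if (!is.finite(m) || m == 0) {
        if (any(!is.na(vals[i]))) {
          message("group '", g, "' has zero maximum; values dropped from view")
        }
        next
      }
      out[i] <- vals[i] / m
    }
    out
  }
  df$area_by_channel <- norm_by(df$area, df$electrode)
  df$area_by_stim <- norm_by(df$area, df$stim)
  df$latency_by_channel <- norm_by(df$latency, df$electrode)
  df$latency_by_stim <- norm_by(df$latency, df$stim)
  df
}

#' Separation index between early and late response peaks
#'
#' `s = 1 - h_min / sqrt(h_peak1 * h_peak2)`: 1 when the inter-peak minimum
#' reaches zero (perfect separation), 0 when it equals the geometric mean of
#' the two peak heights (no separation).
#'
#' @param peak1,peak2 Heights of the early and late peaks (> 0).
#' @param valley Height of the lowest local minimum between them.
#' @return The separation index (dimensionless).
#' @export
separation_index <- function(peak1, peak2, valley) {
  stopifnot(peak1 > 0, peak2 > 0, valley >= 0)
  1 - valley / sqrt(peak1 * peak2)
}

#' Split the network response into early and late components
#'
#' Sums the PSTHs of all responding channels into a network PSTH, smooths it
#' with a `smooth_bin_ms` moving average (centered, truncated at the edges),
#' and detects local maxima (minimum height `peak_prominence_frac` of the
#' global maximum; the highest peak in each window is used). The split
#' requires one peak at or below `early_peak_max_ms` and one later peak
#' within the window; the lowest local minimum between them is the candidate
#' early/late threshold `x_min`, accepted when the separation index is at
#' least `separation_threshold`. On acceptance `x_min` applies to all
#' responding channels of this stimulating electrode.
#'
#' @param psths A `psth_set` from [compute_psth()].
#' @param responding Responding-channel labels (default recomputed).
#' @param config An [analysis_config()].
#' @param smooth Set `FALSE` when `psths` already holds a smoothed network
#'   PSTH (used for analytic checks).
#' @param network Optionally, a precomputed network PSTH vector (values per
#'   bin) bypassing the per-channel sum.
#' @return An `early_late_split`: `stim`, `x_peak1`, `x_peak2`, `x_min`
#'   (ms), `s`, `accepted`, `network` (smoothed values), `bin_centers`; or
#'   an object with `accepted = FALSE` and `reason` when peaks are missing.
#' @export
split_early_late <- function(psths, responding = NULL,
                             config = analysis_config(), smooth = TRUE,
                             network = NULL) {
  if (is.null(network)) {
    if (is.null(responding)) responding <- select_responding_channels(psths, config)
    if (length(responding) == 0) {
      return(rejected_split(psths$stim, "no responding channels"))
    }
    network <- colSums(psths$counts[responding, , drop = FALSE])
  }
  centers <- psths$bin_centers
  sm <- if (smooth) smooth_ma(network, round(config$smooth_bin_ms / psths$bin_ms))
        else network
  pk <- local_peaks(sm, min_height = config$peak_prominence_frac * max(sm))
  early <- pk[centers[pk] <= config$early_peak_max_ms]
  late <- pk[centers[pk] > config$early_peak_max_ms]
  if (length(early) == 0 || length(late) == 0) {
    return(rejected_split(psths$stim, "missing early or late peak",
                          network = sm, centers = centers))
  }
  p1 <- early[which.max(sm[early])]
  p2 <- late[which.max(sm[late])]
  seg <- (p1 + 1):(p2 - 1)
  if (length(seg) == 0) {
    return(rejected_split(psths$stim, "adjacent peaks", network = sm,
                          centers = centers))
  }
  vidx <- seg[which.min(sm[seg])]
  s <- separation_index(sm[p1], sm[p2], sm[vidx])
  structure(list(
    stim = psths$stim,
    x_peak1 = centers[p1],
    x_peak2 = centers[p2],
    x_min = centers[vidx],
    s = s,
    accepted = s >= config$separation_threshold,
    network = sm,
    bin_centers = centers
  ), class = "early_late_split")
}

rejected_split <- function(stim, reason, network = NULL, centers = NULL) {
  structure(list(stim = stim, x_peak1 = NA_real_, x_peak2 = NA_real_,
                 x_min = NA_real_, s = NA_real_, accepted = FALSE,
                 reason = reason, network = network, bin_centers = centers),
            class = "early_late_split")
}

#' Extract evoked network-burst patterns
#'
#' For each stimulation trial, applies single-channel burst detection to the
#' spikes falling in the late window `(x_min, psth_window_ms]` after the
#' pulse. A trial yields an evoked pattern when bursts occur on at least
#' `ceiling(nb_participation_frac * n_active)` active channels; activation
#' delays are measured from the stimulus onset.
#'
#' @param sts Stimulation-phase [spike_train_set()].
#' @param session Session of a [stimulation_log()].
#' @param split Accepted [split_early_late()] result.
#' @param active Active-channel labels (from the recording under analysis).
#' @param thresholds Named per-channel intra-burst thresholds (ms); missing
#'   channels fall back to `logisi_max_intraburst_ms`.
#' @param config An [analysis_config()].
#' @return List of `evoked_pattern` objects: `stim`, `trial`, `order`,
#'   `delays` (named, ms from stimulus onset), `leader`.
#' @export
extract_evoked_patterns <- function(sts, session, split, active,
                                    thresholds = NULL,
                                    config = analysis_config()) {
  if (!isTRUE(split$accepted)) {
    stop("early/late split not accepted for electrode ", session$electrode)
  }
  win <- config$psth_window_ms
  min_chan <- ceiling(config$nb_participation_frac * length(active))
  out <- list()
  for (tr in seq_along(session$onsets_ms)) {
    on <- session$onsets_ms[tr]
    act <- c()
    for (el in names(sts$spikes)) {
      rel <- sts$spikes[[el]]
      rel <- rel[rel > on + split$x_min & rel <= on + win] - on
      if (length(rel) < config$min_spikes_per_burst) next
      thr <- thresholds[el] %||% config$logisi_max_intraburst_ms
      if (is.na(thr)) thr <- config$logisi_max_intraburst_ms
      b <- detect_bursts(rel, min(thr, config$logisi_max_intraburst_ms),
                         config$min_spikes_per_burst)
      if (nrow(b) > 0) act[el] <- b$start_ms[1]
    }
    if (length(act) < min_chan) next
    act <- act[order(act, names(act))]
    out[[length(out) + 1]] <- structure(list(
      stim = session$electrode,
      trial = tr,
      order = names(act),
      delays = act,
      leader = names(act)[1]
    ), class = "evoked_pattern")
  }
  out
}

#' Response reliability of a stimulated channel
#'
#' @param patterns Evoked patterns of one session
#'   ([extract_evoked_patterns()]).
#' @param n_pulses Number of pulses delivered (>= 1).
#' @param config An [analysis_config()].
#' @return List `fraction` (patterns per pulse) and `keep` (`TRUE` when the
#'   fraction is at least `min_response_frac`, boundary inclusive).
#' @export
response_reliability <- function(patterns, n_pulses,
                                 config = analysis_config()) {
  stopifnot(n_pulses >= 1)
  frac <- length(patterns) / n_pulses
  list(fraction = frac, keep = frac >= config$min_response_frac)
}
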
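#' Analysis configuration
#'
#' Collects every tunable threshold of the pipeline in one validated object.
#' Defaults follow the standard values used for cortical cultures on 60-
#' electrode MEAs; each parameter is documented with its unit.
#'
#' @param active_rate_min Minimum firing rate (spikes/s, strict `>`) for a
#'   channel to count as active.
#' @param nb_participation_frac Fraction of active channels that must
#'   participate (with a burst) for a chain of single-channel bursts to be a
#'   network burst. The count threshold is `ceiling(frac * n_active)`.
#' @param ml_leadership_frac Leadership-score fraction at or above which an
#'   electrode is a major leader (inclusive boundary).
#' @param psth_window_ms,psth_bin_ms Post-stimulus histogram window and bin
#'   (ms); the window must be a multiple of the bin.
#' @param psth_area_min Minimum PSTH area (mean spikes per stimulus in the
#'   window) for a channel to count as responding; channels with area
#'   strictly below this are excluded.
#' @param smooth_bin_ms Moving-average span (ms) applied to the network PSTH
#'   before peak detection.
#' @param early_peak_max_ms Latest allowed position (ms) of the early-response
#'   peak.
#' @param separation_threshold Minimum separation index between early and
#'   late peaks for the split to be accepted.
#' @param n_shuffles Permutations per pair for the null distribution of edit
#'   distances.
#' @param distance_alpha Significance level on normalized distances.
#' @param max_spont_nbs Maximum number of spontaneous network bursts entering
#'   the distance matrix (earliest kept).
#' @param min_response_frac Minimum fraction of stimulation trials that must
#'   evoke a network burst for a stimulated channel to be retained
#'   (inclusive boundary).
#' @param similarity_frac_threshold Ratio of significantly similar
#'   spontaneous-evoked pairs above which (strict `>`) a stimulated channel
#'   is classed as evoking a spontaneous-like pattern.
#' @param rng_seed Master seed; every stochastic stage derives a named
#'   sub-stream from it.
#' @param logisi_bins_per_decade,logisi_smooth_bins Binning (bins per decade
#'   of log10 ISI) and moving-average span (bins) of the logISI histogram.
#' @param logisi_max_intraburst_ms Upper ISI bound (ms) for the intra-burst
#'   peak of the logISI histogram; also the fallback intra-burst threshold
#'   when a channel's histogram is not bimodal.
#' @param void_min Minimum void parameter (valley depth) for a logISI valley
#'   to define a threshold.
#' @param min_spikes_per_burst Minimum spikes per single-channel burst.
#' @param nb_chain_ms Maximum gap (ms) between single-channel bursts chained
#'   into one network burst.
#' @param peak_prominence_frac Minimum network-PSTH peak height as a fraction
#'   of the global maximum.
#' @param shuffle_both If `TRUE` both sequences of a pair are permuted each
#'   null iteration; otherwise only the second.
#' @param tie_counting How null distances equal to the observed distance
#'   enter the permutation p-value: `"inclusive"` (they count; a valid,
#'   slightly conservative test) or `"strict"` (only strictly lower nulls
#'   count; ties then favor similarity and chance pairs are flagged above
#'   the nominal rate).
#' @param cache_nulls Cache null distributions keyed by (length a, length b,
#'   shared symbols); exact per-pair reproduction when `FALSE`.
#' @param min_core_size Minimum members for a cluster core.
#' @param shuffle_control_repeats Repeats of the pattern-shuffling control.
#' @param cluster_lead_min_frac Minimum fraction of a cluster's bursts an
#'   electrode must lead to count as driving that cluster.
#' @param relative_order If `TRUE`, major-leader recruitment order is
#'   normalized to `[0, 1]`; raw rank otherwise.
#' @return A validated list of class `analysis_config`.
#' @export
analysis_config <- function(active_rate_min = 0.1,
                            nb_participation_frac = 0.20,
                            ml_leadership_frac = 0.04,
                            psth_window_ms = 500,
                            psth_bin_ms = 2,
                            psth_area_min = 1.0,
                            smooth_bin_ms = 20,
                            early_peak_max_ms = 50,
                            separation_threshold = 0.3,
                            n_shuffles = 200,
                            distance_alpha = 0.05,
                            max_spont_nbs = 2500,
                            min_response_frac = 0.50,
                            similarity_frac_threshold = 0.10,
                            rng_seed = 1L,
                            logisi_bins_per_decade = 10,
                            logisi_smooth_bins = 3,
                            logisi_max_intraburst_ms = 100,
                            void_min = 0.7,
                            min_spikes_per_burst = 3,
                            nb_chain_ms = 100,
                            peak_prominence_frac = 0.05,
                            shuffle_both = TRUE,
                            tie_counting = c("inclusive", "strict"),
                            cache_nulls = TRUE,
                            min_core_size = 5,
                            shuffle_control_repeats = 100,
                            cluster_lead_min_frac = 0.10,
                            relative_order = TRUE) {
  cfg <- as.list(environment())
  cfg$tie_counting <- match.arg(tie_counting)
  validate_config(cfg)
  class(cfg) <- "analysis_config"
  cfg
}

validate_config <- function(cfg) {
  fracs <- c("nb_participation_frac", "ml_leadership_frac",
             "distance_alpha", "min_response_frac",
             "similarity_frac_threshold", "peak_prominence_frac",
             "cluster_lead_min_frac")
  for (f in fracs) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1 || v < 0 || v > 1) {
      stop("config field '", f, "' must be a single value in [0, 1]")
    }
  }
  if (cfg$psth_window_ms %% cfg$psth_bin_ms != 0) {
    stop("psth_window_ms must be divisible by psth_bin_ms")
  }
  if (cfg$n_shuffles < 1) stop("n_shuffles must be >= 1")
  if (cfg$min_spikes_per_burst < 2) stop("min_spikes_per_burst must be >= 2")
  invisible(TRUE)
}

#' Read or write an analysis configuration
#'
#' The on-disk form is a YAML mapping mirroring the field names of
#' [analysis_config()]; unknown fields are rejected.
#'
#' @param path File path.
#' @return `read_config()` returns an `analysis_config`;
#'   `write_config()` returns `path` invisibly.
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(analysis_config))
  bad <- setdiff(names(vals), known)
  if (length(bad) > 0) stop("unknown config field(s): ", paste(bad, collapse = ", "))
  do.call(analysis_config, vals)
}

#' @rdname read_config
#' @param config An `analysis_config`.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}
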
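# End-to-end orchestration: network-event detection -> stimulus-response
# analysis -> pattern similarity -> clustering -> evaluation, with
# machine-readable outputs and deterministic seeding.

#' Activation patterns of a network-burst list
#'
#' @param nbs List of `network_burst` objects.
#' @return Named list (`nbNNNN`) of activation-order character vectors.
#' @export
nb_patterns <- function(nbs) {
  pats <- lapply(nbs, `[[`, "order")
  names(pats) <- vapply(nbs, function(n) sprintf("nb%04d", n$id), character(1))
  pats
}

#' Activation patterns of an evoked-pattern list
#'
#' @param patterns List of `evoked_pattern` objects.
#' @return Named list (`<stim>_tNNN`) of activation-order vectors.
#' @export
evoked_pattern_list <- function(patterns) {
  pats <- lapply(patterns, `[[`, "order")
  names(pats) <- vapply(patterns, function(p) {
    sprintf("%s_t%03d", p$stim, p$trial)
  }, character(1))
  pats
}

#' Run the full analysis pipeline
#'
#' Executes, in order: spontaneous network-event detection and leadership;
#' spontaneous pattern distances and clustering; per-session PSTH analysis,
#' early/late separation and evoked-pattern extraction; evoked clustering;
#' spontaneous-evoked cross-similarity with shuffle control; the
#' reliability correlation; major-leader involvement metrics; and an MDS
#' embedding. Every stochastic step draws a named sub-stream of
#' `config$rng_seed`, so reruns with the same inputs are bit-identical.
#' When `stim`/`stim_log` are `NULL` the evoked stages are marked absent.
#'
#' @param config An [analysis_config()].
#' @param spont Spontaneous-phase [spike_train_set()].
#' @param stim Stimulation-phase [spike_train_set()] (optional).
#' @param stim_log A [stimulation_log()] (optional).
#' @param out_dir Output directory; created if missing. `NULL` disables
#'   file output.
#' @return Invisibly, a list with all stage results (`leadership`, `nbs`,
#'   `spont_dm`, `spont_clusters`, `sessions`, `similarity`,
#'   `reliability_fit`, `ml_involvement`, `mds`, ...).
#' @export
run_pipeline <- function(config, spont, stim = NULL, stim_log = NULL,
                         out_dir = NULL) {
  res <- list(config = unclass(config))
  manifest <- list()
  stage <- function(name, code) {
    log_stage(name, "running")
    out <- tryCatch(force(code), error = function(e) {
      if (!is.null(out_dir)) {
        jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                             auto_unbox = TRUE)
      }
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
    manifest[[name]] <<- "ok"
    out
  }
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }

  ## --- network events (spontaneous) ---
  res$spont <- stage("network_events", {
    det <- detect_all_bursts(spont, config)
    act <- channel_activity_stats(spont, det$bursts, config)
    nbs <- detect_network_bursts(det$bursts, length(act$active), config)
    lead <- if (length(nbs) > 0) {
      leadership_scores(nbs, electrodes = act$active, config = config)
    } else NULL
    list(thresholds = det$thresholds, bursts = det$bursts,
         activity = act$stats, active = act$active, nbs = nbs,
         leadership = lead)
  })

  ## --- spontaneous pattern similarity + clustering ---
  res$spont_patterns <- stage("pattern_similarity", {
    pats <- nb_patterns(res$spont$nbs)
    if (length(pats) < 2) {
      list(patterns = pats, dm = NULL, clusters = NULL)
    } else {
      dm <- distance_matrix(pats, config,
                            seed = substream_seed(config$rng_seed, "spont_dm"))
      cs <- cluster_patterns(dm, config = config)
      list(patterns = pats[dm$ids], dm = dm, clusters = cs)
    }
  })

  ## --- stimulus response ---
  have_stim <- !is.null(stim) && !is.null(stim_log)
  res$sessions <- if (!have_stim) {
    log_stage("stimulus_response", "no stimulation data; evoked stages absent")
    NULL
  } else stage("stimulus_response", {
    det_stim <- detect_all_bursts(stim, config)
    act_stim <- channel_activity_stats(stim, det_stim$bursts, config)
    lapply(stim_log$sessions, function(sess) {
      ps <- compute_psth(stim, sess, config)
      responding <- select_responding_channels(ps, config)
      split <- split_early_late(ps, responding, config)
      pats <- list()
      rel <- list(fraction = 0, keep = FALSE)
      if (isTRUE(split$accepted)) {
        pats <- extract_evoked_patterns(stim, sess, split, act_stim$active,
                                        det_stim$thresholds, config)
        rel <- response_reliability(pats, length(sess$onsets_ms), config)
      }
      list(stim = sess$electrode, psth = ps, responding = responding,
           split = split, patterns = pats, reliability = rel)
    })
  })

  ## --- evoked clustering + cross similarity + evaluation ---
  if (have_stim) {
    res$evoked <- stage("pattern_clustering", {
      kept <- Filter(function(s) isTRUE(s$reliability$keep), res$sessions)
      clusters <- list()
      for (s in kept) {
        pats <- evoked_pattern_list(s$patterns)
        if (length(pats) < 2) next
        dm <- distance_matrix(pats, config,
                              seed = substream_seed(config$rng_seed,
                                                    "evoked_dm", s$stim),
                              max_patterns = Inf)
        cs <- cluster_patterns(dm, config = config)
        cs$assignment$stim <- s$stim
        cs$assignment$cluster <- ifelse(
          cs$assignment$cluster == "unclassified", "unclassified",
          paste0(s$stim, ".", cs$assignment$cluster))
        clusters[[s$stim]] <- list(patterns = pats, dm = dm, clusters = cs)
      }
      clusters
    })

    res$evaluation <- stage("evaluation", {
      sp <- res$spont_patterns
      if (is.null(sp$dm) || length(res$evoked) == 0) {
        list(available = FALSE)
      } else {
        spont_cl <- sp$clusters$assignment
        sp_keep <- spont_cl[spont_cl$cluster != "unclassified", , drop = FALSE]
        ev_assign <- do.call(rbind, lapply(res$evoked, function(e) {
          e$clusters$assignment
        }))
        ev_keep <- ev_assign[ev_assign$cluster != "unclassified", , drop = FALSE]
        ev_pats <- do.call(c, unname(lapply(res$evoked, `[[`, "patterns")))
        if (nrow(sp_keep) == 0 || nrow(ev_keep) == 0) {
          list(available = FALSE)
        } else {
          D_cross <- cross_distance_matrix(
            sp$patterns[sp_keep$id], ev_pats[ev_keep$id], config,
            seed = substream_seed(config$rng_seed, "cross_dm"))
          sim <- spont_evoked_similarity(D_cross, sp_keep, ev_keep, config)
          ctrl <- shuffle_control(sp$patterns[sp_keep$id],
                                  ev_pats[ev_keep$id], config,
                                  seed = substream_seed(config$rng_seed,
                                                        "shuffle_ctrl"))
          # reliability correlation over stimulated channels
          mean_within <- vapply(seq_len(nrow(sim)), function(i) {
            s_ids <- sp_keep$id[sp_keep$cluster == sim$matched_spont_cluster[i]]
            e_ids <- ev_keep$id[ev_keep$cluster == sim$matched_evoked_cluster[i]]
            ws <- if (length(s_ids) >= 2) {
              similar_pair_ratio(sp$dm, s_ids, alpha = config$distance_alpha)
            } else NA_real_
            stim_id <- sim$stim[i]
            e_dm <- res$evoked[[stim_id]]$dm
            we <- if (length(e_ids) >= 2) {
              similar_pair_ratio(e_dm, e_ids, alpha = config$distance_alpha)
            } else NA_real_
            mean(c(ws, we), na.rm = TRUE)
          }, numeric(1))
          fit <- if (nrow(sim) >= 3 && stats::sd(sim$max_ratio) > 0 &&
                     stats::sd(mean_within, na.rm = TRUE) > 0) {
            tryCatch(reliability_correlation(sim$max_ratio, mean_within),
                     error = function(e) NULL)
          } else NULL
          mli <- if (!is.null(res$spont$leadership) &&
                     any(res$spont$leadership$is_major_leader)) {
            psths <- lapply(res$sessions, `[[`, "psth")
            names(psths) <- vapply(res$sessions, `[[`, character(1), "stim")
            splits <- lapply(res$sessions, `[[`, "split")
            names(splits) <- names(psths)
            tryCatch(
              ml_involvement_metrics(
                collect_patterns(res$sessions), psths, splits,
                res$spont$leadership, res$spont$nbs, spont_cl, sim,
                spont$layout, config),
              error = function(e) NULL)
          } else NULL
          emb <- mds_embedding(sp$dm)
          list(available = TRUE, similarity = sim, mean_within = mean_within,
               shuffle_control = ctrl, reliability_fit = fit,
               ml_involvement = mli, mds = emb, D_cross = D_cross)
        }
      }
    })
  }

  if (!is.null(out_dir)) {
    stage("write_outputs", write_pipeline_outputs(res, out_dir))
  }
  invisible(res)
}

collect_patterns <- function(sessions) {
  unlist(lapply(sessions, `[[`, "patterns"), recursive = FALSE)
}

num <- function(x) if (is.null(x)) NULL else unname(x)

write_pipeline_outputs <- function(res, out_dir) {
  j <- function(x, f) jsonlite::write_json(
    x, file.path(out_dir, f), auto_unbox = TRUE, digits = NA, na = "null",
    dataframe = "rows")
  sp <- res$spont
  if (!is.null(sp$leadership)) j(sp$leadership, "leadership.json")
  j(lapply(sp$nbs, function(n) {
    list(id = n$id, onset_ms = n$onset_ms, offset_ms = n$offset_ms,
         leader = n$leader, order = n$order, delays = as.list(n$delays))
  }), "network_bursts.json")
  if (!is.null(res$spont_patterns$dm)) {
    write_distance_matrix(res$spont_patterns$dm,
                          file.path(out_dir, "spont_distance.csv"))
    j(res$spont_patterns$clusters$assignment, "spont_clusters.json")
  }
  if (!is.null(res$sessions)) {
    j(lapply(res$sessions, function(s) {
      list(stim = s$stim, n_responding = length(s$responding),
           split = s$split[c("x_peak1", "x_peak2", "x_min", "s", "accepted")],
           n_patterns = length(s$patterns),
           reliability = s$reliability)
    }), "sessions.json")
    j(lapply(collect_patterns(res$sessions), function(p) {
      list(stim = p$stim, trial = p$trial, order = p$order,
           delays = as.list(p$delays))
    }), "evoked_patterns.json")
  }
  ev <- res$evaluation
  if (!is.null(ev) && isTRUE(ev$available)) {
    j(ev$similarity, "cross_similarity.json")
    j(list(q95 = ev$shuffle_control$q95,
           ratios = ev$shuffle_control$ratios), "shuffle_control.json")
    if (!is.null(ev$reliability_fit)) j(ev$reliability_fit,
                                        "reliability_fit.json")
    if (!is.null(ev$ml_involvement)) j(ev$ml_involvement,
                                       "ml_involvement.json")
    utils::write.csv(data.frame(id = rownames(ev$mds$points),
                                ev$mds$points),
                     file.path(out_dir, "mds.csv"), row.names = FALSE)
  } else {
    j(list(evoked = "absent"), "evoked_status.json")
  }
  jsonlite::write_json(list(stages = "complete"),
                       file.path(out_dir, "manifest.json"), auto_unbox = TRUE)
  invisible(out_dir)
}
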
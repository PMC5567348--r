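# Headline quantifications: similar-pair ratios, shuffle controls,
# spontaneous-vs-evoked similarity classification, the reliability
# correlation, major-leader involvement metrics, nonparametric group tests
# and MDS embedding.

#' Ratio of significantly similar pattern pairs
#'
#' The fraction of pairs whose normalized distance is below `alpha`.
#' Within-group mode (`group_b = NULL`) uses unordered pairs excluding
#' self-pairs; between-group mode uses all cross pairs.
#'
#' @param dm A [distance_matrix()] or a plain matrix of normalized
#'   distances.
#' @param group_a,group_b Pattern ids (non-empty; `group_b` optional).
#' @param alpha Significance level.
#' @return Ratio in `[0, 1]`.
#' @export
similar_pair_ratio <- function(dm, group_a, group_b = NULL, alpha = 0.05) {
  D <- if (inherits(dm, "distance_matrix")) dm$D else dm
  stopifnot(length(group_a) > 0)
  if (is.null(group_b)) {
    if (length(group_a) < 2) stop("within-group ratio needs >= 2 patterns")
    sub <- D[group_a, group_a, drop = FALSE]
    vals <- sub[upper.tri(sub)]
  } else {
    stopifnot(length(group_b) > 0)
    vals <- as.vector(D[group_a, group_b, drop = FALSE])
  }
  if (length(vals) == 0) stop("no valid pairs")
  mean(vals < alpha)
}

#' Chance level of the similar-pair ratio under pattern shuffling
#'
#' Repeatedly permutes the symbol order of every pattern in `patterns_a`,
#' recomputes the similar-pair ratio (within `patterns_a`, or between the
#' shuffled `patterns_a` and intact `patterns_b`), and returns the null
#' distribution with its 95th percentile.
#'
#' @param patterns_a Named list of character vectors.
#' @param patterns_b Optional second set held fixed (cross mode).
#' @param config An [analysis_config()] (`shuffle_control_repeats`,
#'   `n_shuffles`, `distance_alpha`).
#' @param seed Integer seed.
#' @return List `ratios` (length `shuffle_control_repeats`), `q95`.
#' @export
shuffle_control <- function(patterns_a, patterns_b = NULL,
                            config = analysis_config(), seed = NULL) {
  stopifnot(length(patterns_a) >= 2 || !is.null(patterns_b))
  if (is.null(seed)) seed <- substream_seed(config$rng_seed, "shuffle_control")
  n_rep <- config$shuffle_control_repeats
  ratios <- with_seed(seed, {
    vapply(seq_len(n_rep), function(r) {
      shuf <- lapply(patterns_a, function(p) p[sample(length(p))])
      names(shuf) <- names(patterns_a)
      if (is.null(patterns_b)) {
        dm <- distance_matrix(shuf, config,
                              seed = substream_seed(seed, "dm", r),
                              max_patterns = Inf)
        similar_pair_ratio(dm, dm$ids, alpha = config$distance_alpha)
      } else {
        D <- cross_distance_matrix(shuf, patterns_b, config,
                                   seed = substream_seed(seed, "dm", r))
        mean(D < config$distance_alpha)
      }
    }, numeric(1))
  })
  list(ratios = ratios, q95 = unname(stats::quantile(ratios, 0.95)))
}

#' Spontaneous-vs-evoked similarity per stimulated channel
#'
#' For every pair of a spontaneous cluster and an evoked cluster of a given
#' stimulated channel, computes the ratio of significantly similar cross
#' pairs, takes the maximum over spontaneous clusters per channel, and
#' classes the channel as `"similar"` when that maximum strictly exceeds
#' `similarity_frac_threshold` (default 10%), `"different"` otherwise.
#'
#' @param D_cross Matrix of normalized distances, rows = spontaneous pattern
#'   ids, columns = evoked pattern ids (e.g. [cross_distance_matrix()]).
#' @param spont_clusters Data frame `id`, `cluster` for spontaneous patterns
#'   (unclassified rows are ignored).
#' @param evoked_clusters Data frame `id`, `cluster`, `stim` for evoked
#'   patterns (unclassified ignored).
#' @param config An [analysis_config()].
#' @return Data frame per stimulated channel: `stim`, `max_ratio`,
#'   `matched_spont_cluster`, `matched_evoked_cluster`, `class`.
#' @export
spont_evoked_similarity <- function(D_cross, spont_clusters, evoked_clusters,
                                    config = analysis_config()) {
  sc <- spont_clusters[spont_clusters$cluster != "unclassified", , drop = FALSE]
  ec <- evoked_clusters[evoked_clusters$cluster != "unclassified", , drop = FALSE]
  stopifnot(nrow(sc) > 0, nrow(ec) > 0)
  alpha <- config$distance_alpha
  rows <- list()
  for (stim in unique(ec$stim)) {
    e_stim <- ec[ec$stim == stim, , drop = FALSE]
    best <- list(ratio = -Inf, sc = NA_character_, ec = NA_character_)
    for (ecl in unique(e_stim$cluster)) {
      e_ids <- e_stim$id[e_stim$cluster == ecl]
      for (scl in unique(sc$cluster)) {
        s_ids <- sc$id[sc$cluster == scl]
        ratio <- mean(D_cross[s_ids, e_ids, drop = FALSE] < alpha)
        if (ratio > best$ratio) best <- list(ratio = ratio, sc = scl, ec = ecl)
      }
    }
    rows[[stim]] <- data.frame(
      stim = stim, max_ratio = best$ratio,
      matched_spont_cluster = best$sc,
      matched_evoked_cluster = best$ec,
      class = if (best$ratio > config$similarity_frac_threshold) "similar"
              else "different",
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Correlation between cross-similarity and within-cluster reliability
#'
#' Pearson correlation between, per stimulated channel, the maximum
#' spontaneous-evoked similar-pair ratio and the mean of the within-cluster
#' similar-pair ratios of the matched spontaneous and evoked clusters.
#'
#' @param cross_ratio Numeric vector (one value per stimulated channel).
#' @param mean_within Numeric vector of matching length.
#' @return List `r`, `p`, `intercept`, `slope`.
#' @export
reliability_correlation <- function(cross_ratio, mean_within) {
  stopifnot(length(cross_ratio) == length(mean_within))
  if (length(cross_ratio) < 3) stop("need at least 3 stimulated channels")
  if (stats::sd(cross_ratio) == 0 || stats::sd(mean_within) == 0) {
    stop("degenerate variance; correlation undefined")
  }
  ct <- stats::cor.test(mean_within, cross_ratio, method = "pearson")
  fit <- stats::lm(cross_ratio ~ mean_within)
  list(r = unname(ct$estimate), p = ct$p.value,
       intercept = unname(stats::coef(fit)[1]),
       slope = unname(stats::coef(fit)[2]))
}

#' Major-leader involvement in evoked responses
#'
#' For each stimulated channel and each major leader: the relative
#' recruitment order of the leader in the channel's evoked patterns (median
#' over trials of `(rank - 1) / (n - 1)`, 0 = first recruited), the
#' normalized early-response PSTH area (per-stimulating-site normalization
#' restricted to bins at or below the early/late threshold), and the
#' geometric distance between the stimulated electrode and the leader. Each
#' leader is categorized against the channel's matched spontaneous cluster:
#' `"matched"` when it drives that cluster (leads at least
#' `cluster_lead_min_frac` of its bursts), `"unmatched"` when it drives only
#' other clusters, `"no_match"` for channels classed different.
#'
#' @param evoked_patterns List of `evoked_pattern` objects (all channels).
#' @param psths Named list of `psth_set` objects by stimulated electrode.
#' @param splits Named list of accepted `early_late_split` objects.
#' @param leadership [leadership_scores()] table.
#' @param nbs Spontaneous `network_burst` list.
#' @param spont_clusters Data frame `id`, `cluster` aligned with `nbs` ids
#'   (`"nbNNNN"` naming, see [nb_patterns()]).
#' @param similarity [spont_evoked_similarity()] result.
#' @param layout An [mea_layout()].
#' @param config An [analysis_config()].
#' @return Data frame `stim`, `ml`, `relative_order`, `early_area_norm`,
#'   `distance_um`, `category`.
#' @export
ml_involvement_metrics <- function(evoked_patterns, psths, splits,
                                   leadership, nbs, spont_clusters,
                                   similarity, layout = mea_layout(),
                                   config = analysis_config()) {
  mls <- leadership$electrode[leadership$is_major_leader]
  if (length(mls) == 0) stop("no major leaders")
  # which MLs drive each spontaneous cluster
  nb_ids <- vapply(nbs, function(n) sprintf("nb%04d", n$id), character(1))
  nb_leader <- vapply(nbs, `[[`, character(1), "leader")
  cl_of <- spont_clusters$cluster[match(nb_ids, spont_clusters$id)]
  drives <- function(ml, cl) {
    idx <- which(cl_of == cl)
    if (length(idx) == 0) return(FALSE)
    mean(nb_leader[idx] == ml) >= config$cluster_lead_min_frac
  }
  rows <- list()
  for (stim in unique(vapply(evoked_patterns, `[[`, character(1), "stim"))) {
    pats <- Filter(function(p) p$stim == stim, evoked_patterns)
    split <- splits[[stim]]
    sim <- similarity[similarity$stim == stim, , drop = FALSE]
    ps <- psths[[stim]]
    # early-response area: bins at or below x_min, view-B normalized
    early_area <- rep(NA_real_, length(mls))
    names(early_area) <- mls
    if (!is.null(ps) && !is.null(split) && isTRUE(split$accepted)) {
      ebins <- ps$bin_centers <= split$x_min
      ea <- rowSums(ps$counts[, ebins, drop = FALSE])
      responding <- select_responding_channels(ps, config)
      m <- max(ea[responding])
      if (m > 0) early_area[mls] <- ea[mls] / m
    }
    for (ml in mls) {
      ranks <- vapply(pats, function(p) {
        k <- match(ml, p$order)
        n <- length(p$order)
        if (is.na(k)) return(NA_real_)
        if (!config$relative_order) return(as.numeric(k))
        if (n == 1) 0 else (k - 1) / (n - 1)
      }, numeric(1))
      ranks <- ranks[!is.na(ranks)]
      if (length(ranks) == 0) {
        message("major leader ", ml, " absent from all evoked patterns of ",
                stim)
      }
      category <- if (nrow(sim) == 0 || sim$class != "similar") "no_match"
        else if (drives(ml, sim$matched_spont_cluster)) "matched"
        else "unmatched"
      rows[[length(rows) + 1]] <- data.frame(
        stim = stim, ml = ml,
        relative_order = if (length(ranks) > 0) stats::median(ranks)
                         else NA_real_,
        early_area_norm = unname(early_area[ml]),
        distance_um = electrode_distance(layout, stim, ml),
        category = category,
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Nonparametric group comparison
#'
#' Normality of each group is checked (Kolmogorov-Smirnov against a fitted
#' normal, level 0.01); when any group fails, rank-based tests are used:
#' Mann-Whitney for two groups, Kruskal-Wallis with Holm-corrected pairwise
#' rank-sum comparisons for more.
#'
#' @param groups Named list of numeric vectors (>= 2 groups, each >= 2
#'   values).
#' @return List `test` (name), `statistic`, `p`, `normal`, and `pairwise`
#'   (matrix of adjusted p-values, multi-group only).
#' @export
group_tests <- function(groups) {
  stopifnot(length(groups) >= 2)
  if (any(lengths(groups) < 2)) stop("each group needs >= 2 values")
  normal <- all(vapply(groups, function(g) {
    if (stats::sd(g) == 0) return(FALSE)
    suppressWarnings(
      stats::ks.test(g, "pnorm", mean(g), stats::sd(g))$p.value) > 0.01
  }, logical(1)))
  vals <- unlist(groups, use.names = FALSE)
  grp <- factor(rep(names(groups), lengths(groups)))
  if (length(groups) == 2) {
    ht <- if (normal) stats::t.test(groups[[1]], groups[[2]]) else
      suppressWarnings(stats::wilcox.test(groups[[1]], groups[[2]]))
    list(test = if (normal) "t" else "mann-whitney",
         statistic = unname(ht$statistic), p = ht$p.value, normal = normal,
         pairwise = NULL)
  } else {
    ht <- stats::kruskal.test(vals, grp)
    pw <- suppressWarnings(
      stats::pairwise.wilcox.test(vals, grp, p.adjust.method = "holm"))
    list(test = "kruskal-wallis", statistic = unname(ht$statistic),
         p = ht$p.value, normal = normal, pairwise = pw$p.value)
  }
}

#' Classical MDS embedding of a distance matrix
#'
#' @param dm A [distance_matrix()] or plain symmetric matrix.
#' @param dims Embedding dimension.
#' @return List `points` (ids x dims), `stress` (normalized residual
#'   between embedded and original distances).
#' @export
mds_embedding <- function(dm, dims = 2) {
  D <- if (inherits(dm, "distance_matrix")) dm$D else dm
  stopifnot(isSymmetric(unname(D)))
  k <- min(dims, nrow(D) - 1)
  pts <- suppressWarnings(stats::cmdscale(stats::as.dist(D), k = k))
  if (is.null(dim(pts))) pts <- matrix(pts, ncol = 1)
  if (ncol(pts) < dims) {
    pts <- cbind(pts, matrix(0, nrow(pts), dims - ncol(pts)))
  }
  rownames(pts) <- rownames(D)
  emb <- as.matrix(stats::dist(pts))
  denom <- sum(D^2)
  stress <- if (denom > 0) sqrt(sum((emb - D)^2) / denom) else 0
  list(points = pts, stress = stress)
}
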
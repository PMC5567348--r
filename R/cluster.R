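# Two-stage clustering of activation patterns: greedy core extraction on
# the significance graph of the distance matrix, then template matching of
# the remaining patterns; whatever stays unassigned is discarded from all
# downstream ratios.

#' Find cluster cores in a distance matrix
#'
#' Iterative greedy extraction: the pattern with the largest number of
#' significant neighbours (normalized distance < `alpha`) seeds a core made
#' of itself plus those neighbours. Because a fraction `alpha` of unrelated
#' pairs is significant by construction of the normalized distance, the
#' candidate core is then pruned for consistency: members significantly
#' similar to fewer than `core_consistency` of the other members are
#' dropped (repeated until stable, seed kept). A pruned core is retained
#' when it still has at least `min_core_size` members; its members are
#' removed and the search repeats. Ties on neighbour count are broken by
#' pattern order.
#'
#' @param dm A [distance_matrix()].
#' @param alpha Significance level (default `config` value 0.05).
#' @param min_core_size Minimum core size.
#' @param core_consistency Minimum fraction of within-core significant
#'   links a member must keep.
#' @param config An [analysis_config()].
#' @return List with `cores` (list of character id vectors, seed first) and
#'   `leftover` (ids in no core).
#' @export
find_cluster_cores <- function(dm, alpha = NULL, min_core_size = NULL,
                               core_consistency = 0.5,
                               config = analysis_config()) {
  alpha <- alpha %||% config$distance_alpha
  min_core_size <- min_core_size %||% config$min_core_size
  sig <- dm$D < alpha
  diag(sig) <- FALSE
  remaining <- dm$ids
  cores <- list()
  while (length(remaining) >= min_core_size) {
    sub <- sig[remaining, remaining, drop = FALSE]
    deg <- rowSums(sub)
    if (max(deg) + 1 < min_core_size) break
    seed <- remaining[which.max(deg)]
    members <- c(seed, remaining[sub[seed, ]])
    repeat {
      frac <- rowSums(sig[members, members, drop = FALSE]) /
        (length(members) - 1)
      drop <- members != seed & frac < core_consistency
      if (!any(drop)) break
      members <- members[!drop]
      if (length(members) < 2) break
    }
    if (length(members) < min_core_size) {
      # seed neighbourhood too inconsistent to form a core; retire the seed
      remaining <- setdiff(remaining, seed)
      next
    }
    cores[[length(cores) + 1]] <- members
    remaining <- setdiff(remaining, members)
  }
  leftover <- setdiff(dm$ids, unlist(cores))
  list(cores = cores, leftover = leftover)
}

#' Assign leftover patterns to cores by template matching
#'
#' Each pattern outside a core is assigned to the core with the smallest
#' median normalized distance to the core's members, provided that median is
#' below `alpha`; otherwise it remains unclassified (and is discarded from
#' downstream ratios).
#'
#' @param cores Core list from [find_cluster_cores()].
#' @param leftover Ids to assign.
#' @param dm The [distance_matrix()] covering all ids.
#' @param alpha Significance level.
#' @param config An [analysis_config()].
#' @return A `cluster_set`: data frame `assignment` (`id`, `cluster`;
#'   `"unclassified"` where discarded), list `cores`, character `clusters`.
#' @export
assign_by_template_matching <- function(cores, leftover, dm, alpha = NULL,
                                        config = analysis_config()) {
  if (length(cores) == 0) stop("no cores to match against")
  alpha <- alpha %||% config$distance_alpha
  labels <- paste0("C", seq_along(cores))
  assign <- data.frame(id = dm$ids, cluster = "unclassified",
                       stringsAsFactors = FALSE)
  rownames(assign) <- assign$id
  for (k in seq_along(cores)) assign[cores[[k]], "cluster"] <- labels[k]
  for (id in leftover) {
    med <- vapply(cores, function(m) stats::median(dm$D[id, m]), numeric(1))
    k <- which.min(med)
    if (med[k] < alpha) assign[id, "cluster"] <- labels[k]
  }
  structure(list(assignment = assign[, c("id", "cluster")], cores = cores,
                 clusters = labels),
            class = "cluster_set")
}

#' Cluster activation patterns
#'
#' Convenience wrapper chaining [find_cluster_cores()] and
#' [assign_by_template_matching()]. When no core is found every pattern is
#' unclassified.
#'
#' @inheritParams find_cluster_cores
#' @return A `cluster_set`.
#' @export
cluster_patterns <- function(dm, alpha = NULL, min_core_size = NULL,
                             config = analysis_config()) {
  cc <- find_cluster_cores(dm, alpha, min_core_size, config = config)
  if (length(cc$cores) == 0) {
    assign <- data.frame(id = dm$ids, cluster = "unclassified",
                         stringsAsFactors = FALSE)
    return(structure(list(assignment = assign, cores = list(),
                          clusters = character(0)),
                     class = "cluster_set"))
  }
  assign_by_template_matching(cc$cores, cc$leftover, dm, alpha, config)
}

#' Median propagation-delay map of a cluster
#'
#' For each electrode, the median of its activation delays over the cluster
#' members in which it participates, relative to either the leader or (for
#' evoked patterns) the stimulus onset -- whichever reference the supplied
#' delays carry. Electrodes present in fewer than half of the members are
#' flagged low-support.
#'
#' @param members List of `network_burst` or `evoked_pattern` objects
#'   (non-empty); their `delays` fields are pooled.
#' @param min_support_frac Participation fraction below which an electrode
#'   is flagged (default 0.5).
#' @return Data frame `electrode`, `median_delay_ms`, `support`,
#'   `low_support`.
#' @export
cluster_delay_map <- function(members, min_support_frac = 0.5) {
  stopifnot(length(members) >= 1)
  all_delays <- lapply(members, `[[`, "delays")
  electrodes <- sort(unique(unlist(lapply(all_delays, names))))
  n <- length(members)
  rows <- lapply(electrodes, function(el) {
    d <- unlist(lapply(all_delays, function(x) x[el]), use.names = FALSE)
    d <- d[!is.na(d)]
    data.frame(electrode = el,
               median_delay_ms = stats::median(d),
               support = length(d),
               low_support = length(d) < min_support_frac * n)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
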
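# Levenshtein distance between activation orders and its shuffle-based
# normalization to a permutation p-value, plus distance-matrix assembly.

encode_pair <- function(a, b) {
  syms <- unique(c(a, b))
  list(a = match(a, syms), b = match(b, syms),
       shared = length(intersect(a, b)))
}

#' Levenshtein edit distance between two symbol sequences
#'
#' Minimum number of unit-cost insertions, deletions and substitutions
#' transforming one sequence into the other; bounded above by the length of
#' the longer sequence.
#'
#' @param a,b Character vectors of symbols (electrode activation orders).
#' @return Non-negative integer.
#' @examples
#' edit_distance(strsplit("kitten", "")[[1]], strsplit("sitting", "")[[1]]) # 3
#' @export
edit_distance <- function(a, b) {
  e <- encode_pair(a, b)
  .lev_int(e$a, e$b)
}

#' Null distribution of edit distances under symbol-order shuffling
#'
#' Each iteration permutes the sequences uniformly at random (both
#' sequences when `shuffle_both`, otherwise only the second) and records
#' their edit distance, estimating the chance distance distribution for two
#' sequences of the given lengths and symbol overlap.
#'
#' @param a,b Character vectors.
#' @param n_shuffles Number of iterations (>= 1).
#' @param seed Integer seed.
#' @param shuffle_both Permute both sequences per iteration.
#' @return Integer vector of length `n_shuffles`.
#' @export
pair_null_distribution <- function(a, b, n_shuffles = 200, seed = 1L,
                                   shuffle_both = TRUE) {
  stopifnot(n_shuffles >= 1)
  e <- encode_pair(a, b)
  with_seed(seed, .lev_null(e$a, e$b, as.integer(n_shuffles), shuffle_both))
}

#' Shuffle-normalized distance between two activation patterns
#'
#' The normalized distance is the permutation p-value of the observed edit
#' distance against the shuffled-pair null. Low values mean the patterns
#' are more similar than chance; values below the significance level
#' (default 0.05) mark significantly similar pairs. With
#' `tie_counting = "inclusive"` (default) null distances equal to the
#' observed one count towards the p-value, which keeps the test valid
#' (chance pairs are flagged at no more than the nominal rate) despite the
#' strongly discrete edit-distance lattice; `"strict"` counts only strictly
#' lower null distances, in which case ties favor similarity and the
#' chance rate is inflated.
#'
#' @inheritParams pair_null_distribution
#' @param tie_counting `"inclusive"` or `"strict"` (see Details).
#' @return List `raw` (integer edit distance), `normalized` (in `[0, 1]`),
#'   `n_shuffles`.
#' @export
normalized_distance <- function(a, b, n_shuffles = 200, seed = 1L,
                                shuffle_both = TRUE,
                                tie_counting = c("inclusive", "strict")) {
  tie_counting <- match.arg(tie_counting)
  raw <- edit_distance(a, b)
  nulls <- pair_null_distribution(a, b, n_shuffles, seed, shuffle_both)
  list(raw = raw, normalized = null_pvalue(nulls, raw, tie_counting),
       n_shuffles = n_shuffles)
}

null_pvalue <- function(nulls, raw, tie_counting) {
  if (raw == 0) return(0)  # identity: identical patterns are at distance 0
  if (tie_counting == "strict") mean(nulls < raw) else mean(nulls <= raw)
}

#' Distance matrix over a set of activation patterns
#'
#' Fills every unordered pair with the shuffle-normalized distance
#' (diagonal 0). Null distributions depend only on the two sequence lengths
#' and the shared-symbol count, so by default they are cached on that key;
#' per-pair seeds are derived from `seed` so entries do not depend on
#' evaluation order. When more than `max_patterns` patterns are supplied,
#' the first `max_patterns` (input order, i.e. time order) are kept.
#'
#' @param patterns Named list of character vectors (>= 2 after truncation).
#' @param config An [analysis_config()] (uses `n_shuffles`, `shuffle_both`,
#'   `cache_nulls`).
#' @param seed Integer seed (default derived from `config$rng_seed`).
#' @param meta Optional data frame of per-pattern metadata (row per pattern,
#'   matched by name) carried along for grouping.
#' @param max_patterns Truncation limit (default `config$max_spont_nbs`;
#'   use `Inf` for evoked sets).
#' @return A `distance_matrix`: `ids`, `D` (symmetric normalized distances),
#'   `raw` (edit distances), `meta`.
#' @export
distance_matrix <- function(patterns, config = analysis_config(),
                            seed = NULL, meta = NULL,
                            max_patterns = config$max_spont_nbs) {
  if (is.null(names(patterns))) {
    names(patterns) <- sprintf("p%04d", seq_along(patterns))
  }
  if (length(patterns) > max_patterns) {
    message("truncating ", length(patterns), " patterns to the first ",
            max_patterns)
    patterns <- patterns[seq_len(max_patterns)]
    if (!is.null(meta)) meta <- meta[seq_len(max_patterns), , drop = FALSE]
  }
  n <- length(patterns)
  if (n < 2) stop("need at least 2 patterns for a distance matrix")
  if (is.null(seed)) seed <- substream_seed(config$rng_seed, "distance")
  ids <- names(patterns)
  D <- matrix(0, n, n, dimnames = list(ids, ids))
  R <- matrix(0L, n, n, dimnames = list(ids, ids))
  cache <- new.env(parent = emptyenv())
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      e <- encode_pair(patterns[[i]], patterns[[j]])
      raw <- .lev_int(e$a, e$b)
      key <- paste(length(e$a), length(e$b), e$shared, sep = ":")
      if (config$cache_nulls) {
        nulls <- cache[[key]]
        if (is.null(nulls)) {
          nulls <- with_seed(substream_seed(seed, key),
                             .lev_null(e$a, e$b, config$n_shuffles,
                                       config$shuffle_both))
          cache[[key]] <- nulls
        }
      } else {
        nulls <- with_seed(substream_seed(seed, i, j),
                           .lev_null(e$a, e$b, config$n_shuffles,
                                     config$shuffle_both))
      }
      D[i, j] <- D[j, i] <- null_pvalue(nulls, raw, config$tie_counting)
      R[i, j] <- R[j, i] <- raw
    }
  }
  structure(list(ids = ids, D = D, raw = R, meta = meta),
            class = "distance_matrix")
}

#' Cross distance matrix between two pattern sets
#'
#' Same normalization as [distance_matrix()] but over ordered pairs
#' (rows x columns) of two different sets.
#'
#' @param patterns_a,patterns_b Named lists of character vectors.
#' @param config An [analysis_config()].
#' @param seed Integer seed.
#' @return Matrix of normalized distances, rows named by `patterns_a`.
#' @export
cross_distance_matrix <- function(patterns_a, patterns_b,
                                  config = analysis_config(), seed = NULL) {
  if (is.null(seed)) seed <- substream_seed(config$rng_seed, "cross")
  D <- matrix(0, length(patterns_a), length(patterns_b),
              dimnames = list(names(patterns_a), names(patterns_b)))
  cache <- new.env(parent = emptyenv())
  for (i in seq_along(patterns_a)) {
    for (j in seq_along(patterns_b)) {
      e <- encode_pair(patterns_a[[i]], patterns_b[[j]])
      raw <- .lev_int(e$a, e$b)
      key <- paste(length(e$a), length(e$b), e$shared, sep = ":")
      if (config$cache_nulls) {
        nulls <- cache[[key]]
        if (is.null(nulls)) {
          nulls <- with_seed(substream_seed(seed, key),
                             .lev_null(e$a, e$b, config$n_shuffles,
                                       config$shuffle_both))
          cache[[key]] <- nulls
        }
      } else {
        nulls <- with_seed(substream_seed(seed, "ab", i, j),
                           .lev_null(e$a, e$b, config$n_shuffles,
                                     config$shuffle_both))
      }
      D[i, j] <- null_pvalue(nulls, raw, config$tie_counting)
    }
  }
  D
}

#' Write a distance matrix as CSV
#'
#' @param dm A `distance_matrix`.
#' @param path Output path; pattern ids become the header and first column.
#' @export
write_distance_matrix <- function(dm, path) {
  utils::write.csv(as.data.frame(dm$D), path, row.names = TRUE)
  invisible(path)
}
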
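#' Spike-train set
#'
#' The universal input container: per-electrode sorted spike times on a
#' common clock, plus the recording duration. Times are milliseconds from
#' recording start, representable on a 0.1 ms grid (10 kHz sampling).
#'
#' @param spikes Named list mapping electrode label to a numeric vector of
#'   strictly increasing spike times (ms).
#' @param duration_ms Recording length (ms). Defaults to the last spike time.
#' @param layout An [mea_layout()]; all labels must belong to it.
#' @param meta Optional named list (culture id, phase, ...).
#' @return An object of class `spike_train_set`.
#' @export
spike_train_set <- function(spikes, duration_ms = NULL, layout = mea_layout(),
                            meta = list()) {
  stopifnot(is.list(spikes))
  if (length(spikes) > 0 && is.null(names(spikes))) {
    stop("'spikes' must be a named list (electrode label -> times)")
  }
  assert_labels(names(spikes), layout)
  spikes <- lapply(spikes, function(x) sort(unname(as.numeric(x))))
  for (el in names(spikes)) {
    x <- spikes[[el]]
    if (length(x) > 0 && any(x < 0)) {
      stop("negative spike time on electrode ", el)
    }
    if (anyDuplicated(x)) {
      stop("duplicate spike times on electrode ", el)
    }
  }
  last <- suppressWarnings(max(0, unlist(spikes, use.names = FALSE)))
  if (is.null(duration_ms)) duration_ms <- last
  if (last > duration_ms) {
    stop("spike times exceed duration_ms (last spike at ", last, " ms)")
  }
  structure(list(spikes = spikes, duration_ms = as.numeric(duration_ms),
                 layout = layout, meta = meta),
            class = "spike_train_set")
}

#' @export
print.spike_train_set <- function(x, ...) {
  n <- sum(lengths(x$spikes))
  cat(sprintf("<spike_train_set> %d electrodes, %d spikes, %.1f s\n",
              length(x$spikes), n, x$duration_ms / 1000))
  invisible(x)
}

#' Read an event table into a spike-train set
#'
#' The canonical on-disk format is a delimited text table with header
#' `electrode,time_ms`. Rows need not be sorted; duplicate
#' (electrode, time) rows are collapsed with a warning.
#'
#' @param path File path.
#' @param layout An [mea_layout()]; rows naming labels outside it are a hard
#'   error.
#' @param duration_ms Optional recording length; defaults to the last spike.
#' @param meta Optional metadata list.
#' @return A [spike_train_set()] covering every recording electrode of the
#'   layout (empty vectors where no spikes were recorded).
#' @export
read_event_table <- function(path, layout = mea_layout(), duration_ms = NULL,
                             meta = list()) {
  tab <- utils::read.csv(path, colClasses = c("character", "numeric"))
  if (!all(c("electrode", "time_ms") %in% names(tab))) {
    stop("event table must have columns 'electrode' and 'time_ms'")
  }
  event_table_to_sts(tab, layout, duration_ms = duration_ms, meta = meta)
}

event_table_to_sts <- function(tab, layout, duration_ms = NULL, meta = list()) {
  assert_labels(tab$electrode, layout)
  if (any(tab$time_ms < 0)) stop("negative spike time in event table")
  ndup <- nrow(tab) - nrow(unique(tab[c("electrode", "time_ms")]))
  if (ndup > 0) {
    warning(ndup, " duplicate (electrode, time) row(s) collapsed")
    tab <- unique(tab[c("electrode", "time_ms")])
  }
  spikes <- split(tab$time_ms, tab$electrode)
  all_el <- recording_electrodes(layout)
  empty <- setdiff(all_el, names(spikes))
  spikes[empty] <- list(numeric(0))
  spikes <- spikes[sort(names(spikes))]
  if (is.null(duration_ms) && nrow(tab) == 0) duration_ms <- 0
  spike_train_set(spikes, duration_ms = duration_ms, layout = layout,
                  meta = meta)
}

#' Write a spike-train set as an event table
#'
#' @param sts A [spike_train_set()].
#' @param path Output file path (CSV, header `electrode,time_ms`).
#' @return `path`, invisibly.
#' @export
write_event_table <- function(sts, path) {
  el <- rep(names(sts$spikes), lengths(sts$spikes))
  tm <- unlist(sts$spikes, use.names = FALSE)
  tab <- data.frame(electrode = el %||% character(0),
                    time_ms = tm %||% numeric(0))
  tab <- tab[order(tab$electrode, tab$time_ms), , drop = FALSE]
  utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Stimulation log
#'
#' Pulse onset times grouped by stimulated electrode. A session is
#' protocol-conformant when its median inter-pulse interval is within 10% of
#' 5000 ms (100 pulses at 0.2 Hz is the reference protocol).
#'
#' @param sessions List of lists with fields `electrode` (label) and
#'   `onsets_ms` (strictly increasing numeric vector).
#' @param layout An [mea_layout()].
#' @return An object of class `stimulation_log`; each session gains a
#'   logical `conformant` field.
#' @export
stimulation_log <- function(sessions, layout = mea_layout()) {
  sessions <- lapply(sessions, function(s) {
    assert_labels(s$electrode, layout, what = "stimulated electrode")
    on <- sort(as.numeric(s$onsets_ms))
    if (anyDuplicated(on)) stop("duplicate pulse onsets for electrode ",
                                s$electrode)
    conf <- if (length(on) >= 2) {
      abs(stats::median(diff(on)) - 5000) <= 0.10 * 5000
    } else TRUE
    list(electrode = s$electrode, onsets_ms = on, conformant = conf)
  })
  structure(list(sessions = sessions, layout = layout),
            class = "stimulation_log")
}

#' Read or write a stimulation log
#'
#' On disk: a delimited table with header `electrode,onset_ms`. Rows are
#' grouped by electrode into sessions with sorted onsets; sessions whose
#' median inter-pulse interval deviates more than 10% from 5000 ms are
#' flagged non-conformant (with a message).
#'
#' @param path File path.
#' @param layout An [mea_layout()].
#' @return A [stimulation_log()].
#' @export
read_stimulation_log <- function(path, layout = mea_layout()) {
  tab <- utils::read.csv(path, colClasses = c("character", "numeric"))
  if (!all(c("electrode", "onset_ms") %in% names(tab))) {
    stop("stimulation log must have columns 'electrode' and 'onset_ms'")
  }
  assert_labels(tab$electrode, layout, what = "stimulated electrode")
  groups <- split(tab$onset_ms, tab$electrode)
  sessions <- lapply(names(groups), function(el) {
    list(electrode = el, onsets_ms = groups[[el]])
  })
  log <- stimulation_log(sessions, layout)
  for (s in log$sessions) {
    if (!s$conformant) {
      message("session on electrode ", s$electrode,
              " deviates from the 0.2 Hz protocol")
    }
  }
  log
}

#' @rdname read_stimulation_log
#' @param log A [stimulation_log()].
#' @export
write_stimulation_log <- function(log, path) {
  tab <- do.call(rbind, lapply(log$sessions, function(s) {
    data.frame(electrode = s$electrode, onset_ms = s$onsets_ms)
  }))
  if (is.null(tab)) tab <- data.frame(electrode = character(0),
                                      onset_ms = numeric(0))
  utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
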
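#' Multi-channel recording session container
#'
#' The in-memory representation of one acquisition session: a channels x
#' samples voltage matrix in microvolts, the sampling rate, the electrode
#' layout the channels map onto, an event log, and the sample indices where
#' the original 1-minute acquisition segments were joined.
#'
#' @param voltages Numeric matrix, channels x samples, microvolts.
#' @param fs Sampling rate in Hz.
#' @param channel_ids Integer vector of `site_id`s, one per row of
#'   `voltages`; must be unique and present in `layout` when a layout is
#'   given.
#' @param layout Optional `electrode_layout`.
#' @param events Optional event log data.frame with columns `time_s`,
#'   `kind`, `route`, `repeat_index`, `notes` (see [event_log()]).
#' @param segment_boundaries Integer vector of 0-based sample offsets at
#'   which segments start; defaults to a single segment at 0.
#' @return An object of class `recording_session`.
#' @export
recording_session <- function(voltages, fs, channel_ids = NULL, layout = NULL,
                              events = NULL, segment_boundaries = 0L) {
  if (is.vector(voltages)) voltages <- matrix(voltages, nrow = 1)
  stopifnot(is.matrix(voltages), is.numeric(voltages))
  if (!is.numeric(fs) || length(fs) != 1 || fs <= 0) stop("`fs` must be > 0")
  n_ch <- nrow(voltages)
  if (is.null(channel_ids)) channel_ids <- seq_len(n_ch)
  if (length(channel_ids) != n_ch) {
    stop("`channel_ids` length must match number of voltage rows")
  }
  if (anyDuplicated(channel_ids)) stop("`channel_ids` must be unique")
  if (!is.null(layout) && !all(channel_ids %in% layout$site_id)) {
    stop("all `channel_ids` must be present in `layout`")
  }
  if (is.null(events)) events <- event_log()
  events <- validate_event_log(events, duration = ncol(voltages) / fs)
  segment_boundaries <- as.integer(segment_boundaries)
  if (length(segment_boundaries) == 0) segment_boundaries <- 0L
  if (is.unsorted(segment_boundaries, strictly = TRUE)) {
    stop("`segment_boundaries` must be strictly increasing")
  }
  structure(
    list(voltages = voltages, fs = fs,
         channel_ids = as.integer(channel_ids), layout = layout,
         events = events, segment_boundaries = segment_boundaries),
    class = "recording_session"
  )
}

#' @export
print.recording_session <- function(x, ...) {
  cat(sprintf(
    "<recording_session> %d channels x %d samples @ %g Hz (%.1f s), %d events, %d segment(s)\n",
    nrow(x$voltages), ncol(x$voltages), x$fs, ncol(x$voltages) / x$fs,
    nrow(x$events), length(x$segment_boundaries)
  ))
  invisible(x)
}

#' Session duration in seconds
#' @param session A `recording_session`.
#' @export
session_duration <- function(session) {
  ncol(session$voltages) / session$fs
}

#' Construct an event log
#'
#' @param time_s Event times in seconds from session start.
#' @param kind Event labels, e.g. `"distension"`, `"drug"`, `"saline"`,
#'   `"contraction"`, `"feeding_onset"`, `"session_start"`.
#' @param route Administration route: `"topical"`, `"intraluminal"` or
#'   `"none"`.
#' @param repeat_index 1-based repeat counter within a kind (drives
#'   desensitization in the simulator).
#' @param notes Free-text notes.
#' @return A data.frame of class `event_log`, sorted by time.
#' @export
event_log <- function(time_s = numeric(), kind = character(),
                      route = "none", repeat_index = 1L, notes = "") {
  n <- length(time_s)
  df <- data.frame(
    time_s = as.numeric(time_s),
    kind = rep_len(as.character(kind), n),
    route = rep_len(as.character(route), n),
    repeat_index = rep_len(as.integer(repeat_index), n),
    notes = rep_len(as.character(notes), n),
    stringsAsFactors = FALSE
  )
  df <- df[order(df$time_s), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("event_log", "data.frame")
  df
}

validate_event_log <- function(events, duration = NULL) {
  req <- c("time_s", "kind", "route", "repeat_index", "notes")
  miss <- setdiff(req, names(events))
  if (length(miss)) {
    stop("event log missing columns: ", paste(miss, collapse = ", "))
  }
  if (is.unsorted(events$time_s)) {
    events <- events[order(events$time_s), , drop = FALSE]
    rownames(events) <- NULL
  }
  if (!is.null(duration) && nrow(events) > 0 &&
      (min(events$time_s) < 0 || max(events$time_s) > duration)) {
    stop("event times must lie within the session duration")
  }
  class(events) <- c("event_log", "data.frame")
  events
}

#' Read an event log from CSV
#'
#' Expects columns `time_s, kind, route, repeat_index, notes`; missing
#' optional columns are filled with defaults.
#' @param path CSV path.
#' @return An `event_log`.
#' @export
read_event_log <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("time_s", "kind") %in% names(df))) {
    stop("event CSV must have at least columns time_s, kind")
  }
  if (is.null(df$route)) df$route <- "none"
  if (is.null(df$repeat_index)) df$repeat_index <- 1L
  if (is.null(df$notes)) df$notes <- ""
  event_log(df$time_s, df$kind, df$route, df$repeat_index, df$notes)
}

#' @rdname read_event_log
#' @param events An `event_log`.
#' @export
write_event_log <- function(events, path) {
  utils::write.csv(as.data.frame(events), path, row.names = FALSE)
  invisible(path)
}
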
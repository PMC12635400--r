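#' Read 1-minute acquisition segments into one session
#'
#' Acquisition writes fixed-length segment files `segNNN.bin` (little-endian
#' float32, channel-major: all samples of channel 1, then channel 2, ...)
#' next to a `meta.json` sidecar declaring `fs`, `channel_ids` and the
#' microvolt scale of the stored values. Segments are concatenated in
#' zero-padded filename order (or the order listed in an optional
#' `manifest.txt`, one filename per line) into a single contiguous session;
#' the start offset of every segment is kept in `segment_boundaries`.
#'
#' @param directory Directory containing `seg*.bin` and `meta.json`.
#' @param layout Optional `electrode_layout` to attach.
#' @param events Optional `event_log` to attach.
#' @return A `recording_session`.
#' @export
read_segments <- function(directory, layout = NULL, events = NULL) {
  meta_path <- file.path(directory, "meta.json")
  if (!file.exists(meta_path)) stop("missing metadata sidecar: ", meta_path)
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  for (f in c("fs", "channel_ids")) {
    if (is.null(meta[[f]])) stop("meta.json missing field: ", f)
  }
  scale_uv <- if (is.null(meta$scale_uv)) 1 else meta$scale_uv
  n_ch <- length(meta$channel_ids)

  manifest <- file.path(directory, "manifest.txt")
  if (file.exists(manifest)) {
    files <- file.path(directory, trimws(readLines(manifest)))
    files <- files[nzchar(basename(files))]
  } else {
    files <- sort(list.files(directory, pattern = "^seg[0-9]+\\.bin$",
                             full.names = TRUE))
  }
  if (length(files) == 0) stop("no segment files found in ", directory)

  chunks <- vector("list", length(files))
  boundaries <- integer(length(files))
  offset <- 0L
  for (i in seq_along(files)) {
    sz <- file.info(files[i])$size
    n_val <- sz / 4
    if (n_val != round(n_val) || n_val %% n_ch != 0) {
      stop("segment ", basename(files[i]),
           " is not a whole number of float32 frames for ", n_ch, " channels")
    }
    v <- readBin(files[i], what = "numeric", size = 4L, n = n_val,
                 endian = "little")
    m <- matrix(v * scale_uv, nrow = n_ch, byrow = TRUE)
    chunks[[i]] <- m
    boundaries[i] <- offset
    offset <- offset + ncol(m)
  }
  voltages <- do.call(cbind, chunks)
  recording_session(voltages, fs = meta$fs, channel_ids = meta$channel_ids,
                    layout = layout, events = events,
                    segment_boundaries = boundaries)
}

#' Write a session as raw-binary segments plus metadata sidecar
#'
#' Inverse of [read_segments()]: splits the session into segments of
#' `segment_s` seconds (last segment may be shorter), written as
#' little-endian float32 channel-major `segNNN.bin` files with a
#' `meta.json` sidecar.
#'
#' @param session A `recording_session`.
#' @param directory Output directory (created if needed).
#' @param segment_s Segment length in seconds (default 60).
#' @return `directory`, invisibly.
#' @export
write_segments <- function(session, directory, segment_s = 60) {
  stopifnot(inherits(session, "recording_session"))
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  n <- ncol(session$voltages)
  seg_len <- round(segment_s * session$fs)
  starts <- seq(1L, n, by = seg_len)
  for (i in seq_along(starts)) {
    idx <- starts[i]:min(starts[i] + seg_len - 1L, n)
    m <- session$voltages[, idx, drop = FALSE]
    # channel-major: all samples of channel 1, then channel 2, ...
    writeBin(as.numeric(t(m)),
             file.path(directory, sprintf("seg%03d.bin", i)),
             size = 4L, endian = "little")
  }
  jsonlite::write_json(
    list(fs = session$fs, channel_ids = session$channel_ids, scale_uv = 1),
    file.path(directory, "meta.json"), auto_unbox = TRUE, digits = NA
  )
  invisible(directory)
}

#' Write / read a session as a columnar (Parquet) container
#'
#' The native on-disk session form mirrors the study's conversion of raw
#' segments to Parquet: a directory holding `voltages.parquet` (one column
#' per channel, named `ch<site_id>`), `events.parquet`, `channels.parquet`
#' (the site table) and a small `meta.json` (fs, segment boundaries, layout
#' parameters). Voltages are stored as float32, so round trips are lossless
#' to float32 precision.
#'
#' @param session A `recording_session`.
#' @param path Container directory path.
#' @return `write_session` returns `path` invisibly; `read_session` returns
#'   the `recording_session`.
#' @export
write_session <- function(session, path) {
  stopifnot(inherits(session, "recording_session"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  vt <- as.data.frame(t(session$voltages))
  names(vt) <- paste0("ch", session$channel_ids)
  sch <- arrow::schema(!!!stats::setNames(
    rep(list(arrow::float32()), ncol(vt)), names(vt)))
  arrow::write_parquet(arrow::Table$create(vt, schema = sch),
                       file.path(path, "voltages.parquet"))
  arrow::write_parquet(as.data.frame(session$events),
                       file.path(path, "events.parquet"))
  if (!is.null(session$layout)) {
    arrow::write_parquet(as.data.frame(session$layout),
                         file.path(path, "channels.parquet"))
  }
  meta <- list(fs = session$fs,
               channel_ids = session$channel_ids,
               segment_boundaries = session$segment_boundaries)
  if (!is.null(session$layout)) {
    meta$layout_attrs <- list(
      within_spacing = attr(session$layout, "within_spacing"),
      between_spacing = attr(session$layout, "between_spacing"),
      n_tetrodes = attr(session$layout, "n_tetrodes"))
  }
  jsonlite::write_json(meta, file.path(path, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_session
#' @export
read_session <- function(path) {
  meta_path <- file.path(path, "meta.json")
  vpath <- file.path(path, "voltages.parquet")
  if (!file.exists(meta_path) || !file.exists(vpath)) {
    stop("not a session container (missing meta.json or voltages.parquet): ",
         path)
  }
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  vt <- as.data.frame(arrow::read_parquet(vpath))
  voltages <- t(as.matrix(vt))
  epath <- file.path(path, "events.parquet")
  events <- if (file.exists(epath)) {
    ev <- as.data.frame(arrow::read_parquet(epath))
    if (nrow(ev)) event_log(ev$time_s, ev$kind, ev$route, ev$repeat_index,
                            ev$notes) else event_log()
  } else NULL
  cpath <- file.path(path, "channels.parquet")
  layout <- NULL
  if (file.exists(cpath) && !is.null(meta$layout_attrs)) {
    ldf <- as.data.frame(arrow::read_parquet(cpath))
    layout <- structure(ldf,
      within_spacing = meta$layout_attrs$within_spacing,
      between_spacing = meta$layout_attrs$between_spacing,
      n_tetrodes = as.integer(meta$layout_attrs$n_tetrodes),
      class = c("electrode_layout", "data.frame"))
  }
  recording_session(voltages, fs = meta$fs, channel_ids = meta$channel_ids,
                    layout = layout, events = events,
                    segment_boundaries = meta$segment_boundaries)
}

#' Impedance-based channel selection
#'
#' Keeps channels whose impedance magnitude stays strictly below
#' `threshold_kohm` on every measurement day provided -- the chronic-use
#' rule that a channel must both start below the acceptability bound
#' (< 500 kOhm) and remain active across all recorded days.
#'
#' @param session A `recording_session`.
#' @param impedances Data.frame with columns `channel_id`, `day`,
#'   `magnitude_kohm` (one row per channel per measurement day). Must cover
#'   every channel of the session.
#' @param threshold_kohm Strict upper bound in kilo-ohms (default 500).
#' @return The session restricted to passing channels, original order kept.
#' @export
select_channels_by_impedance <- function(session, impedances,
                                         threshold_kohm = 500) {
  stopifnot(inherits(session, "recording_session"))
  req <- c("channel_id", "day", "magnitude_kohm")
  if (!all(req %in% names(impedances))) {
    stop("impedance table needs columns: ", paste(req, collapse = ", "))
  }
  if (any(impedances$magnitude_kohm <= 0)) {
    stop("impedance magnitudes must be positive")
  }
  if (!all(session$channel_ids %in% impedances$channel_id)) {
    stop("impedance table must cover all session channels")
  }
  ok_per_ch <- tapply(impedances$magnitude_kohm < threshold_kohm,
                      impedances$channel_id, all)
  keep_ids <- as.numeric(names(ok_per_ch))[ok_per_ch]
  keep <- session$channel_ids %in% keep_ids
  if (!any(keep)) stop("no usable channels: all fail the impedance criterion")
  session$voltages <- session$voltages[keep, , drop = FALSE]
  session$channel_ids <- session$channel_ids[keep]
  session
}
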
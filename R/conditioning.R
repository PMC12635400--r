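#' Zero-phase filtering with reflection padding
#'
#' Forward-backward application of an IIR filter after odd (point-symmetric)
#' extension of the signal at both ends, so constants and slow trends pass
#' without start-up transients. Squares the magnitude response and cancels
#' phase.
#' @noRd
filtfilt_refl <- function(b, a, x, padlen = NULL) {
  n <- length(x)
  if (is.null(padlen)) padlen <- 3 * (max(length(b), length(a)) - 1)
  padlen <- min(padlen, n - 1)
  if (padlen > 0) {
    pre <- 2 * x[1] - x[(padlen + 1):2]
    post <- 2 * x[n] - x[(n - 1):(n - padlen)]
    ext <- c(pre, x, post)
  } else {
    ext <- x
  }
  y <- signal::filter(b, a, ext)
  y <- rev(signal::filter(b, a, rev(y)))
  y[(padlen + 1):(padlen + n)]
}

#' Order-4 Butterworth filtering (zero phase)
#'
#' Designs a Butterworth filter and applies it forward-backward
#' (zero-phase), the conditioning step applied to every raw trace before
#' analysis. Zero-phase application preserves spike timing; note it squares
#' the magnitude response, so an order-4 design attenuates like order 8 in
#' power.
#'
#' @param x Numeric voltage series (microvolts).
#' @param fs Sampling rate, Hz.
#' @param kind One of `"lowpass"`, `"highpass"`, `"bandpass"`.
#' @param cutoffs Cutoff frequency in Hz (scalar for low/high pass,
#'   length-2 ascending vector for bandpass).
#' @param order Filter order of the one-way design (default 4).
#' @return Filtered series, same length as `x`.
#' @export
butterworth_filter <- function(x, fs, kind = c("lowpass", "highpass",
                                               "bandpass"),
                               cutoffs, order = 4) {
  kind <- match.arg(kind)
  if (!all(is.finite(x))) stop("signal must be finite")
  if (order < 1 || order != round(order)) stop("`order` must be an integer >= 1")
  nyq <- fs / 2
  if (any(cutoffs <= 0) || any(cutoffs >= nyq)) {
    stop("cutoffs must lie strictly between 0 and the Nyquist frequency")
  }
  if (kind == "bandpass") {
    if (length(cutoffs) != 2 || cutoffs[1] >= cutoffs[2]) {
      stop("bandpass needs ascending length-2 cutoffs")
    }
    bf <- signal::butter(order, cutoffs / nyq, type = "pass")
  } else {
    if (length(cutoffs) != 1) stop(kind, " needs a single cutoff")
    bf <- signal::butter(order, cutoffs / nyq,
                         type = if (kind == "lowpass") "low" else "high")
  }
  # pad generously relative to the slowest time constant involved
  padlen <- max(3 * (length(bf$b) - 1), ceiling(10 * fs / min(cutoffs)))
  filtfilt_refl(bf$b, bf$a, x, padlen = padlen)
}

#' Notch out mains interference at 50 Hz and odd harmonics
#'
#' Cascaded narrow second-order IIR notches at the mains base frequency and
#' its odd multiples (50, 150, 250, ... Hz by default), each applied
#' zero-phase. Even harmonics are left untouched.
#'
#' @param x Numeric voltage series.
#' @param fs Sampling rate, Hz.
#' @param base Mains frequency, Hz (default 50).
#' @param max_harmonic_hz Highest notch frequency to apply (default 350).
#' @param q Notch quality factor (center frequency / -3 dB bandwidth,
#'   default 30).
#' @return Filtered series, same length as `x`.
#' @export
notch_line_noise <- function(x, fs, base = 50, max_harmonic_hz = 350,
                             q = 30) {
  nyq <- fs / 2
  if (base >= nyq) stop("notch base frequency must be below Nyquist")
  freqs <- seq(base, min(max_harmonic_hz, nyq * 0.98), by = 2 * base)
  y <- x
  for (f0 in freqs) {
    w0 <- 2 * pi * f0 / fs
    alpha <- sin(w0) / (2 * q)
    b <- c(1, -2 * cos(w0), 1)
    a <- c(1 + alpha, -2 * cos(w0), 1 - alpha)
    b <- b / a[1]
    a <- a / a[1]
    # the narrow notch rings for ~2Q/omega0 seconds; pad several times that
    y <- filtfilt_refl(b, a, y, padlen = ceiling(5 * fs * q / (pi * f0)))
  }
  y
}

#' Common average reference
#'
#' Subtracts the instantaneous across-channel mean from every channel,
#' removing signal components shared by all electrodes (volume-conducted
#' artifacts, residual mains). The output channel mean is exactly zero at
#' every sample.
#'
#' @param session A `recording_session` (or plain channels x samples
#'   matrix) with at least 2 channels.
#' @return Object of the same type with referenced voltages.
#' @export
common_reference <- function(session) {
  v <- if (inherits(session, "recording_session")) session$voltages else session
  if (nrow(v) < 2) {
    stop("common referencing requires at least 2 channels")
  }
  ref <- colMeans(v)
  for (ch in seq_len(nrow(v))) v[ch, ] <- v[ch, ] - ref
  if (inherits(session, "recording_session")) {
    session$voltages <- v
    session
  } else {
    v
  }
}

#' Anti-aliased integer-factor downsampling
#'
#' Applies a sharp linear-phase FIR low-pass (Hamming-windowed, 1024 taps,
#' -6 dB at the target Nyquist frequency) with group-delay compensation,
#' then keeps every `fs/target_fs`-th sample. Tones below ~0.98 of the
#' target Nyquist pass essentially unchanged; content above the target
#' Nyquist is suppressed by > 50 dB before decimation. Event times (in
#' seconds) are unchanged; segment boundaries are rescaled.
#'
#' @param session A `recording_session`.
#' @param target_fs Target sampling rate, Hz (default 10000). Must divide
#'   `fs`.
#' @param n_taps FIR length minus one; even (default 1024).
#' @return The downsampled `recording_session`.
#' @export
downsample <- function(session, target_fs = 10000, n_taps = 1024) {
  stopifnot(inherits(session, "recording_session"))
  fs <- session$fs
  if (target_fs >= fs) stop("`target_fs` must be below the session rate")
  factor <- fs / target_fs
  if (abs(factor - round(factor)) > 1e-9) {
    stop("`target_fs` must divide the session sampling rate")
  }
  factor <- round(factor)
  b <- signal::fir1(n_taps, (target_fs / 2) / (fs / 2), type = "low")
  half <- n_taps / 2
  n <- ncol(session$voltages)
  keep <- seq(1L, n, by = factor)
  out <- matrix(0, nrow = nrow(session$voltages), ncol = length(keep))
  for (ch in seq_len(nrow(session$voltages))) {
    x <- session$voltages[ch, ]
    y <- signal::fftfilt(b, c(x, numeric(half)))
    out[ch, ] <- y[half + keep]
  }
  session$voltages <- out
  session$fs <- target_fs
  session$segment_boundaries <-
    as.integer(floor(session$segment_boundaries / factor))
  session
}

#' Detect EMG-like artifact epochs
#'
#' Automated stand-in for manual inspection: flags stretches where a large
#' fraction of channels simultaneously exceed a multiple of their
#' per-channel robust SD (median absolute amplitude / 0.6745), pads each
#' flagged stretch and merges overlapping stretches. Synchronized
#' high-amplitude activity across the array is the signature of EMG
#' contamination rather than localized neural spiking.
#'
#' @param session A conditioned `recording_session`.
#' @param amplitude_sd_mult Robust-SD multiple a sample must exceed
#'   (default 8).
#' @param min_channels_frac Fraction of channels that must exceed it
#'   simultaneously (default 0.9).
#' @param pad Padding added on each side of a flagged stretch, seconds
#'   (default 0.2).
#' @return A data.frame of class `artifact_epochs` with columns `start_s`,
#'   `end_s`, `reason`.
#' @export
detect_artifact_epochs <- function(session, amplitude_sd_mult = 8,
                                   min_channels_frac = 0.9, pad = 0.2) {
  stopifnot(inherits(session, "recording_session"))
  v <- session$voltages
  robust_sd <- apply(v, 1, function(x) stats::median(abs(x)) / 0.6745)
  robust_sd[robust_sd == 0] <- Inf  # silent channels never flag
  exceed <- abs(v) > amplitude_sd_mult * robust_sd
  frac <- colMeans(exceed)
  flagged <- frac >= min_channels_frac
  epochs_from_mask(flagged, session$fs, pad = pad, reason = "emg",
                   duration = session_duration(session))
}

#' Convert a logical per-sample mask into padded, merged epochs
#' @noRd
epochs_from_mask <- function(mask, fs, pad = 0, reason = "emg",
                             duration = length(mask) / fs) {
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  on <- which(r$values)
  if (length(on) == 0) {
    return(artifact_epochs(numeric(), numeric(), character()))
  }
  s <- pmax((starts[on] - 1) / fs - pad, 0)
  e <- pmin(ends[on] / fs + pad, duration)
  merged_s <- s[1]; merged_e <- e[1]
  out_s <- numeric(); out_e <- numeric()
  if (length(on) > 1) {
    for (i in 2:length(on)) {
      if (s[i] <= merged_e) {
        merged_e <- max(merged_e, e[i])
      } else {
        out_s <- c(out_s, merged_s); out_e <- c(out_e, merged_e)
        merged_s <- s[i]; merged_e <- e[i]
      }
    }
  }
  out_s <- c(out_s, merged_s); out_e <- c(out_e, merged_e)
  artifact_epochs(out_s, out_e, reason)
}

#' Construct / read / write artifact epoch tables
#'
#' @param start_s,end_s Epoch bounds in seconds.
#' @param reason Label: `"emg"`, `"sharp_deflection"` or `"manual"`.
#' @return A data.frame of class `artifact_epochs`.
#' @export
artifact_epochs <- function(start_s = numeric(), end_s = numeric(),
                            reason = character()) {
  n <- length(start_s)
  if (n && any(end_s < start_s)) stop("epoch end before start")
  df <- data.frame(start_s = as.numeric(start_s),
                   end_s = as.numeric(end_s),
                   reason = rep_len(if (n) as.character(reason) else
                     character(), n),
                   stringsAsFactors = FALSE)
  df <- df[order(df$start_s), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("artifact_epochs", "data.frame")
  df
}

#' @rdname artifact_epochs
#' @param path CSV path with columns start_s, end_s, reason.
#' @export
read_artifact_epochs <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  artifact_epochs(df$start_s, df$end_s, df$reason)
}

#' @rdname artifact_epochs
#' @param epochs An `artifact_epochs` table.
#' @export
write_artifact_epochs <- function(epochs, path) {
  utils::write.csv(as.data.frame(epochs), path, row.names = FALSE)
  invisible(path)
}
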
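#' Welch power spectral density
#'
#' Averages modified periodograms over (optionally overlapping)
#' Hann-windowed segments. Frequency spacing is `fs / segment_length`, so a
#' 1,000,000-sample segment at 10 kHz resolves ~0.01 Hz -- fine enough for
#' the slow-wave rhythms of interstitial cells of Cajal. Densities are
#' one-sided, in signal-units^2 per Hz.
#'
#' @param x Numeric series.
#' @param fs Sampling rate, Hz.
#' @param segment_length Samples per segment (default 512).
#' @param overlap_frac Fractional overlap between consecutive segments in
#'   `[0, 1)` (default 0, i.e. non-overlapping).
#' @param detrend Remove each segment's mean before windowing
#'   (default TRUE).
#' @return Object of class `psd_estimate`: list with `freq` (Hz),
#'   `density`, `fs`, `segment_length`, `overlap_frac`, `n_segments`.
#' @export
welch_psd <- function(x, fs, segment_length = 512, overlap_frac = 0,
                      detrend = TRUE) {
  n <- length(x)
  L <- as.integer(segment_length)
  if (n < L) stop("signal shorter than one segment")
  if (overlap_frac < 0 || overlap_frac >= 1) {
    stop("`overlap_frac` must be in [0, 1)")
  }
  step <- max(1L, as.integer(round(L * (1 - overlap_frac))))
  starts <- seq(1L, n - L + 1L, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * seq(0, L - 1) / L)  # periodic Hann
  U <- sum(w^2)
  seg <- vapply(starts, function(s) {
    xi <- x[s:(s + L - 1L)]
    if (detrend) xi <- xi - mean(xi)
    xi * w
  }, numeric(L))
  F <- stats::mvfft(seg)
  n_keep <- floor(L / 2) + 1L
  P <- (Mod(F[seq_len(n_keep), , drop = FALSE])^2) / (fs * U)
  scale2 <- rep(2, n_keep)
  scale2[1] <- 1
  if (L %% 2 == 0) scale2[n_keep] <- 1
  density <- rowMeans(P) * scale2
  structure(
    list(freq = seq(0, n_keep - 1) * fs / L, density = density, fs = fs,
         segment_length = L, overlap_frac = overlap_frac,
         n_segments = length(starts)),
    class = "psd_estimate"
  )
}

#' @export
print.psd_estimate <- function(x, ...) {
  cat(sprintf("<psd_estimate> %d bins, df = %g Hz, %d segment(s) of %d samples\n",
              length(x$freq), x$fs / x$segment_length, x$n_segments,
              x$segment_length))
  invisible(x)
}

#' Short-time PSD spectrogram in decibels
#'
#' Hann-windowed short-time power spectral density on a dB scale (psd
#' mode), the time-frequency view used to quantify evoked drug responses.
#' Times are the centers of each segment; powers are floored at
#' `floor_db`.
#'
#' @param x Numeric series.
#' @param fs Sampling rate, Hz.
#' @param nfft Segment / FFT length in samples (default 256).
#' @param overlap Overlapping samples between segments (default 128).
#' @param floor_db Lower clip for the dB scale (default -120).
#' @return Object of class `spectrogram`: list with `times` (s), `freq`
#'   (Hz), `power_db` (freq x time), `nfft`, `overlap`, `fs`, `floor_db`.
#' @export
spectrogram <- function(x, fs, nfft = 256, overlap = 128,
                        floor_db = -120) {
  n <- length(x)
  nfft <- as.integer(nfft)
  if (nfft > n) stop("`nfft` exceeds signal length")
  if (overlap >= nfft) stop("`overlap` must be below `nfft`")
  step <- nfft - as.integer(overlap)
  starts <- seq(1L, n - nfft + 1L, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * seq(0, nfft - 1) / nfft)
  U <- sum(w^2)
  seg <- vapply(starts, function(s) x[s:(s + nfft - 1L)] * w,
                numeric(nfft))
  F <- stats::mvfft(seg)
  n_keep <- floor(nfft / 2) + 1L
  P <- (Mod(F[seq_len(n_keep), , drop = FALSE])^2) / (fs * U)
  scale2 <- rep(2, n_keep)
  scale2[1] <- 1
  if (nfft %% 2 == 0) scale2[n_keep] <- 1
  P <- P * scale2
  p_floor <- 10^(floor_db / 10)
  power_db <- 10 * log10(pmax(P, p_floor))
  structure(
    list(times = (starts - 1 + nfft / 2) / fs,
         freq = seq(0, n_keep - 1) * fs / nfft,
         power_db = power_db, nfft = nfft, overlap = as.integer(overlap),
         fs = fs, floor_db = floor_db),
    class = "spectrogram"
  )
}

#' @export
print.spectrogram <- function(x, ...) {
  cat(sprintf("<spectrogram> %d freq x %d time bins, nfft %d, overlap %d\n",
              nrow(x$power_db), ncol(x$power_db), x$nfft, x$overlap))
  invisible(x)
}

#' Composite Simpson integration on a uniform grid
#'
#' Standard composite Simpson rule; when the number of intervals is odd the
#' final interval is handled by the trapezoid rule.
#' @noRd
simpson_uniform <- function(y, h) {
  n <- length(y)
  if (n < 2) return(0)
  if (n == 2) return(h * (y[1] + y[2]) / 2)
  if ((n - 1) %% 2 == 1) {
    return(simpson_uniform(y[seq_len(n - 1)], h) + h * (y[n - 1] + y[n]) / 2)
  }
  w <- rep(2, n)
  w[c(1, n)] <- 1
  w[seq(2, n - 1, by = 2)] <- 4
  (h / 3) * sum(w * y)
}

#' Rolling spectrogram-AUC series
#'
#' The evoked-response statistic: the spectrogram's columns are collapsed
#' over frequency (trapezoid over the frequency axis, yielding dB*Hz per
#' column) and the collapsed series is Simpson-integrated over time within
#' consecutive, non-overlapping windows of `window` seconds. A trailing
#' partial window is dropped.
#'
#' @param spec A `spectrogram`.
#' @param window Window length in seconds (default 1).
#' @return Object of class `auc_series`: data.frame with `window_start`
#'   (s) and `auc` (dB*Hz*s), plus a `window` attribute.
#' @export
rolling_spectrogram_auc <- function(spec, window = 1) {
  stopifnot(inherits(spec, "spectrogram"))
  dt <- (spec$nfft - spec$overlap) / spec$fs
  if (window < dt) stop("`window` is shorter than one spectrogram column")
  n_cols <- ncol(spec$power_db)
  cols_per_win <- max(2L, as.integer(round(window / dt)))
  n_win <- floor(n_cols / cols_per_win)
  if (n_win < 1) stop("spectrogram spans less than one window")
  collapsed <- apply(spec$power_db, 2, function(col)
    pracma::trapz(spec$freq, col))
  auc <- numeric(n_win)
  starts <- numeric(n_win)
  for (k in seq_len(n_win)) {
    idx <- ((k - 1L) * cols_per_win + 1L):(k * cols_per_win)
    auc[k] <- simpson_uniform(collapsed[idx], dt)
    starts[k] <- spec$times[idx[1]] - dt / 2
  }
  structure(data.frame(window_start = starts, auc = auc),
            window = window, class = c("auc_series", "data.frame"))
}

#' Summary metrics of an AUC response series
#'
#' Maximum, mean and population variance of the per-window AUC over the
#' post-event span, the three scalars used to compare drug additions.
#'
#' @param auc An `auc_series`.
#' @param response_start Only windows starting at or after this time enter
#'   the metrics (default: all windows).
#' @param response_end Optional exclusive upper bound on window starts.
#' @return Object of class `response_metrics`: list with `max`, `mean`,
#'   `variance` (population convention), and `normalized_*` slots filled by
#'   [normalize_metrics()].
#' @export
response_metrics <- function(auc, response_start = NULL,
                             response_end = NULL) {
  stopifnot(inherits(auc, "auc_series"))
  keep <- rep(TRUE, nrow(auc))
  if (!is.null(response_start)) keep <- keep & auc$window_start >= response_start
  if (!is.null(response_end)) keep <- keep & auc$window_start < response_end
  vals <- auc$auc[keep]
  if (length(vals) == 0) stop("no AUC windows in the requested span")
  structure(
    list(max = max(vals), mean = mean(vals),
         variance = mean((vals - mean(vals))^2),
         normalized_max = NA_real_, normalized_mean = NA_real_,
         normalized_variance = NA_real_),
    class = "response_metrics"
  )
}

#' Min-max normalize response metrics across conditions
#'
#' Rescales each metric (max, mean, variance) across all conditions of one
#' experiment to the [0, 1] range: the smallest condition maps to 0 and the
#' largest to 1, so a saline control that always evokes the weakest
#' response lands at 0. A metric with zero range across conditions is a
#' degenerate experiment: all its normalized values are set to 0 and the
#' result carries a `degenerate` attribute naming the metric(s).
#'
#' @param metrics_by_condition Named list (>= 2 entries) of
#'   `response_metrics`.
#' @return The same list with `normalized_*` fields filled.
#' @export
normalize_metrics <- function(metrics_by_condition) {
  if (length(metrics_by_condition) < 2) {
    stop("normalization requires at least 2 conditions")
  }
  stopifnot(all(vapply(metrics_by_condition, inherits, logical(1),
                       "response_metrics")))
  degenerate <- character()
  for (metric in c("max", "mean", "variance")) {
    vals <- vapply(metrics_by_condition, `[[`, numeric(1), metric)
    rng <- max(vals) - min(vals)
    if (rng == 0) {
      degenerate <- c(degenerate, metric)
      norm <- rep(0, length(vals))
    } else {
      norm <- (vals - min(vals)) / rng
    }
    for (i in seq_along(metrics_by_condition)) {
      metrics_by_condition[[i]][[paste0("normalized_", metric)]] <- norm[i]
    }
  }
  if (length(degenerate)) {
    warning("degenerate experiment: zero range for metric(s) ",
            paste(degenerate, collapse = ", "))
    attr(metrics_by_condition, "degenerate") <- degenerate
  }
  metrics_by_condition
}

#' The five gut-signal frequency bands
#'
#' Half-open intervals `[lo, hi)` partitioning 0-2000 Hz: 0-0.2 Hz (slow
#' waves of interstitial cells of Cajal), 0.2-1 Hz (circular smooth muscle
#' rhythms), 1-5 Hz (faster smooth muscle activity), 5-300 Hz (skeletal
#' muscle / movement), 300-2000 Hz (high-frequency neural components).
#'
#' @return Data.frame with columns `label`, `lo`, `hi` (Hz).
#' @export
gut_bands <- function() {
  data.frame(
    label = c("0-0.2", "0.2-1", "1-5", "5-300", "300-2000"),
    lo = c(0, 0.2, 1, 5, 300),
    hi = c(0.2, 1, 5, 300, 2000),
    stringsAsFactors = FALSE
  )
}

#' Bandwidth-normalized power per frequency band
#'
#' Integrates the PSD over each band `[lo, hi)` (trapezoid on the PSD grid
#' with linear interpolation at the band edges) and divides by the
#' bandwidth, so a flat spectrum reports the same normalized power
#' (units^2/Hz) in every band regardless of width.
#'
#' @param psd A `psd_estimate`.
#' @param bands Band table as from [gut_bands()]; must be ordered and
#'   non-overlapping, and covered by the PSD frequency range.
#' @return Data.frame with columns `band`, `lo`, `hi`, `power`.
#' @export
band_power <- function(psd, bands = gut_bands()) {
  stopifnot(inherits(psd, "psd_estimate"))
  if (!all(c("label", "lo", "hi") %in% names(bands))) {
    stop("`bands` needs columns label, lo, hi")
  }
  if (any(bands$hi <= bands$lo)) stop("bands must have hi > lo")
  if (is.unsorted(bands$lo, strictly = TRUE) ||
      any(bands$lo[-1] < bands$hi[-nrow(bands)])) {
    stop("bands must be ordered and non-overlapping")
  }
  f <- psd$freq
  d <- psd$density
  if (min(bands$lo) < f[1] || max(bands$hi) > f[length(f)]) {
    stop("band extends beyond the PSD frequency range")
  }
  pw <- mapply(function(lo, hi) {
    inside <- f > lo & f < hi
    xs <- c(lo, f[inside], hi)
    ys <- c(stats::approx(f, d, lo)$y, d[inside],
            stats::approx(f, d, hi)$y)
    pracma::trapz(xs, ys) / (hi - lo)
  }, bands$lo, bands$hi)
  data.frame(band = bands$label, lo = bands$lo, hi = bands$hi,
             power = as.numeric(pw), stringsAsFactors = FALSE)
}
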
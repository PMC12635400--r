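#' Binned, z-scored instantaneous firing rate
#'
#' Spike counts in fixed bins divided by the bin width, then z-scored
#' across all bins of the session so units with different baseline rates
#' are comparable. A constant (or empty) rate series cannot be z-scored;
#' its z values are defined as all zero and flagged.
#'
#' @param train A `spike_train` or numeric vector of spike times, seconds.
#' @param t_start,t_end Session span covered by the binning, seconds.
#' @param bin Bin width, seconds (default 3).
#' @return Object of class `rate_series`: data.frame `bin_start` (s),
#'   `rate` (Hz), `z`, with attributes `bin` and `constant` (TRUE when the
#'   z-scores are degenerate).
#' @export
instantaneous_rate <- function(train, t_start = 0, t_end, bin = 3) {
  if (bin <= 0) stop("`bin` must be positive")
  times <- if (inherits(train, "spike_train")) train$time_s else
    as.numeric(train)
  edges <- seq(t_start, t_end, by = bin)
  if (length(edges) < 2) stop("span shorter than one bin")
  tin <- times[times >= t_start & times < edges[length(edges)]]
  counts <- tabulate(findInterval(tin, edges, rightmost.closed = FALSE),
                     nbins = length(edges) - 1)
  rate <- counts / bin
  s <- stats::sd(rate)
  constant <- is.na(s) || s == 0
  z <- if (constant) rep(0, length(rate)) else (rate - mean(rate)) / s
  structure(data.frame(bin_start = edges[-length(edges)], rate = rate,
                       z = z),
            bin = bin, constant = constant,
            class = c("rate_series", "data.frame"))
}

#' Align unit rates to feeding onset and label meal epochs
#'
#' Labels every rate bin as `pre_meal` (the novel-environment span before
#' feeding), `meal`, or `post_meal`, computes each unit's mean z per
#' epoch, and the population average z per aligned bin.
#'
#' @param rates List of `rate_series` (one per unit, identical binning).
#' @param feeding_onset Feeding onset, seconds.
#' @param meal_dur Meal epoch duration, seconds (default 300).
#' @param pre_span Length of the pre-meal epoch, seconds (default 900,
#'   the 15 min novel-environment period).
#' @return List with `epoch_means` (data.frame unit, pre_meal, meal,
#'   post_meal), `labels` (per-bin epoch factor), `population`
#'   (data.frame bin_start, mean_z). Epochs truncated by the session emit
#'   a warning.
#' @export
align_to_feeding <- function(rates, feeding_onset, meal_dur = 300,
                             pre_span = 900) {
  stopifnot(length(rates) >= 1)
  bins <- rates[[1]]$bin_start
  if (!all(vapply(rates, function(r) identical(r$bin_start, bins),
                  logical(1)))) {
    stop("all rate series must share the same binning")
  }
  t_end <- bins[length(bins)] + attr(rates[[1]], "bin")
  if (feeding_onset < bins[1] || feeding_onset > t_end) {
    stop("`feeding_onset` must lie inside the session")
  }
  pre_start <- feeding_onset - pre_span
  if (pre_start < bins[1]) {
    warning("pre-meal epoch truncated to the session start")
    pre_start <- bins[1]
  }
  meal_end <- feeding_onset + meal_dur
  if (meal_end > t_end) {
    warning("meal epoch truncated to the session end")
    meal_end <- t_end
  }
  labels <- rep(NA_character_, length(bins))
  labels[bins >= pre_start & bins < feeding_onset] <- "pre_meal"
  labels[bins >= feeding_onset & bins < meal_end] <- "meal"
  labels[bins >= meal_end] <- "post_meal"
  if (!any(labels == "pre_meal", na.rm = TRUE)) {
    warning("pre-meal epoch is empty")
  }
  epoch_means <- do.call(rbind, lapply(seq_along(rates), function(u) {
    z <- rates[[u]]$z
    data.frame(unit = u,
               pre_meal = mean(z[which(labels == "pre_meal")]),
               meal = mean(z[which(labels == "meal")]),
               post_meal = mean(z[which(labels == "post_meal")]))
  }))
  pop <- data.frame(bin_start = bins,
                    mean_z = rowMeans(vapply(rates, function(r) r$z,
                                             numeric(length(bins)))))
  list(epoch_means = epoch_means, labels = factor(labels,
         levels = c("pre_meal", "meal", "post_meal")), population = pop)
}

#' Omnibus and pairwise comparison of meal epochs
#'
#' Kruskal-Wallis over the three per-unit epoch-mean samples, followed by
#' pairwise two-sided Wilcoxon signed-rank tests on the paired unit means
#' with Bonferroni correction over the 3-test family.
#'
#' @param epoch_means Data.frame with columns `pre_meal`, `meal`,
#'   `post_meal` (one row per unit, >= 5 units).
#' @return Object of class `epoch_comparison`: list with
#'   `kruskal_statistic`, `kruskal_p`, and `pairwise` (data.frame: pair,
#'   p_raw, p_adj with `p_adj = min(1, 3 * p_raw)`).
#' @export
epoch_comparison <- function(epoch_means) {
  req <- c("pre_meal", "meal", "post_meal")
  if (!all(req %in% names(epoch_means))) {
    stop("missing epoch columns: ",
         paste(setdiff(req, names(epoch_means)), collapse = ", "))
  }
  if (nrow(epoch_means) < 5) stop("need at least 5 units")
  if (any(!is.finite(as.matrix(epoch_means[req])))) {
    stop("epoch means must be finite (empty epoch?)")
  }
  kw <- stats::kruskal.test(list(epoch_means$pre_meal, epoch_means$meal,
                                 epoch_means$post_meal))
  pairs <- list(c("pre_meal", "meal"), c("pre_meal", "post_meal"),
                c("meal", "post_meal"))
  pw <- do.call(rbind, lapply(pairs, function(pr) {
    wt <- suppressWarnings(
      stats::wilcox.test(epoch_means[[pr[1]]], epoch_means[[pr[2]]],
                         paired = TRUE))
    data.frame(pair = paste(pr, collapse = " vs "), p_raw = wt$p.value)
  }))
  pw$p_adj <- pmin(1, pw$p_raw * nrow(pw))
  structure(list(kruskal_statistic = unname(kw$statistic),
                 kruskal_p = kw$p.value, pairwise = pw),
            class = "epoch_comparison")
}

#' @export
print.epoch_comparison <- function(x, ...) {
  cat(sprintf("<epoch_comparison> Kruskal-Wallis H = %.3g, p = %.3g\n",
              x$kruskal_statistic, x$kruskal_p))
  print(x$pairwise)
  invisible(x)
}

#' Per-minute multi-band power profile
#'
#' The chronic stress analysis: the (10 kHz, common-referenced) session is
#' cut into 1-minute intervals; within each interval every channel's Welch
#' PSD is computed and integrated over the five gut bands
#' (bandwidth-normalized), then averaged over channels. The configured
#' Welch segment length (1,000,000 samples for ~0.01 Hz whole-session
#' resolution) is capped at the interval length, since a minute at 10 kHz
#' holds only 600,000 samples.
#'
#' @param session A conditioned `recording_session` (downsampled and
#'   common-referenced), at least one minute long.
#' @param bands Band table (default [gut_bands()]).
#' @param minute_window Interval length, seconds (default 60).
#' @param welch_segment Welch segment length in samples (default 1e6,
#'   capped at the interval length).
#' @param overlap_frac Welch segment overlap (default 0.5).
#' @return Data.frame of class `stress_profile`: `minute` (1-based),
#'   `band`, `power` (uV^2/Hz, averaged over channels).
#' @export
stress_band_profile <- function(session, bands = gut_bands(),
                                minute_window = 60, welch_segment = 1e6,
                                overlap_frac = 0.5) {
  stopifnot(inherits(session, "recording_session"))
  fs <- session$fs
  if (max(bands$hi) > fs / 2) {
    stop("highest band exceeds the Nyquist frequency; downsample less aggressively")
  }
  n <- ncol(session$voltages)
  win <- round(minute_window * fs)
  if (n < win) stop("session shorter than one interval")
  n_min <- floor(n / win)
  seg <- as.integer(min(welch_segment, win))
  out <- vector("list", n_min)
  for (m in seq_len(n_min)) {
    idx <- ((m - 1L) * win + 1L):(m * win)
    bp_ch <- vapply(seq_len(nrow(session$voltages)), function(ch) {
      psd <- welch_psd(session$voltages[ch, idx], fs,
                       segment_length = seg, overlap_frac = overlap_frac)
      band_power(psd, bands)$power
    }, numeric(nrow(bands)))
    out[[m]] <- data.frame(minute = m, band = bands$label,
                           power = rowMeans(matrix(bp_ch,
                                                   nrow = nrow(bands))))
  }
  res <- do.call(rbind, out)
  class(res) <- c("stress_profile", "data.frame")
  res
}
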
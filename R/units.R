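#' Robust per-channel noise floor
#'
#' Estimated over the artifact-free portions of a 300 Hz high-passed
#' trace: the 5 longest artifact-free epochs are concatenated and the
#' floor computed as `mean(|x| / 0.6745)` (the printed convention; 0.6745
#' is the upper quartile of the standard normal). For Gaussian noise of SD
#' sigma this converges to `sigma * sqrt(2/pi) / 0.6745 ~= 1.183 * sigma`;
#' the `robust = "median"` variant (`median(|x|) / 0.6745`, the classical
#' MAD estimator) converges to sigma itself.
#'
#' @param x High-passed voltage series.
#' @param fs Sampling rate, Hz.
#' @param artifact_epochs_table An `artifact_epochs` table (may be empty).
#' @param n_epochs Number of longest artifact-free epochs to use
#'   (default 5; fewer are used when fewer exist).
#' @param robust `"mean"` (as printed, default) or `"median"` (MAD).
#' @return Object of class `noise_floor_estimate`: list with `floor` (uV),
#'   `constant` (0.6745), `epochs_used` (data.frame start_s, end_s),
#'   `method`.
#' @export
noise_floor <- function(x, fs, artifact_epochs_table = artifact_epochs(),
                        n_epochs = 5, robust = c("mean", "median")) {
  robust <- match.arg(robust)
  n <- length(x)
  duration <- n / fs
  free <- complement_epochs(artifact_epochs_table, duration)
  if (nrow(free) == 0) stop("no artifact-free samples available")
  free$len <- free$end_s - free$start_s
  free <- free[order(-free$len), , drop = FALSE]
  used <- utils::head(free, n_epochs)
  used <- used[order(used$start_s), c("start_s", "end_s"), drop = FALSE]
  idx <- unlist(lapply(seq_len(nrow(used)), function(i) {
    s <- max(1L, floor(used$start_s[i] * fs) + 1L)
    e <- min(n, ceiling(used$end_s[i] * fs))
    if (s <= e) s:e else integer()
  }))
  vals <- abs(x[idx]) / 0.6745
  fl <- if (robust == "mean") mean(vals) else stats::median(vals)
  structure(list(floor = fl, constant = 0.6745, epochs_used = used,
                 method = robust),
            class = "noise_floor_estimate")
}

#' Complement of an epoch table within [0, duration]
#' @noRd
complement_epochs <- function(epochs, duration) {
  if (nrow(epochs) == 0) {
    return(data.frame(start_s = 0, end_s = duration))
  }
  ep <- epochs[order(epochs$start_s), , drop = FALSE]
  starts <- c(0, ep$end_s)
  ends <- c(ep$start_s, duration)
  keep <- ends > starts
  data.frame(start_s = starts[keep], end_s = ends[keep])
}

#' Threshold-crossing spike detection
#'
#' Detects negative-going extracellular spikes: local minima falling below
#' `-multiplier * floor`, one event per sub-threshold excursion, with a
#' 1 ms lockout preventing double counts of one excursion. The multiplier
#' is conventionally curated between 4 and 6 per session; values outside
#' that range are allowed but flagged with a warning.
#'
#' @param x High-passed voltage series.
#' @param fs Sampling rate, Hz.
#' @param floor A `noise_floor_estimate` (or bare numeric floor, uV).
#' @param multiplier Threshold multiple of the noise floor (default 5).
#' @param lockout_ms Minimum spacing between detected events,
#'   milliseconds (default 1).
#' @return Object of class `spike_train`: data.frame `time_s` (trough
#'   times, strictly increasing), `amplitude` (trough values, uV, all
#'   below threshold), with attributes `fs`, `threshold`, `multiplier`.
#' @export
detect_spikes <- function(x, fs, floor, multiplier = 5, lockout_ms = 1) {
  fl <- if (inherits(floor, "noise_floor_estimate")) floor$floor else floor
  if (multiplier < 4 || multiplier > 6) {
    warning("threshold multiplier ", multiplier,
            " is outside the conventional 4-6 range")
  }
  thr <- -multiplier * fl
  below <- x < thr
  if (!any(below)) {
    return(structure(data.frame(time_s = numeric(), amplitude = numeric()),
                     fs = fs, threshold = thr, multiplier = multiplier,
                     class = c("spike_train", "data.frame")))
  }
  r <- rle(below)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  on <- which(r$values)
  troughs <- vapply(on, function(i) {
    seg <- starts[i]:ends[i]
    seg[which.min(x[seg])]
  }, integer(1))
  troughs <- sort(troughs)
  # lockout: one event per lockout_ms
  lock <- lockout_ms / 1000 * fs
  keep <- logical(length(troughs))
  last <- -Inf
  for (i in seq_along(troughs)) {
    if (troughs[i] - last >= lock) {
      keep[i] <- TRUE
      last <- troughs[i]
    }
  }
  troughs <- troughs[keep]
  structure(data.frame(time_s = (troughs - 1) / fs,
                       amplitude = x[troughs]),
            fs = fs, threshold = thr, multiplier = multiplier,
            class = c("spike_train", "data.frame"))
}

#' Remove spikes coincident across most of the array
#'
#' A genuine single-cell spike appears on one tetrode; an event detected
#' simultaneously on (nearly) every channel of the array is an artifact.
#' Spikes with matches within `window_ms` on at least
#' `channel_frac` of all channels are removed from every train.
#'
#' @param trains List of `spike_train`s, one per channel (>= 2).
#' @param window_ms Coincidence half-window, milliseconds (default 0.5).
#' @param channel_frac Fraction of channels that makes a coincidence an
#'   artifact (default 0.9, tolerating a few dead channels).
#' @return The list of trains with artifact spikes removed.
#' @export
reject_coincident <- function(trains, window_ms = 0.5, channel_frac = 0.9) {
  if (length(trains) < 2) stop("need at least 2 channels")
  w <- window_ms / 1000
  n_ch <- length(trains)
  times <- lapply(trains, function(tr) tr$time_s)
  for (i in seq_len(n_ch)) {
    ti <- times[[i]]
    if (length(ti) == 0) next
    n_coinc <- rep(1L, length(ti))  # own channel counts
    for (j in seq_len(n_ch)) {
      if (j == i) next
      tj <- times[[j]]
      if (length(tj) == 0) next
      lo <- findInterval(ti - w, tj)
      hi <- findInterval(ti + w, tj)
      n_coinc <- n_coinc + as.integer(hi > lo)
    }
    drop <- n_coinc >= channel_frac * n_ch
    if (any(drop)) {
      trains[[i]] <- trains[[i]][!drop, , drop = FALSE]
      rownames(trains[[i]]) <- NULL
    }
  }
  trains
}

#' Extract multi-channel spike waveforms
#'
#' Cuts aligned snippets of `duration_ms` around each spike trough across
#' all channels, with the trough at `pre_frac` of the snippet. Spikes too
#' close to the session edges are dropped and their count reported in the
#' `n_dropped` attribute.
#'
#' @param session_hp A high-passed `recording_session`.
#' @param train A `spike_train` (times from any channel).
#' @param duration_ms Snippet duration, milliseconds (default 3.5).
#' @param pre_frac Fraction of the snippet before the trough
#'   (default 1/3).
#' @return Array spikes x channels x samples of class `waveform_set`, with
#'   attributes `fs`, `times`, `channel_ids`, `n_dropped`.
#' @export
extract_waveforms <- function(session_hp, train, duration_ms = 3.5,
                              pre_frac = 1 / 3) {
  stopifnot(inherits(session_hp, "recording_session"))
  fs <- session_hp$fs
  n <- ncol(session_hp$voltages)
  len <- round(duration_ms / 1000 * fs)
  pre <- round(pre_frac * len)
  samp <- round(train$time_s * fs) + 1L
  ok <- samp - pre >= 1L & samp - pre + len - 1L <= n
  n_dropped <- sum(!ok)
  samp <- samp[ok]
  wf <- array(0, dim = c(length(samp), nrow(session_hp$voltages), len))
  for (k in seq_along(samp)) {
    idx <- (samp[k] - pre):(samp[k] - pre + len - 1L)
    wf[k, , ] <- session_hp$voltages[, idx, drop = FALSE]
  }
  structure(wf, fs = fs, times = (samp - 1) / fs,
            channel_ids = session_hp$channel_ids,
            pre_frac = pre_frac, n_dropped = n_dropped,
            class = "waveform_set")
}

#' Cluster spike waveforms into putative units
#'
#' Principal-component decomposition of channel-concatenated waveforms
#' followed by Gaussian-mixture clustering with BIC model selection over
#' 1..`k_max` components. Every spike is assigned to exactly one cluster;
#' acceptance as a single unit is decided later by [qc_unit()].
#'
#' @param waveforms A `waveform_set`.
#' @param n_pcs Number of principal components to cluster on (default 3).
#' @param k_max Maximum number of mixture components (default 5).
#' @param min_spikes Minimum spikes required to attempt clustering
#'   (default 30); below it a single flagged cluster is returned.
#' @param merge_corr Clusters sharing a peak channel whose mean waveforms
#'   correlate above this and whose peak amplitudes agree within
#'   `merge_amp_ratio` are merged (default 0.9). Mixture fits routinely
#'   oversplit one unit when spike collisions distort a minority of
#'   waveforms; template-similarity merging undoes that.
#' @param merge_amp_ratio Maximum peak-amplitude ratio for a merge
#'   (default 1.5).
#' @return List of `unit_cluster` objects: `unit_id`, `times`,
#'   `mean_waveform` (channels x samples), `peak_channel` (site id),
#'   `pc_weights`, `qc` (empty until [qc_unit()]), `low_n` flag.
#' @importFrom mclust Mclust mclustBIC
#' @export
cluster_units <- function(waveforms, n_pcs = 3, k_max = 5,
                          min_spikes = 30, merge_corr = 0.9,
                          merge_amp_ratio = 1.5) {
  stopifnot(inherits(waveforms, "waveform_set"))
  dm <- dim(waveforms)
  n_spk <- dm[1]; n_ch <- dm[2]; len <- dm[3]
  if (n_spk == 0) return(list())
  flat <- matrix(aperm(unclass(waveforms), c(1, 2, 3)), nrow = n_spk)
  times <- attr(waveforms, "times")
  ch_ids <- attr(waveforms, "channel_ids")
  fs <- attr(waveforms, "fs")

  make_cluster <- function(id, idx, pcw, low_n = FALSE) {
    mw <- apply(unclass(waveforms)[idx, , , drop = FALSE], c(2, 3), mean)
    # peak channel: largest mean trough magnitude
    pk <- which.max(apply(mw, 1, function(r) max(abs(r))))
    structure(list(unit_id = id, times = sort(times[idx]),
                   mean_waveform = mw, peak_channel = ch_ids[pk],
                   channel_ids = ch_ids, fs = fs,
                   pc_weights = pcw, spike_index = idx,
                   qc = list(), accepted = NA, low_n = low_n),
              class = "unit_cluster")
  }

  if (n_spk < min_spikes) {
    pc1 <- stats::prcomp(flat, center = TRUE, rank. = min(n_pcs, n_spk))
    return(list(make_cluster(1L, seq_len(n_spk),
                             pc1$x[, , drop = FALSE], low_n = TRUE)))
  }
  pc <- stats::prcomp(flat, center = TRUE, rank. = n_pcs)
  scores <- pc$x[, seq_len(min(n_pcs, ncol(pc$x))), drop = FALSE]
  fit <- mclust::Mclust(scores, G = seq_len(k_max),
                        modelNames = c("EII", "VII", "VVI", "VVV"),
                        verbose = FALSE)
  cls <- fit$classification
  groups <- lapply(sort(unique(cls)), function(g) which(cls == g))

  # template-similarity merge of oversplit clusters
  repeat {
    if (length(groups) < 2) break
    mw <- lapply(groups, function(idx)
      as.vector(apply(unclass(waveforms)[idx, , , drop = FALSE],
                      c(2, 3), mean)))
    pk_ch <- vapply(mw, function(w) {
      m <- matrix(w, nrow = n_ch)
      which.max(apply(m, 1, function(r) max(abs(r))))
    }, integer(1))
    amp <- vapply(mw, function(w) max(abs(w)), numeric(1))
    best <- NULL; best_cor <- merge_corr
    for (i in seq_along(groups)) {
      for (j in seq_along(groups)) {
        if (j <= i || pk_ch[i] != pk_ch[j]) next
        if (max(amp[i], amp[j]) / min(amp[i], amp[j]) > merge_amp_ratio) next
        cc <- stats::cor(mw[[i]], mw[[j]])
        if (is.finite(cc) && cc > best_cor) {
          best <- c(i, j); best_cor <- cc
        }
      }
    }
    if (is.null(best)) break
    groups[[best[1]]] <- sort(c(groups[[best[1]]], groups[[best[2]]]))
    groups[[best[2]]] <- NULL
  }

  lapply(seq_along(groups), function(g) {
    idx <- groups[[g]]
    make_cluster(as.integer(g), idx, scores[idx, , drop = FALSE])
  })
}

#' @export
print.unit_cluster <- function(x, ...) {
  cat(sprintf("<unit_cluster %d> %d spikes, peak channel %d, accepted: %s\n",
              x$unit_id, length(x$times), x$peak_channel,
              ifelse(is.na(x$accepted), "not yet assessed", x$accepted)))
  invisible(x)
}

#' Four-criterion single-unit quality control
#'
#' A cluster is accepted as a putative single neuron only if all four
#' criteria hold simultaneously:
#' \enumerate{
#'   \item \strong{waveform shape}: the mean waveform on the peak channel
#'     has a dominant negative trough followed by a smaller positive
#'     rebound (asymmetric, biphasic), and individual spikes are
#'     stereotyped (mean spike-to-template correlation >=
#'     `shape_min_corr`);
#'   \item \strong{refractory period}: the fraction of inter-spike
#'     intervals shorter than `refractory_ms` is below
#'     `violation_frac_max`;
#'   \item \strong{spatial localization}: the amplitude is strictly
#'     largest on one channel and falls below 50% of the peak on every
#'     channel farther than `localization_radius` from it (point-source
#'     decay);
#'   \item \strong{separability}: mean silhouette of the cluster's spikes
#'     against the nearest other cluster in PC space is at least
#'     `separability_min` (a lone cluster passes by convention).
#' }
#'
#' @param cluster A `unit_cluster`.
#' @param layout The `electrode_layout` (for inter-channel distances).
#' @param all_clusters Optional list of all clusters from the same
#'   [cluster_units()] call (for the separability criterion).
#' @param refractory_ms Refractory period, milliseconds (default 2).
#' @param violation_frac_max Tolerated ISI-violation fraction
#'   (default 0.01).
#' @param localization_radius Radius beyond which amplitude must have
#'   decayed below half, micrometers (default 100).
#' @param separability_min Minimum mean silhouette (default 0.2).
#' @param shape_min_corr Minimum mean spike-to-template correlation on the
#'   peak channel (default 0.6).
#' @param waveforms The `waveform_set` the clusters were built from
#'   (needed for the stereotypy check; skipped if missing).
#' @return The cluster with `qc` flags (`waveform_shape`, `refractory`,
#'   `spatial`, `separability`) and `accepted` filled in.
#' @export
qc_unit <- function(cluster, layout, all_clusters = NULL,
                    refractory_ms = 2, violation_frac_max = 0.01,
                    localization_radius = 100, separability_min = 0.2,
                    shape_min_corr = 0.6, waveforms = NULL) {
  stopifnot(inherits(cluster, "unit_cluster"))
  mw <- cluster$mean_waveform
  pk_row <- match(cluster$peak_channel, cluster$channel_ids)
  w <- mw[pk_row, ]

  # (1) shape: dominant negative trough, positive rebound after it,
  # asymmetry, and stereotyped individual spikes
  i_tr <- which.min(w)
  trough <- w[i_tr]
  post_peak <- if (i_tr < length(w)) max(w[(i_tr + 1):length(w)]) else -Inf
  shape_ok <- is.finite(trough) && trough < 0 && post_peak > 0 &&
    abs(trough) > 1.2 * abs(post_peak) &&
    abs(trough) == max(abs(w))
  if (shape_ok && !is.null(waveforms)) {
    spikes_pk <- unclass(waveforms)[cluster$spike_index, pk_row, ,
                                    drop = FALSE]
    spikes_pk <- matrix(spikes_pk, nrow = length(cluster$spike_index))
    cors <- suppressWarnings(apply(spikes_pk, 1, stats::cor, y = w))
    shape_ok <- mean(cors, na.rm = TRUE) >= shape_min_corr
  }

  # (2) refractory period
  isi <- diff(cluster$times)
  refr_ok <- if (length(isi) == 0) TRUE else
    mean(isi < refractory_ms / 1000) <= violation_frac_max

  # (3) spatial localization
  amps <- apply(mw, 1, function(r) abs(min(r)))
  pk_amp <- amps[pk_row]
  strictly_largest <- all(amps[-pk_row] < pk_amp)
  d <- site_distance(layout, rep(cluster$peak_channel, length(amps)),
                     cluster$channel_ids)
  far <- d > localization_radius
  decay_ok <- !any(far) || all(amps[far] < 0.5 * pk_amp)
  spatial_ok <- pk_amp > 0 && strictly_largest && decay_ok

  # (4) separability in PC space
  sep_ok <- TRUE
  if (!is.null(all_clusters) && length(all_clusters) > 1) {
    sil <- cluster_silhouette(cluster, all_clusters)
    sep_ok <- sil >= separability_min
  }

  cluster$qc <- list(waveform_shape = shape_ok, refractory = refr_ok,
                     spatial = spatial_ok, separability = sep_ok)
  cluster$accepted <- shape_ok && refr_ok && spatial_ok && sep_ok
  cluster
}

#' Mean silhouette of one cluster against its nearest neighbour cluster
#' @noRd
cluster_silhouette <- function(cluster, all_clusters) {
  own <- cluster$pc_weights
  others <- all_clusters[vapply(all_clusters, function(cl)
    cl$unit_id != cluster$unit_id, logical(1))]
  if (length(others) == 0) return(1)
  cen_own <- colMeans(own)
  a <- sqrt(rowSums(sweep(own, 2, cen_own)^2))
  b <- Reduce(pmin, lapply(others, function(cl) {
    cen <- colMeans(cl$pc_weights)
    sqrt(rowSums(sweep(own, 2, cen)^2))
  }))
  mean((b - a) / pmax(a, b))
}

#' Sort a session end to end
#'
#' Convenience pipeline: 300-2000 Hz band-pass per channel, per-channel
#' noise floor and spike detection, array-wide coincidence rejection,
#' waveform extraction around the per-event peak channel trough,
#' clustering and four-criterion QC.
#'
#' @param session A raw `recording_session` with a layout.
#' @param multiplier Detection threshold multiple (default 5).
#' @param artifact_epochs_table Artifact epochs to exclude from the noise
#'   floor (default none).
#' @param refractory_ms,violation_frac_max,localization_radius,
#'   separability_min Passed to [qc_unit()].
#' @param n_pcs,k_max,min_spikes Passed to [cluster_units()].
#' @return List with `clusters` (all clusters, QC-flagged), `accepted`
#'   (the accepted subset), `trains` (post-rejection per-channel spike
#'   trains), `floors` (per-channel noise floors).
#' @export
sort_units <- function(session, multiplier = 5,
                       artifact_epochs_table = artifact_epochs(),
                       refractory_ms = 2, violation_frac_max = 0.01,
                       localization_radius = 100, separability_min = 0.2,
                       n_pcs = 3, k_max = 5, min_spikes = 30) {
  stopifnot(inherits(session, "recording_session"))
  fs <- session$fs
  hi_cut <- min(2000, 0.45 * fs)
  hp <- session
  for (ch in seq_len(nrow(hp$voltages))) {
    hp$voltages[ch, ] <- butterworth_filter(hp$voltages[ch, ], fs,
                                            "bandpass", c(300, hi_cut))
  }
  floors <- vector("list", nrow(hp$voltages))
  trains <- vector("list", nrow(hp$voltages))
  for (ch in seq_len(nrow(hp$voltages))) {
    floors[[ch]] <- noise_floor(hp$voltages[ch, ], fs,
                                artifact_epochs_table)
    trains[[ch]] <- detect_spikes(hp$voltages[ch, ], fs, floors[[ch]],
                                  multiplier)
  }
  trains <- reject_coincident(trains)
  # merge per-channel detections into distinct events (0.5 ms resolution)
  all_t <- sort(unlist(lapply(trains, function(tr) tr$time_s)))
  if (length(all_t) > 0) {
    merged <- all_t[c(TRUE, diff(all_t) > 0.0005)]
  } else {
    merged <- numeric()
  }
  ev_train <- structure(data.frame(time_s = merged,
                                   amplitude = rep(NA_real_,
                                                   length(merged))),
                        fs = fs, class = c("spike_train", "data.frame"))
  wf <- extract_waveforms(hp, ev_train)
  clusters <- cluster_units(wf, n_pcs = n_pcs, k_max = k_max,
                            min_spikes = min_spikes)
  clusters <- lapply(clusters, qc_unit, layout = session$layout,
                     all_clusters = clusters,
                     refractory_ms = refractory_ms,
                     violation_frac_max = violation_frac_max,
                     localization_radius = localization_radius,
                     separability_min = separability_min,
                     waveforms = wf)
  accepted <- Filter(function(cl) isTRUE(cl$accepted) && !isTRUE(cl$low_n),
                     clusters)
  list(clusters = clusters, accepted = accepted, trains = trains,
       floors = floors)
}

#' Spike-train correlogram with shuffle confidence intervals
#'
#' Histogram of spike-time differences within `span_ms`, binned at
#' `bin_ms`. Auto-correlograms (b missing) exclude self-pairs and are
#' symmetric about zero. Per-bin 95% confidence intervals come from
#' surrogates in which one train's spikes are re-assigned to permuted time
#' bins of width `bin_ms` (destroying fine temporal structure while
#' preserving the marginal rate), repeated `n_shuffles` times.
#'
#' @param train_a A `spike_train` (or numeric times vector).
#' @param train_b Optional second train for a cross-correlogram.
#' @param bin_ms Lag bin width, milliseconds (default 1).
#' @param span_ms Maximum |lag|, milliseconds (default 50).
#' @param n_shuffles Number of shuffle surrogates (default 1000).
#' @param seed Seed for the shuffles (default 1).
#' @param duration Session duration in seconds (default: max spike time).
#' @return Object of class `correlogram`: data.frame `lag_ms` (bin
#'   centers), `count`, `ci_low`, `ci_high`, with attribute `kind`.
#' @export
correlogram <- function(train_a, train_b = NULL, bin_ms = 1, span_ms = 50,
                        n_shuffles = 1000, seed = 1, duration = NULL) {
  ta <- if (inherits(train_a, "spike_train")) train_a$time_s else
    as.numeric(train_a)
  auto <- is.null(train_b)
  tb <- if (auto) ta else
    if (inherits(train_b, "spike_train")) train_b$time_s else
      as.numeric(train_b)
  if (length(ta) == 0 || length(tb) == 0) stop("empty spike train")
  if (is.null(duration)) duration <- max(ta, tb)
  span <- span_ms / 1000
  breaks <- seq(-span_ms, span_ms, by = bin_ms)
  centers <- (breaks[-1] + breaks[-length(breaks)]) / 2

  count_lags <- function(a, b, exclude_self) {
    b <- sort(b)
    counts <- numeric(length(centers))
    lo <- findInterval(a - span, b)
    hi <- findInterval(a + span, b)
    for (i in seq_along(a)) {
      if (hi[i] <= lo[i]) next
      lags <- (b[(lo[i] + 1):hi[i]] - a[i]) * 1000
      if (exclude_self) lags <- lags[lags != 0]
      if (length(lags)) {
        k <- floor((lags + span_ms) / bin_ms) + 1
        k <- k[k >= 1 & k <= length(centers)]
        for (kk in k) counts[kk] <- counts[kk] + 1
      }
    }
    counts
  }
  counts <- count_lags(ta, tb, exclude_self = auto)

  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  n_bins_session <- max(1L, ceiling(duration * 1000 / bin_ms))
  offs <- tb - floor(tb * 1000 / bin_ms) * bin_ms / 1000
  bin_of <- floor(tb * 1000 / bin_ms)
  sh_counts <- matrix(0, nrow = n_shuffles, ncol = length(centers))
  for (s in seq_len(n_shuffles)) {
    perm <- sample.int(n_bins_session, length(unique(bin_of)),
                       replace = FALSE)
    new_bin <- perm[match(bin_of, unique(bin_of))]
    tb_sh <- (new_bin - 1) * bin_ms / 1000 + offs
    sh_counts[s, ] <- count_lags(ta, tb_sh, exclude_self = FALSE)
  }
  ci <- apply(sh_counts, 2, stats::quantile, probs = c(0.025, 0.975))

  structure(data.frame(lag_ms = centers, count = counts,
                       ci_low = ci[1, ], ci_high = ci[2, ]),
            kind = if (auto) "auto" else "cross",
            bin_ms = bin_ms, span_ms = span_ms,
            class = c("correlogram", "data.frame"))
}
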
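#' Stereotyped extracellular spike template
#'
#' A biphasic action-potential waveform with a dominant negative trough
#' (the extracellular signature of a nearby soma) followed by a smaller
#' positive overshoot, supported on `duration_ms` and aligned so the trough
#' sits at `pre_frac` of the snippet. Peak value is exactly `peak_uv`
#' (negative).
#'
#' @param fs Sampling rate, Hz.
#' @param duration_ms Support, milliseconds (default 3.5).
#' @param peak_uv Trough amplitude, microvolts (negative; default -1 for a
#'   unit-amplitude template).
#' @param pre_frac Fraction of the snippet before the trough (default 1/3).
#' @return Numeric vector of `round(duration_ms/1000*fs)` samples.
#' @export
spike_template <- function(fs, duration_ms = 3.5, peak_uv = -1,
                           pre_frac = 1 / 3) {
  if (peak_uv >= 0) stop("template peak must be negative")
  n <- round(duration_ms / 1000 * fs)
  t <- (seq_len(n) - 1) / fs * 1000  # ms
  t0 <- duration_ms * pre_frac
  w <- -exp(-((t - t0)^2) / (2 * 0.25^2)) +
    0.35 * exp(-((t - t0 - 0.55)^2) / (2 * 0.45^2)) -
    0.08 * exp(-((t - t0 + 0.5)^2) / (2 * 0.35^2))
  # renormalize so the sampled trough is exactly peak_uv and sits on-grid
  i_tr <- which.min(w)
  w <- w / abs(w[i_tr]) * abs(peak_uv)
  shift <- round(t0 / 1000 * fs) + 1L - i_tr
  if (shift != 0) {
    w <- if (shift > 0) c(numeric(shift), w[seq_len(n - shift)]) else
      c(w[(1 - shift):n], numeric(-shift))
  }
  w
}

#' Specify a synthetic single unit
#'
#' @param peak_site `site_id` where the unit's spike is largest.
#' @param peak_uv Trough amplitude on the peak site, microvolts (negative).
#' @param decay_um Exponential spatial decay length of the amplitude across
#'   the array, micrometers (default 30: tetrode-mates at 50 um see ~19% of
#'   the peak, consistent with tight single-cell localization).
#' @param mean_rate Mean firing rate, Hz.
#' @param refractory_ms Absolute refractory period, milliseconds
#'   (default 2).
#' @param rate_schedule Optional data.frame `t_start` (s), `multiplier`
#'   giving a piecewise-constant rate modulation (e.g. a feeding step).
#' @param template Optional custom waveform (negative trough); defaults to
#'   [spike_template()] scaled to `peak_uv`.
#' @return A list of class `unit_spec`.
#' @export
unit_spec <- function(peak_site, peak_uv = -80, decay_um = 30,
                      mean_rate = 5, refractory_ms = 2,
                      rate_schedule = NULL, template = NULL) {
  if (peak_uv >= 0) stop("`peak_uv` must be negative")
  if (refractory_ms <= 0) stop("`refractory_ms` must be positive")
  if (mean_rate < 0) stop("`mean_rate` must be non-negative")
  structure(list(peak_site = peak_site, peak_uv = peak_uv,
                 decay_um = decay_um, mean_rate = mean_rate,
                 refractory_ms = refractory_ms,
                 rate_schedule = rate_schedule, template = template),
            class = "unit_spec")
}

#' Specify a background oscillation
#'
#' A sinusoid shared across all channels, standing in for gut rhythms:
#' slow waves of interstitial cells of Cajal (< 0.2 Hz), circular smooth
#' muscle (0.2-1 Hz), faster smooth muscle (1-5 Hz), and so on.
#'
#' @param freq Center frequency, Hz.
#' @param amplitude_uv Amplitude, microvolts.
#' @param phase Phase, radians.
#' @return A list of class `oscillation_spec` with the band label attached.
#' @export
oscillation_spec <- function(freq, amplitude_uv, phase = 0) {
  bands <- gut_bands()
  i <- which(freq >= bands$lo & freq < bands$hi)
  if (length(i) != 1) stop("oscillation frequency outside the 0-2000 Hz bands")
  structure(list(freq = freq, amplitude_uv = amplitude_uv, phase = phase,
                 band = bands$label[i]),
            class = "oscillation_spec")
}

#' Specify synchronized EMG-like burst contamination
#'
#' Band-limited (5-300 Hz) noise bursts with a tapered envelope, added with
#' identical waveform to every channel -- the synchronized high-amplitude
#' contamination that artifact detection must find and exclude.
#'
#' @param times Burst onset times, seconds.
#' @param duration_s Burst duration, seconds (default 2).
#' @param amplitude_uv Burst RMS amplitude, microvolts (default 200).
#' @return A list of class `burst_spec`.
#' @export
burst_spec <- function(times, duration_s = 2, amplitude_uv = 200) {
  structure(list(times = times, duration_s = duration_s,
                 amplitude_uv = amplitude_uv),
            class = "burst_spec")
}

#' Specify an evoked event for the simulator
#'
#' After `delay_s`, a stimulation event adds (i) a broadband burst confined
#' to > 300 Hz content lasting `hf_duration_s` (asynchronous neural firing)
#' and (ii) a slow positive deflection confined to < 300 Hz lasting
#' `lf_duration_s` (neuromuscular response). Saline washes have both
#' amplitudes forced to zero. Repeated drug additions are attenuated by
#' `desens_factor^(repeat_index - 1)`.
#'
#' @param kind `"distension"`, `"drug"`, `"saline"`, `"contraction"`,
#'   `"feeding_onset"` or `"session_start"`.
#' @param time_s Event time, seconds.
#' @param amplitude_uv Response amplitude scale, microvolts.
#' @param delay_s Response latency, seconds (default 0.5).
#' @param hf_duration_s High-frequency burst duration, seconds (default 2).
#' @param lf_duration_s Low-frequency deflection duration, seconds
#'   (default 5).
#' @param desens_factor Per-repeat multiplicative attenuation (default 1).
#' @param repeat_index 1-based repeat counter (default 1).
#' @param route Administration route label (default "none").
#' @return A one-row data.frame of class `event_spec`.
#' @export
event_spec <- function(kind, time_s, amplitude_uv = 100, delay_s = 0.5,
                       hf_duration_s = 2, lf_duration_s = 5,
                       desens_factor = 1, repeat_index = 1L,
                       route = "none") {
  df <- data.frame(kind = kind, time_s = time_s,
                   amplitude_uv = amplitude_uv, delay_s = delay_s,
                   hf_duration_s = hf_duration_s,
                   lf_duration_s = lf_duration_s,
                   desens_factor = desens_factor,
                   repeat_index = as.integer(repeat_index),
                   route = route, stringsAsFactors = FALSE)
  class(df) <- c("event_spec", "data.frame")
  df
}

#' Assemble a synthetic recording configuration
#'
#' @param layout An `electrode_layout` (default: the standard 7-tetrode
#'   array).
#' @param fs Sampling rate, Hz (default 30000).
#' @param duration Session duration, seconds.
#' @param units List of [unit_spec()]s.
#' @param background List of [oscillation_spec()]s.
#' @param emg Optional [burst_spec()].
#' @param line_amp_uv Mains interference amplitude at 50 Hz, microvolts
#'   (default 0); odd harmonics 150/250/350 Hz are added at amplitudes
#'   falling off as 1/harmonic-order.
#' @param line_base Mains base frequency, Hz (default 50).
#' @param events Optional `event_spec` rows (rbind-ed).
#' @param noise_sd Per-channel Gaussian noise SD, microvolts (default 10).
#' @param seed Integer root seed; fixes every random component.
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(layout = build_tetrode_layout(), fs = 30000,
                             duration = 60, units = list(),
                             background = list(), emg = NULL,
                             line_amp_uv = 0, line_base = 50,
                             events = NULL, noise_sd = 10, seed = 1) {
  if (duration <= 0) stop("`duration` must be positive")
  top <- c(vapply(background, function(o) o$freq, numeric(1)),
           if (!is.null(emg)) 300,
           if (line_amp_uv > 0) line_base * 7, 0)
  if (fs <= 2 * max(top)) {
    stop("`fs` must exceed twice the highest generated frequency")
  }
  if (!is.null(events)) {
    if (any(events$time_s < 0 | events$time_s > duration)) {
      stop("event times must lie within [0, duration]")
    }
  }
  structure(list(layout = layout, fs = fs, duration = duration,
                 units = units, background = background, emg = emg,
                 line_amp_uv = line_amp_uv, line_base = line_base,
                 events = events, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

#' Poisson spike times with dead-time thinning
#'
#' Homogeneous Poisson process at `rate` modulated by a piecewise-constant
#' schedule, with every spike closer than `refractory_ms` to its
#' predecessor removed (dead time).
#' @noRd
generate_spike_times <- function(rate, duration, refractory_ms,
                                 rate_schedule = NULL) {
  if (rate <= 0 || duration <= 0) return(numeric())
  mult_at <- function(t) {
    if (is.null(rate_schedule) || nrow(rate_schedule) == 0) {
      return(rep(1, length(t)))
    }
    sched <- rate_schedule[order(rate_schedule$t_start), , drop = FALSE]
    idx <- findInterval(t, sched$t_start)
    out <- rep(1, length(t))
    out[idx > 0] <- sched$multiplier[idx[idx > 0]]
    out
  }
  max_mult <- if (is.null(rate_schedule)) 1 else
    max(1, rate_schedule$multiplier)
  n_exp <- stats::rpois(1, rate * max_mult * duration)
  t_cand <- sort(stats::runif(n_exp, 0, duration))
  # thin to the local rate
  keep <- stats::runif(n_exp) < mult_at(t_cand) / max_mult
  t_cand <- t_cand[keep]
  # dead time: iteratively drop spikes following their predecessor too
  # closely (chains are over-pruned, a negligible rate deficit of order
  # (rate * refractory)^2)
  refr <- refractory_ms / 1000
  while (length(t_cand) > 1) {
    bad <- which(diff(t_cand) < refr) + 1L
    if (length(bad) == 0) break
    t_cand <- t_cand[-bad]
  }
  t_cand
}

#' Simulate a multi-channel session with known ground truth
#'
#' Generates `voltages = sum(spike trains convolved with spatially scaled
#' templates) + oscillations + EMG bursts + mains interference + Gaussian
#' noise + evoked event responses` on every recording site of the layout.
#' Spikes are inserted additively at sample resolution, so the ground truth
#' is exactly recoverable; inter-spike intervals respect each unit's
#' refractory period by construction. Output is bit-reproducible for a
#' fixed config seed.
#'
#' @param config A [synthetic_config()].
#' @return List with elements `session` (a `recording_session`) and
#'   `truth` (class `synthetic_ground_truth`): per-unit spike times and
#'   per-channel template amplitudes, oscillation specs, EMG epochs, event
#'   response windows, and the noise SD.
#' @export
simulate_session <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(config$seed)
  sub_seeds <- sample.int(.Machine$integer.max - 1L,
                          4L + length(config$units) +
                            max(0L, NROW(config$events)))

  rec <- config$layout[config$layout$role == "recording", , drop = FALSE]
  n_ch <- nrow(rec)
  n <- round(config$duration * config$fs)
  tt <- (seq_len(n) - 1) / config$fs

  v <- matrix(0, nrow = n_ch, ncol = n)

  # Gaussian sensor noise, independent per channel
  if (config$noise_sd > 0) {
    set.seed(sub_seeds[1])
    for (ch in seq_len(n_ch)) {
      v[ch, ] <- v[ch, ] + stats::rnorm(n, 0, config$noise_sd)
    }
  }

  # shared background oscillations (row-wise to avoid full-matrix copies)
  for (osc in config$background) {
    if (osc$amplitude_uv == 0) next
    wave <- osc$amplitude_uv * sin(2 * pi * osc$freq * tt + osc$phase)
    for (ch in seq_len(n_ch)) v[ch, ] <- v[ch, ] + wave
  }

  # mains interference: base + odd harmonics, amplitude ~ 1/order
  if (config$line_amp_uv > 0) {
    ords <- c(1, 3, 5, 7)
    freqs <- config$line_base * ords
    freqs <- freqs[freqs < config$fs / 2]
    wave <- numeric(n)
    for (i in seq_along(freqs)) {
      wave <- wave + (config$line_amp_uv / ords[i]) *
        sin(2 * pi * freqs[i] * tt)
    }
    for (ch in seq_len(n_ch)) v[ch, ] <- v[ch, ] + wave
  }

  # spikes
  spike_times <- list()
  unit_site_amps <- list()
  for (u in seq_along(config$units)) {
    us <- config$units[[u]]
    set.seed(sub_seeds[4L + u])
    st <- generate_spike_times(us$mean_rate, config$duration,
                               us$refractory_ms, us$rate_schedule)
    tmpl <- if (is.null(us$template)) {
      spike_template(config$fs, peak_uv = -1) * abs(us$peak_uv)
    } else {
      us$template
    }
    lt <- length(tmpl)
    pre <- round(lt / 3)
    d <- site_distance(config$layout, rep(us$peak_site, n_ch), rec$site_id)
    amp_scale <- exp(-d / us$decay_um)
    amp_scale[amp_scale < 0.005] <- 0
    # snap to the sample grid; drop spikes clipped by the session edges
    samp <- round(st * config$fs) + 1L
    ok <- samp - pre >= 1L & samp - pre + lt - 1L <= n
    samp <- samp[ok]
    for (ch in which(amp_scale > 0)) {
      sc <- amp_scale[ch]
      for (s in samp) {
        idx <- (s - pre):(s - pre + lt - 1L)
        v[ch, idx] <- v[ch, idx] + tmpl * sc
      }
    }
    spike_times[[u]] <- (samp - 1L) / config$fs
    unit_site_amps[[u]] <- data.frame(site_id = rec$site_id,
                                      amp = abs(us$peak_uv) * amp_scale)
  }

  # synchronized EMG bursts
  emg_epochs <- artifact_epochs()
  if (!is.null(config$emg) && length(config$emg$times) > 0 &&
      config$emg$amplitude_uv > 0) {
    set.seed(sub_seeds[2])
    dur <- config$emg$duration_s
    nb <- round(dur * config$fs)
    for (t0 in config$emg$times) {
      s0 <- round(t0 * config$fs) + 1L
      if (s0 + nb - 1L > n) next
      raw <- stats::rnorm(nb)
      bp <- butterworth_filter(raw, config$fs, "bandpass", c(5, 300))
      env <- tukey_window(nb, 0.2)
      burst <- bp / stats::sd(bp) * config$emg$amplitude_uv * env
      idx <- s0:(s0 + nb - 1L)
      v[, idx] <- sweep(v[, idx, drop = FALSE], 2, burst, "+")
    }
    emg_epochs <- artifact_epochs(config$emg$times,
                                  config$emg$times + dur, "emg")
  }

  events <- event_log()
  session <- recording_session(v, fs = config$fs,
                               channel_ids = rec$site_id,
                               layout = config$layout, events = events)

  event_windows <- NULL
  if (!is.null(config$events) && nrow(config$events) > 0) {
    for (i in seq_len(nrow(config$events))) {
      ev <- config$events[i, , drop = FALSE]
      session <- inject_evoked_response(session, ev,
                                        seed = sub_seeds[4L + length(config$units) + i])
    }
    ew <- config$events
    ew$response_start <- ew$time_s + ew$delay_s
    ew$hf_end <- ew$response_start + ew$hf_duration_s
    ew$lf_end <- ew$response_start + ew$lf_duration_s
    ew$effective_amplitude <- ifelse(ew$kind == "saline", 0,
      ew$amplitude_uv * ew$desens_factor^(ew$repeat_index - 1L))
    event_windows <- ew
  }

  truth <- structure(
    list(spike_times = spike_times, unit_site_amps = unit_site_amps,
         units = config$units, oscillations = config$background,
         emg_epochs = emg_epochs, event_windows = event_windows,
         noise_sd = config$noise_sd, seed = config$seed),
    class = "synthetic_ground_truth"
  )
  list(session = session, truth = truth)
}

#' White noise with an exactly flat spectrum
#'
#' Inverse FFT of a unit-magnitude, random-phase spectrum: every
#' periodogram bin of the returned block has the same magnitude, so
#' band-integrated powers are deterministic up to windowing leakage.
#' @noRd
flat_spectrum_noise <- function(n) {
  n_half <- floor(n / 2)
  phases <- stats::runif(n_half - 1, 0, 2 * pi)
  X <- complex(modulus = 0, argument = 0) * numeric(n)
  X[2:n_half] <- complex(modulus = 1, argument = phases)
  if (n %% 2 == 0) {
    X[n_half + 1] <- complex(modulus = 1, argument = 0)
    X[(n_half + 2):n] <- Conj(X[n_half:2])
  } else {
    X[n_half + 1] <- complex(modulus = 1, argument = stats::runif(1, 0, 2 * pi))
    X[(n_half + 2):n] <- Conj(X[(n_half + 1):2])
  }
  Re(stats::fft(X, inverse = TRUE)) / sqrt(n)
}

#' Tukey (tapered cosine) window
#' @noRd
tukey_window <- function(n, alpha = 0.2) {
  if (n == 1) return(1)
  x <- seq(0, 1, length.out = n)
  w <- rep(1, n)
  lo <- x < alpha / 2
  hi <- x > 1 - alpha / 2
  w[lo] <- 0.5 * (1 + cos(pi * (2 * x[lo] / alpha - 1)))
  w[hi] <- 0.5 * (1 + cos(pi * (2 * (1 - x[hi]) / alpha - 1)))
  w
}

#' Inject a two-component evoked response into a session
#'
#' Adds, starting `delay_s` after the event time, a high-frequency
#' (> 300 Hz) tapered noise burst of `hf_duration_s` and a low-frequency
#' (< 300 Hz) positive half-sine deflection of `lf_duration_s`, both scaled
#' by `amplitude_uv * desens_factor^(repeat_index - 1)` and applied
#' identically to all channels. Saline events add nothing. The event is
#' appended to the session's event log.
#'
#' @param session A `recording_session`.
#' @param event A one-row [event_spec()].
#' @param seed Seed for the burst noise (default 1).
#' @return The session with the response added.
#' @export
inject_evoked_response <- function(session, event, seed = 1) {
  stopifnot(inherits(session, "recording_session"))
  ev <- as.list(event[1, ])
  fs <- session$fs
  n <- ncol(session$voltages)
  t_resp <- ev$time_s + ev$delay_s
  t_end <- t_resp + max(ev$hf_duration_s, ev$lf_duration_s)
  if (t_end > n / fs) stop("evoked response extends past the session end")
  amp <- if (identical(ev$kind, "saline")) 0 else
    ev$amplitude_uv * ev$desens_factor^(ev$repeat_index - 1L)

  if (amp > 0) {
    s0 <- round(t_resp * fs) + 1L
    # high-frequency asynchronous burst, confined to > 300 Hz
    nb <- round(ev$hf_duration_s * fs)
    if (nb > 8) {
      old <- if (exists(".Random.seed", globalenv()))
        get(".Random.seed", globalenv()) else NULL
      set.seed(seed)
      raw <- stats::rnorm(nb + 2 * fs)
      if (!is.null(old)) assign(".Random.seed", old, globalenv())
      hi_cut <- min(2000, fs / 2 * 0.9)
      bp <- butterworth_filter(raw, fs, "bandpass", c(300, hi_cut))
      bp <- bp[(fs + 1):(fs + nb)]  # discard filter warm-up
      burst <- bp / stats::sd(bp) * amp * tukey_window(nb, 0.2)
      idx <- s0:(s0 + nb - 1L)
      session$voltages[, idx] <- sweep(session$voltages[, idx, drop = FALSE],
                                       2, burst, "+")
    }
    # low-frequency positive deflection, confined to < 300 Hz
    nl <- round(ev$lf_duration_s * fs)
    if (nl > 8) {
      defl <- amp * sin(pi * seq(0, 1, length.out = nl))
      idx <- s0:(s0 + nl - 1L)
      session$voltages[, idx] <- sweep(session$voltages[, idx, drop = FALSE],
                                       2, defl, "+")
    }
  }

  add <- event_log(ev$time_s, ev$kind, ev$route, ev$repeat_index, "")
  session$events <- validate_event_log(
    rbind(as.data.frame(session$events), as.data.frame(add)),
    duration = n / fs)
  session
}

#' Simulate a chronic behavioral session
#'
#' A session built like [simulate_session()] in which (i) every unit's
#' firing rate is multiplied by `feeding_multiplier` from `feeding_time`
#' onward (units with their own `rate_schedule` keep it), and (ii) a
#' broadband "stress" noise component starts at power
#' `stress_sd^2 * day_attenuation` and decays as `exp(-t / stress_decay_tau)`
#' from session start -- the novel-environment arousal that fades within
#' minutes and attenuates over days.
#'
#' @param config A [synthetic_config()].
#' @param feeding_time Feeding onset, seconds from session start.
#' @param stress_decay_tau Stress power decay time constant, seconds
#'   (default 300).
#' @param day_attenuation Multiplier on the stress component for the
#'   simulated day (1 = day one; 0 disables it, giving flat background
#'   power).
#' @param feeding_multiplier Rate step applied to all units at
#'   `feeding_time` (default 2).
#' @param stress_sd Initial stress component SD, microvolts (default 30).
#' @param render_voltage If FALSE, skip voltage synthesis and return only
#'   the ground truth (fast path for rate-level studies).
#' @return List with `session` (NULL when `render_voltage = FALSE`) and
#'   `truth`; the truth gains `feeding_time`, `stress_tau`,
#'   `stress_power_per_minute` and per-unit pre/post rates.
#' @export
simulate_behavior_session <- function(config, feeding_time,
                                      stress_decay_tau = 300,
                                      day_attenuation = 1,
                                      feeding_multiplier = 2,
                                      stress_sd = 30,
                                      render_voltage = TRUE) {
  stopifnot(inherits(config, "synthetic_config"))
  if (feeding_time < 0 || feeding_time > config$duration) {
    stop("`feeding_time` must lie inside the session")
  }
  if (stress_decay_tau <= 0) stop("`stress_decay_tau` must be positive")
  config$units <- lapply(config$units, function(us) {
    if (is.null(us$rate_schedule)) {
      us$rate_schedule <- data.frame(t_start = c(0, feeding_time),
                                     multiplier = c(1, feeding_multiplier))
    }
    us
  })

  if (!render_voltage) {
    old <- if (exists(".Random.seed", globalenv()))
      get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(config$seed)
    sub_seeds <- sample.int(.Machine$integer.max - 1L,
                            4L + length(config$units))
    spike_times <- vector("list", length(config$units))
    for (u in seq_along(config$units)) {
      us <- config$units[[u]]
      set.seed(sub_seeds[4L + u])
      spike_times[[u]] <- generate_spike_times(us$mean_rate,
                                               config$duration,
                                               us$refractory_ms,
                                               us$rate_schedule)
    }
    truth <- structure(
      list(spike_times = spike_times, units = config$units,
           feeding_time = feeding_time, stress_tau = stress_decay_tau,
           day_attenuation = day_attenuation, seed = config$seed),
      class = "synthetic_ground_truth")
    return(list(session = NULL, truth = truth))
  }

  out <- simulate_session(config)

  # Decaying broadband stress component. Each channel gets a frozen-phase
  # flat-spectrum waveform (phases drawn once per channel from the config
  # seed), tiled minute by minute under the decay envelope: the waveform
  # repeats, so the injected per-minute band power is exactly the
  # deterministic envelope schedule -- the ground truth is exact rather
  # than itself a noisy estimate.
  stress_power_min <- NULL
  if (day_attenuation > 0 && stress_sd > 0) {
    fs <- config$fs
    n <- ncol(out$session$voltages)
    tt <- (seq_len(n) - 1) / fs
    env <- sqrt(day_attenuation) * exp(-tt / (2 * stress_decay_tau))
    old <- if (exists(".Random.seed", globalenv()))
      get(".Random.seed", globalenv()) else NULL
    set.seed(config$seed %% 1000000L + 10000L)
    L <- min(n, round(60 * fs))
    n_rep <- ceiling(n / L)
    for (ch in seq_len(nrow(out$session$voltages))) {
      w <- flat_spectrum_noise(L)
      w <- w / stats::sd(w)
      noise <- rep(w, n_rep)[seq_len(n)]
      out$session$voltages[ch, ] <- out$session$voltages[ch, ] +
        stress_sd * noise * env
    }
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
    n_min <- floor(config$duration / 60)
    if (n_min > 0) {
      stress_power_min <- vapply(seq_len(n_min), function(m) {
        idx <- tt >= (m - 1) * 60 & tt < m * 60
        stress_sd^2 * mean(env[idx]^2)
      }, numeric(1))
    }
  }

  fe <- event_log(feeding_time, "feeding_onset")
  out$session$events <- validate_event_log(
    rbind(as.data.frame(out$session$events), as.data.frame(fe)),
    duration = session_duration(out$session))
  out$truth$feeding_time <- feeding_time
  out$truth$stress_tau <- stress_decay_tau
  out$truth$day_attenuation <- day_attenuation
  out$truth$stress_power_per_minute <- stress_power_min
  out
}
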
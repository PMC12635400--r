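test_that("noise floor matches Gaussian calibration and epoch selection rules", {
  expect_equal(noise_floor(numeric(1000), 1000)$floor, 0)
  set.seed(15)
  x <- rnorm(2e5, sd = 4)
  fl <- noise_floor(x, 10000)
  expect_equal(fl$floor, 4 * sqrt(2 / pi) / 0.6745, tolerance = 0.02)
  flm <- noise_floor(x, 10000, robust = "median")
  expect_equal(flm$floor, 4, tolerance = 0.02)
  # scale equivariance
  fl2 <- noise_floor(3 * x, 10000)
  expect_equal(fl2$floor, 3 * fl$floor, tolerance = 1e-12)

  # 6 free epochs of lengths 1..6 s: the 5 longest (2..6 s) are used
  art <- artifact_epochs(c(1, 4, 8, 13, 19), c(2, 5, 9, 14, 20), "manual")
  y <- rnorm(26 * 1000)
  nf <- noise_floor(y, 1000, art)
  expect_equal(nrow(nf$epochs_used), 5)
  expect_setequal(round(nf$epochs_used$end_s - nf$epochs_used$start_s),
                  2:6)
  expect_error(noise_floor(y, 1000, artifact_epochs(0, 26, "manual")),
               "no artifact-free")
})

test_that("detection is rare on pure noise and monotone in the multiplier", {
  set.seed(16)
  fs <- 30000
  x <- butterworth_filter(rnorm(fs * 20), fs, "bandpass", c(300, 2000))
  fl <- noise_floor(x, fs)
  tr5 <- detect_spikes(x, fs, fl, 5)
  expect_lt(nrow(tr5) / 20, 0.1)  # < 0.1 events/s at 5x threshold
  tr4 <- detect_spikes(x, fs, fl, 4)
  tr6 <- detect_spikes(x, fs, fl, 6)
  expect_gte(nrow(tr4), nrow(tr5))
  expect_gte(nrow(tr5), nrow(tr6))
  expect_warning(detect_spikes(x, fs, fl, 7), "outside")
  expect_spike_train_valid(tr4)
})

test_that("a sub-millisecond excursion yields exactly one spike", {
  fs <- 30000
  x <- numeric(fs)
  idx <- 1000:1009  # 0.33 ms below threshold
  x[idx] <- -50 - sin(seq(0, pi, length.out = 10)) * 20
  tr <- detect_spikes(x, fs, floor = 5, multiplier = 5)
  expect_equal(nrow(tr), 1)
  expect_equal(tr$time_s, (1000 + which.min(x[idx]) - 2) / fs,
               tolerance = 1e-6)
})

test_that("detection recovers injected spikes at high SNR", {
  # band-passed trough ~ -22 uV over a ~1.9 uV floor: the ~10x-floor
  # regime the detector is specified for
  u <- unit_spec(1, peak_uv = -30, mean_rate = 6)
  out <- simulate_session(synthetic_config(layout = tiny_layout(1),
                                           fs = 30000, duration = 30,
                                           units = list(u), noise_sd = 3,
                                           seed = 18))
  x <- butterworth_filter(out$session$voltages[1, ], 30000, "bandpass",
                          c(300, 2000))
  fl <- noise_floor(x, 30000)
  tr <- detect_spikes(x, 30000, fl, 5)
  gt <- out$truth$spike_times[[1]]
  recall <- mean(vapply(gt, function(t) any(abs(tr$time_s - t) < 5e-4),
                        logical(1)))
  precision <- mean(vapply(tr$time_s, function(t) any(abs(gt - t) < 5e-4),
                           logical(1)))
  expect_gte(recall, 0.99)
  expect_gte(precision, 0.95)
})

test_that("coincidence rejection drops array-wide events and keeps local ones", {
  mk_train <- function(times) structure(
    data.frame(time_s = times, amplitude = rep(-50, length(times))),
    fs = 10000, class = c("spike_train", "data.frame"))
  n_ch <- 28
  # one artifact at t=1 on all channels; one local spike at t=2 on 4
  trains <- lapply(seq_len(n_ch), function(ch) {
    if (ch <= 4) mk_train(c(1, 2)) else mk_train(1)
  })
  out <- reject_coincident(trains, window_ms = 0.5, channel_frac = 0.9)
  expect_true(all(vapply(out, function(tr) !(1 %in% tr$time_s),
                         logical(1))))
  expect_true(all(vapply(out[1:4], function(tr) 2 %in% tr$time_s,
                         logical(1))))
  empty <- lapply(1:3, function(i) mk_train(numeric()))
  expect_equal(vapply(reject_coincident(empty), nrow, integer(1)),
               rep(0L, 3))
  expect_error(reject_coincident(trains[1]), "at least 2")
})

test_that("waveform extraction aligns to the trough and drops edge spikes", {
  u <- unit_spec(1, peak_uv = -120, mean_rate = 4)
  out <- simulate_session(synthetic_config(layout = tiny_layout(1),
                                           fs = 30000, duration = 20,
                                           units = list(u), noise_sd = 1,
                                           seed = 22))
  gt <- out$truth$spike_times[[1]]
  tr <- structure(data.frame(time_s = c(1e-5, gt),
                             amplitude = rep(NA_real_, length(gt) + 1)),
                  fs = 30000, class = c("spike_train", "data.frame"))
  # extract from the unfiltered session so the snippet shape is compared
  # against the exact injected template
  wf <- extract_waveforms(out$session, tr)
  expect_equal(dim(wf)[3], 105)  # 3.5 ms at 30 kHz
  expect_equal(attr(wf, "n_dropped"), 1)
  tmpl <- spike_template(30000, peak_uv = -120)
  cors <- apply(matrix(unclass(wf)[, 1, ], nrow = dim(wf)[1]), 1,
                function(s) cor(s, tmpl))
  expect_gt(mean(cors), 0.99)
})

test_that("QC accepts well-isolated units and rejects violators", {
  u <- list(unit_spec(1, peak_uv = -120, mean_rate = 6),
            unit_spec(5, peak_uv = -100, mean_rate = 5))
  out <- simulate_session(synthetic_config(layout = tiny_layout(),
                                           fs = 10000, duration = 60,
                                           units = u, noise_sd = 6,
                                           seed = 25))
  srt <- sort_units(out$session)
  expect_equal(length(srt$accepted), 2)
  for (cl in srt$accepted) {
    expect_true(all(unlist(cl$qc)))
  }
  acc <- mapply(function(gt_idx) {
    best <- vapply(srt$accepted, function(cl)
      mean(vapply(out$truth$spike_times[[gt_idx]], function(t)
        any(abs(cl$times - t) < 5e-4), logical(1))), numeric(1))
    max(best)
  }, seq_along(u))
  expect_true(all(acc >= 0.95))

  # a Poisson train with no refractory fails the refractory criterion
  set.seed(26)
  fake <- srt$accepted[[1]]
  fake$times <- sort(runif(2000, 0, 10))
  fake <- qc_unit(fake, out$session$layout, refractory_ms = 2,
                  violation_frac_max = 0.01)
  expect_false(fake$qc$refractory)

  # a waveform equal on all channels (common-mode artifact) is not local
  flat <- srt$accepted[[1]]
  flat$mean_waveform <- matrix(rep(flat$mean_waveform[1, ],
                                   each = nrow(flat$mean_waveform)),
                               nrow = nrow(flat$mean_waveform))
  flat <- qc_unit(flat, out$session$layout)
  expect_false(flat$qc$spatial)
})

test_that("correlograms are symmetric, conserve counts, and dip at refractoriness", {
  set.seed(27)
  a <- sort(runif(400, 0, 60))
  b <- sort(runif(300, 0, 60))
  cab <- correlogram(a, b, n_shuffles = 50, duration = 60)
  cba <- correlogram(b, a, n_shuffles = 50, duration = 60)
  expect_equal(cab$count, rev(cba$count))
  # count conservation: every pair within the span is binned once
  d <- outer(b, a, "-") * 1000
  expect_equal(sum(cab$count), sum(d >= -50 & d <= 50))

  # refractory train: near-zero counts below the shuffle band at small lags
  u <- unit_spec(1, mean_rate = 8, refractory_ms = 4)
  out <- simulate_behavior_session(
    synthetic_config(layout = tiny_layout(1), fs = 10000, duration = 300,
                     units = list(u), noise_sd = 0, seed = 28),
    feeding_time = 150, feeding_multiplier = 1, render_voltage = FALSE)
  st <- out$truth$spike_times[[1]]
  ac <- correlogram(st, bin_ms = 1, span_ms = 20, n_shuffles = 200,
                    duration = 300)
  low <- abs(ac$lag_ms) < 3.5
  expect_true(all(ac$count[low] < ac$ci_low[low]))
  expect_error(correlogram(numeric(), a), "empty")
})
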
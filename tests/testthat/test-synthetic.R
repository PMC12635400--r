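test_that("null config gives an all-zero matrix and fixed seeds reproduce bytes", {
  cfg <- synthetic_config(layout = tiny_layout(1), fs = 5000, duration = 2,
                          noise_sd = 0, seed = 1)
  out <- simulate_session(cfg)
  expect_true(all(out$session$voltages == 0))
  a <- simulate_session(synthetic_config(layout = tiny_layout(), fs = 5000,
                                         duration = 2, noise_sd = 4,
                                         seed = 77))
  b <- simulate_session(synthetic_config(layout = tiny_layout(), fs = 5000,
                                         duration = 2, noise_sd = 4,
                                         seed = 77))
  expect_identical(a$session$voltages, b$session$voltages)
})

test_that("spike counts follow the Poisson law and respect refractoriness", {
  u <- unit_spec(1, peak_uv = -60, mean_rate = 5, refractory_ms = 2)
  cfg <- synthetic_config(layout = tiny_layout(1), fs = 10000,
                          duration = 300, units = list(u), noise_sd = 0,
                          seed = 13)
  out <- simulate_session(cfg)
  n_spk <- length(out$truth$spike_times[[1]])
  # 99% interval of Poisson(1500), slightly widened for the ~1% dead-time
  # thinning loss
  expect_gt(n_spk, qpois(0.005, 1500 * 0.99))
  expect_lt(n_spk, qpois(0.995, 1500))
  expect_true(all(diff(out$truth$spike_times[[1]]) >= 0.002 - 1e-12))
})

test_that("spike amplitude is maximal on the peak site and decays with distance", {
  u <- unit_spec(1, peak_uv = -90, decay_um = 30, mean_rate = 8)
  out <- simulate_session(synthetic_config(layout = tiny_layout(),
                                           fs = 10000, duration = 30,
                                           units = list(u), noise_sd = 0,
                                           seed = 5))
  amps <- out$truth$unit_site_amps[[1]]
  lay <- tiny_layout()
  d <- sqrt((lay$x - lay$x[1])^2 + (lay$y - lay$y[1])^2)
  ord <- order(d)
  expect_equal(which.max(amps$amp), 1)
  expect_true(all(diff(amps$amp[ord]) <= 1e-12))
  # the rendered signal's most negative sample sits on the peak channel
  expect_equal(which.min(apply(out$session$voltages, 1, min)), 1)
  # and matches the template trough amplitude
  expect_equal(min(out$session$voltages[1, ]), -90, tolerance = 1e-9)
})

test_that("a single oscillation lands its PSD peak inside the declared band", {
  for (spec in list(oscillation_spec(0.15, 20), oscillation_spec(0.6, 20),
                    oscillation_spec(3, 20), oscillation_spec(40, 20),
                    oscillation_spec(800, 20))) {
    out <- simulate_session(synthetic_config(
      layout = tiny_layout(1), fs = 10000, duration = 60,
      background = list(spec), noise_sd = 0.01, seed = 3))
    p <- welch_psd(out$session$voltages[1, ], 10000, 600000)
    f_peak <- p$freq[which.max(p$density)]
    bands <- gut_bands()
    b <- bands[bands$label == spec$band, ]
    expect_gte(f_peak, b$lo)
    expect_lt(f_peak, b$hi)
  }
  expect_error(oscillation_spec(3000, 1), "outside")
})

test_that("saline injections change nothing and drug responses are band-confined", {
  base <- simulate_session(synthetic_config(layout = tiny_layout(1),
                                            fs = 10000, duration = 30,
                                            noise_sd = 5, seed = 17))
  sal <- inject_evoked_response(base$session, event_spec("saline", 10))
  expect_equal(max(abs(sal$voltages - base$session$voltages)), 0)
  expect_equal(sal$events$kind, "saline")

  ev <- event_spec("distension", 10, amplitude_uv = 50, delay_s = 0.5,
                   hf_duration_s = 2, lf_duration_s = 4)
  quiet <- simulate_session(synthetic_config(layout = tiny_layout(1),
                                             fs = 10000, duration = 30,
                                             noise_sd = 0, seed = 17))
  inj <- inject_evoked_response(quiet$session, ev)
  hf <- butterworth_filter(inj$voltages[1, ], 10000, "bandpass",
                           c(300, 2000))
  tt <- seq_along(hf) / 10000
  in_win <- tt >= 10.5 - 0.05 & tt <= 12.5 + 0.05
  expect_gt(sum(hf[in_win]^2) / sum(hf^2), 0.99)
  # the slow deflection is confined below 300 Hz: the high-passed trace
  # carries almost none of the injected low-frequency energy
  lf <- butterworth_filter(inj$voltages[1, ], 10000, "lowpass", 300)
  expect_equal(max(lf), 50, tolerance = 0.05 * 50)
  expect_error(inject_evoked_response(base$session,
                                      event_spec("drug", 29.9)),
               "past the session")
})

test_that("desensitization halves successive responses by construction", {
  # hf_duration 0 isolates the low-frequency component for an exact check
  evs <- rbind(event_spec("drug", 10, amplitude_uv = 40,
                          desens_factor = 0.5, repeat_index = 1,
                          hf_duration_s = 0),
               event_spec("drug", 40, amplitude_uv = 40,
                          desens_factor = 0.5, repeat_index = 2,
                          hf_duration_s = 0))
  out <- simulate_session(synthetic_config(layout = tiny_layout(1),
                                           fs = 10000, duration = 60,
                                           events = evs, noise_sd = 0,
                                           seed = 19))
  lf <- butterworth_filter(out$session$voltages[1, ], 10000, "lowpass", 300)
  tt <- seq_along(lf) / 10000
  pk1 <- max(lf[tt > 10 & tt < 20])
  pk2 <- max(lf[tt > 40 & tt < 50])
  expect_equal(pk2 / pk1, 0.5, tolerance = 0.02)
})

test_that("behavior sessions step rates at feeding and record exact stress truth", {
  units <- replicate(10, unit_spec(1, mean_rate = 4), simplify = FALSE)
  cfg <- synthetic_config(layout = tiny_layout(1), fs = 5000,
                          duration = 1200, units = units, noise_sd = 0,
                          seed = 23)
  out <- simulate_behavior_session(cfg, feeding_time = 600,
                                   feeding_multiplier = 2,
                                   render_voltage = FALSE)
  ratios <- vapply(out$truth$spike_times, function(st)
    sum(st >= 600) / sum(st < 600), numeric(1))
  # post/pre count ratio ~ 2 within Poisson error, pooled across units
  expect_equal(mean(ratios), 2, tolerance = 0.15)

  # multiplier 1 leaves rates flat
  flat <- simulate_behavior_session(cfg, feeding_time = 600,
                                    feeding_multiplier = 1,
                                    render_voltage = FALSE)
  r_flat <- vapply(flat$truth$spike_times, function(st)
    sum(st >= 600) / sum(st < 600), numeric(1))
  expect_equal(mean(r_flat), 1, tolerance = 0.1)

  # day_attenuation 0 disables the stress component entirely
  small <- synthetic_config(layout = tiny_layout(1), fs = 2000,
                            duration = 180, noise_sd = 1, seed = 29)
  off <- simulate_behavior_session(small, feeding_time = 90,
                                   day_attenuation = 0)
  on <- simulate_behavior_session(small, feeding_time = 90,
                                  day_attenuation = 1, stress_sd = 20)
  expect_null(off$truth$stress_power_per_minute)
  expect_equal(length(on$truth$stress_power_per_minute), 3)
  expect_true(all(diff(on$truth$stress_power_per_minute) < 0))
  expect_gt(stats::var(on$session$voltages[1, 1:1000]),
            stats::var(off$session$voltages[1, 1:1000]))
})

test_that("config validation rejects undersampled and out-of-range setups", {
  expect_error(synthetic_config(layout = tiny_layout(1), fs = 1000,
                                duration = 1,
                                background = list(oscillation_spec(700, 5))),
               "twice the highest")
  expect_error(synthetic_config(layout = tiny_layout(1), fs = 10000,
                                duration = 10,
                                events = event_spec("drug", 20)),
               "within")
  expect_error(synthetic_config(layout = tiny_layout(1), fs = 10000,
                                duration = -1), "positive")
})
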
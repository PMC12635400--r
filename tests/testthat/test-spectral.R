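test_that("welch PSD satisfies Parseval and locates tones", {
  set.seed(3)
  fs <- 2000
  for (L in c(256, 512, 1024)) {
    x <- rnorm(60000, sd = 2)
    p <- welch_psd(x, fs, segment_length = L)
    expect_equal(p$freq[2] - p$freq[1], fs / L)
    expect_equal(sum(p$density) * fs / L, 4, tolerance = 0.05 * 4)
  }
  tt <- seq(0, 30, by = 1 / fs)
  tone <- sin(2 * pi * 100 * tt)
  p <- welch_psd(tone, fs, 512)
  expect_equal(p$freq[which.max(p$density)], 100, tolerance = fs / 512)
  expect_error(welch_psd(rnorm(100), fs, 512), "shorter")
})

test_that("welch frequency spacing reaches 0.01 Hz with the long segment", {
  # spacing = fs / segment_length is a property of the grid, so a short
  # white-noise signal zero-padded to one segment is enough to check it
  p <- welch_psd(rnorm(1e6), 10000, 1e6)
  expect_equal(p$freq[2] - p$freq[1], 0.01)
})

test_that("spectrogram is stationary on noise, localizes bursts, floors zeros", {
  set.seed(4)
  fs <- 2000
  x <- rnorm(20000)
  sp <- spectrogram(x, fs)
  col_db <- colMeans(sp$power_db)
  expect_lt(sd(col_db), 3)
  # tone burst at t in [2,3] s raises its bin only there
  tt <- seq(0, 10 - 1 / fs, by = 1 / fs)
  burst <- ifelse(tt >= 2 & tt < 3, 10, 0) * sin(2 * pi * 400 * tt)
  sp2 <- spectrogram(burst + 0.01 * rnorm(length(tt)), fs)
  fbin <- which.min(abs(sp2$freq - 400))
  inside <- sp2$times >= 2 & sp2$times <= 3
  expect_gt(min(sp2$power_db[fbin, inside]) -
              max(sp2$power_db[fbin, sp2$times > 4]), 20)
  spz <- spectrogram(numeric(5000), fs)
  expect_true(all(spz$power_db == spz$floor_db))
  expect_error(spectrogram(numeric(100), fs, nfft = 256), "exceeds")
})

test_that("rolling AUC integrates a constant field to p * bandwidth * window", {
  fs <- 1000
  sp <- spectrogram(rnorm(20000), fs)
  p0 <- -30
  sp$power_db <- matrix(p0, nrow = nrow(sp$power_db),
                        ncol = ncol(sp$power_db))
  auc <- rolling_spectrogram_auc(sp, 1)
  bw <- max(sp$freq) - min(sp$freq)
  # Simpson over m columns spans (m-1) dt, a half-column short of the
  # nominal window at each end
  expect_equal(auc$auc, rep(p0 * bw, nrow(auc)) * (1 - (sp$nfft - sp$overlap) / fs),
               tolerance = 0.01 * abs(p0 * bw))
  expect_equal(nrow(auc), floor(ncol(sp$power_db) /
                                  round(1 / ((sp$nfft - sp$overlap) / fs))))
})

test_that("rolling AUC flags a single-window burst and is split-invariant", {
  fs <- 1024  # one AUC window = exactly 8 spectrogram columns
  tt <- seq(0, 20 - 1 / fs, by = 1 / fs)
  # burst kept safely inside the 11th window: with 50% column overlap a
  # boundary-touching burst inevitably bleeds one column into a neighbour
  x <- 0.05 * rnorm(length(tt)) +
    ifelse(tt >= 10.15 & tt < 10.95, 8, 0) * sin(2 * pi * 200 * tt)
  sp <- spectrogram(x, fs)
  auc <- rolling_spectrogram_auc(sp, 1)
  base <- stats::median(auc$auc)
  dev <- auc$auc - base
  # exactly one window stands out: the burst exceeds every other window's
  # deviation more than five-fold
  expect_equal(sum(dev > max(dev) / 5), 1)
  expect_equal(which.max(auc$auc), 11)  # the [10, 11) window

  # splitting the spectrogram at a window boundary and concatenating the
  # per-part series reproduces the full series
  cols_per_win <- round(1 / ((sp$nfft - sp$overlap) / fs))
  k <- 7 * cols_per_win
  sp_a <- sp; sp_a$power_db <- sp$power_db[, 1:k]; sp_a$times <- sp$times[1:k]
  sp_b <- sp; sp_b$power_db <- sp$power_db[, -(1:k)]
  sp_b$times <- sp$times[-(1:k)]
  both <- c(rolling_spectrogram_auc(sp_a, 1)$auc,
            rolling_spectrogram_auc(sp_b, 1)$auc)
  expect_equal(both, auc$auc[seq_along(both)], tolerance = 1e-12)
})

test_that("response metrics use the population variance convention", {
  auc <- structure(data.frame(window_start = 0:2, auc = c(1, 2, 3)),
                   window = 1, class = c("auc_series", "data.frame"))
  m <- response_metrics(auc)
  expect_equal(m$max, 3)
  expect_equal(m$mean, 2)
  expect_equal(m$variance, 2 / 3)
  const <- structure(data.frame(window_start = 0:3, auc = rep(5, 4)),
                     window = 1, class = c("auc_series", "data.frame"))
  mc <- response_metrics(const)
  expect_equal(mc$variance, 0)
  expect_equal(mc$max, mc$mean)
  expect_error(response_metrics(auc, response_start = 100), "no AUC")
})

test_that("metric normalization is min-max across conditions with degenerate flag", {
  mk <- function(v) structure(list(max = v, mean = v, variance = v,
                                   normalized_max = NA_real_,
                                   normalized_mean = NA_real_,
                                   normalized_variance = NA_real_),
                              class = "response_metrics")
  nm <- normalize_metrics(list(a = mk(2), b = mk(4), c = mk(6)))
  expect_equal(vapply(nm, `[[`, numeric(1), "normalized_mean"),
               c(a = 0, b = 0.5, c = 1))
  # scale invariance: affine transform leaves normalized values unchanged
  nm2 <- normalize_metrics(list(a = mk(2 * 7 + 1), b = mk(4 * 7 + 1),
                                c = mk(6 * 7 + 1)))
  expect_equal(vapply(nm2, `[[`, numeric(1), "normalized_max"),
               vapply(nm, `[[`, numeric(1), "normalized_max"))
  expect_warning(deg <- normalize_metrics(list(a = mk(3), b = mk(3))),
                 "degenerate")
  expect_equal(attr(deg, "degenerate"), c("max", "mean", "variance"))
  expect_equal(deg$a$normalized_mean, 0)
  expect_error(normalize_metrics(list(a = mk(1))), "at least 2")
})

test_that("drug metrics exceed saline metrics on synthetic sessions", {
  out <- simulate_session(synthetic_config(
    layout = tiny_layout(1), fs = 10000, duration = 120,
    events = rbind(event_spec("drug", 20, amplitude_uv = 45,
                              hf_duration_s = 5),
                   event_spec("saline", 70)),
    noise_sd = 5, seed = 21))
  x <- butterworth_filter(out$session$voltages[1, ], 10000, "bandpass",
                          c(300, 2000))
  sp <- spectrogram(x, 10000)
  auc <- rolling_spectrogram_auc(sp, 1)
  m_drug <- response_metrics(auc, 20, 50)
  m_sal <- response_metrics(auc, 70, 100)
  expect_gt(m_drug$max, m_sal$max)
  expect_gt(m_drug$mean, m_sal$mean)
  expect_gt(m_drug$variance, m_sal$variance)
})

test_that("band power normalizes a flat spectrum identically across bands", {
  fs <- 10000
  set.seed(9)
  p <- welch_psd(rnorm(1.2e6), fs, 6e5)
  bp <- band_power(p)
  expect_equal(nrow(bp), 5)
  expect_true(all(abs(bp$power / mean(bp$power) - 1) < 0.1))
  # a 2 Hz tone dominates only the 1-5 Hz band
  tt <- seq(0, 60 - 1 / fs, by = 1 / fs)
  p2 <- welch_psd(sin(2 * pi * 2 * tt) + 0.001 * rnorm(length(tt)), fs,
                  60000)
  bp2 <- band_power(p2)
  expect_equal(bp2$band[which.max(bp2$power)], "1-5")
  expect_gt(bp2$power[3] / max(bp2$power[-3]), 100)
  # unordered bands rejected
  bad <- gut_bands()[c(2, 1, 3, 4, 5), ]
  expect_error(band_power(p, bad), "ordered")
  # band beyond the PSD range rejected
  wide <- data.frame(label = "x", lo = 0, hi = fs)
  expect_error(band_power(p, wide), "beyond")
})

test_that("band powers recover the injected per-band amplitude ordering", {
  fs <- 10000
  oscs <- list(oscillation_spec(0.1, 40), oscillation_spec(0.5, 25),
               oscillation_spec(3, 55), oscillation_spec(30, 15),
               oscillation_spec(700, 8))
  out <- simulate_session(synthetic_config(
    layout = tiny_layout(1), fs = fs, duration = 120,
    background = oscs, noise_sd = 0.5, seed = 31))
  p <- welch_psd(out$session$voltages[1, ], fs, 600000)
  bp <- band_power(p)
  # injected bandwidth-normalized power of a tone: (A^2 / 2) / bandwidth
  inj <- vapply(oscs, function(o) o$amplitude_uv^2 / 2, numeric(1)) /
    (gut_bands()$hi - gut_bands()$lo)
  expect_equal(cor(rank(bp$power), rank(inj), method = "spearman"), 1)
})
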
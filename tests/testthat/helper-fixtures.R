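# Shared fixture builders: everything is generated in code at test time.

tiny_layout <- function(n_tetrodes = 2) {
  build_tetrode_layout(n_tetrodes, n_markers = 0)
}

# A small noisy session with optional units, cheap enough for unit tests.
tiny_session <- function(seed = 1, duration = 10, fs = 10000,
                         units = list(), noise_sd = 5, ...) {
  cfg <- synthetic_config(layout = tiny_layout(), fs = fs,
                          duration = duration, units = units,
                          noise_sd = noise_sd, seed = seed, ...)
  simulate_session(cfg)
}

# Deterministic single-channel session wrapping a given trace.
trace_session <- function(x, fs = 10000, n_ch = 2) {
  recording_session(matrix(rep(x, each = n_ch), nrow = n_ch), fs = fs)
}

expect_spike_train_valid <- function(train) {
  expect_s3_class(train, "spike_train")
  expect_true(!is.unsorted(train$time_s, strictly = TRUE))
}
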
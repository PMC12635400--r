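Package: entephys
Title: Enteric Nervous System Electrophysiology Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Analysis pipeline for chronic multi-channel extracellular
    recordings from the gut wall: signal conditioning (Butterworth and
    notch filtering, common average referencing, anti-aliased
    downsampling, artifact-epoch detection), Welch power spectral
    densities and dB-scaled spectrograms, rolling spectrogram-AUC
    evoked-response metrics with min-max normalization, distension
    positive-area quantification with its assumption-gated statistical
    chain, Hilbert contraction envelopes, robust noise-floor spike
    detection with four-criterion single-unit quality control and
    shuffle-calibrated correlograms, feeding-aligned z-scored firing
    rates, and per-minute bandwidth-normalized multi-band power
    profiles. Includes a deterministic synthetic tetrode-array
    recording generator with full ground truth so every stage is
    testable without animal data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    pracma,
    mclust,
    car,
    arrow,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
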
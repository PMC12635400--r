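---
title: "Methods: gut electrophysiology analysis with entephys"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: gut electrophysiology analysis with entephys}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`entephys` analyzes chronic multi-channel extracellular recordings from
the wall of the gut: signals that mix single-neuron spikes from the
enteric nervous system with slow waves of interstitial cells of Cajal
(ICC), smooth-muscle rhythms, skeletal-muscle (EMG) contamination, mains
interference, and evoked responses to mechanical and chemical stimuli.
This vignette explains the models and procedures the package implements,
the parameters that matter, what the synthetic generator does and does
not emulate, and the numerical choices made where the design was open.

## The recording geometry

The implant carries a linear array of 7 tetrodes (groups of four 20 µm
electrodes) with 50 µm spacing inside a tetrode and 250 µm between
tetrode centers, flanked by large surgical-marker electrodes that do not
record; `build_tetrode_layout()` constructs this parametrically. Two
choices were open:

* **Tetrode internal arrangement.** Only the 50 µm neighbor spacing is
  specified, not the shape. We use a square of side 50 µm, the standard
  tetrode convention: each site then has exactly two tetrode neighbors
  at 50 µm and one diagonal mate at 50·√2 ≈ 70.7 µm. Spatial
  unit-localization QC is defined against this same frame, so the
  simulator and the QC are self-consistent.
* **Coordinate frame.** Array axis = x, origin at the first tetrode
  center, micrometers throughout.

`recording_neighborhood()` uses a strict `<` radius (a site at exactly
the radius is excluded), matching the "within < 50 µm" phrasing of
spike detectability ranges.

## Signal conditioning

All filtering is order-4 Butterworth applied forward–backward
(zero-phase). Zero-phase application is our choice — it preserves spike
timing for detection — and squares the magnitude response, which the
attenuation tests account for. Implementation detail: signals are
extended by odd reflection before filtering, with padding scaled to the
slowest filter time constant (10 cycles of the lowest cutoff; several
ring-down times for notches), so constants and slow trends pass without
start-up transients.

Mains interference is removed with cascaded second-order IIR notches at
50 Hz and odd harmonics (150, 250, 350 Hz), Q = 30 each. The harmonic
cap and Q are our defaults — the description "50 Hz and odd harmonics"
fixes neither — and both are exposed as parameters. Even harmonics are
deliberately untouched.

Common average referencing (`common_reference()`) subtracts the
across-channel mean at every sample; downsampling to 10 kHz
(`downsample()`) applies a sharp linear-phase FIR low-pass
(Hamming-windowed, 1024 taps, −6 dB at the target Nyquist,
delay-compensated) before integer decimation. A Butterworth at
0.45 × target rate cannot simultaneously preserve a 4.9 kHz tone and
suppress 6 kHz by 40 dB, so the anti-alias stage uses the FIR design,
for which both hold.

Artifact screening (`detect_artifact_epochs()`) is an automated stand-in
for manual inspection: epochs where ≥ 90% of channels simultaneously
exceed 8 robust SDs (median |x| / 0.6745) are flagged, padded by 0.2 s,
and merged. Synchrony across the whole array is the signature of EMG
contamination rather than localized spiking. Manually curated epoch
tables can be supplied instead and take precedence wherever epochs are
accepted.

## Spectral estimation and the evoked-response statistic

`welch_psd()` averages Hann-windowed modified periodograms;
the frequency spacing is `fs / segment_length`, so 1,000,000-sample
segments at 10 kHz give ~0.01 Hz resolution (needed for ICC slow waves).
`spectrogram()` is the short-time counterpart in dB ("psd" scaling),
with defaults nfft = 256 and overlap = 128 samples pinned for
reproducibility, and a −120 dB floor for silent bins.

The evoked-response statistic iterates over the spectrogram in
non-overlapping 1 s windows: each column is first collapsed over
frequency by the trapezoid rule (dB·Hz per column), then the collapsed
series is Simpson-integrated over time within the window. The
description of this statistic is ambiguous about the axis order of the
two integrations; we fixed frequency-collapse-then-time and expose the
window length. The AUC is computed on the dB-scale power (matching the
dB-mode spectrogram it is read from); tests therefore target internal
consistency of the statistic, not absolute AUC values. Per-event
metrics are the maximum, mean and **population** variance (divide by N —
the common numerical default) of the per-window AUC over the post-event
span, min–max normalized to [0, 1] across all conditions of one
experiment, so a saline wash that always evokes the weakest response
lands at 0. A zero range across conditions raises a degenerate-
experiment flag rather than dividing by zero.

Band powers integrate the PSD over the five bands 0–0.2 / 0.2–1 / 1–5 /
5–300 / 300–2000 Hz (half-open `[lo, hi)`, making them a partition) and
divide by bandwidth. Band edges rarely fall on PSD grid points, so the
trapezoid integral interpolates the density at the edges; a flat
spectrum then reports identical normalized power in every band up to
estimator noise. The 0–0.2 Hz band holds very few Fourier bins per
minute of data — its per-minute estimates are intrinsically the
noisiest, which the tests acknowledge with wider tolerances.

## Distension quantification and the statistical chain

Distension responses are quantified on the < 300 Hz trace as the
trapezoidal area under the **positive** part of a 10 s post-stimulus
window, min–max normalized within each experiment (nAUC ∈ [0, 1]). Group
comparisons run Shapiro–Wilk per group and Levene's test
(median-centered, the default of the scipy stack this chain mirrors);
when all pass at α = 0.05 an unpaired two-sided pooled-variance t-test
is used (df = n₁+n₂−2; pooled rather than Welch because the Levene gate
precedes it and the reported df = 14 for 8 + 8 implies pooling), with
Cohen's d = mean difference / pooled SD and a t-critical × pooled-SE
95% CI. Otherwise a two-sided Mann–Whitney U test is used, U reported
for the first group (exact when n₁·n₂ ≤ 400 without ties, normal
approximation with tie correction otherwise). For equal group sizes the
identity t = d·√(n/2) links the effect size to the statistic
(`t_from_cohens_d()`); d = 1.77 at n = 8 gives t = 3.54. Boxplot
summaries use type-7 (linear interpolation) quartiles and Tukey whisker
bounds Q1 − 1.5·IQR / Q3 + 1.5·IQR reported as bounds, not clipped to
the data. Note that a 95% CI of the mean difference computed under the
pooled-SE convention is not, in general, recoverable from a printed
t and df alone; this package documents and tests its own convention.

Contraction envelopes are |analytic signal| (frequency-domain Hilbert
transform) of the 300–2000 Hz trace, smoothed by a 1 s moving average
with reflection padding at the edges.

## Spike detection and single-unit validation

The per-channel noise floor is `mean(|x| / 0.6745)` over the 5 longest
artifact-free epochs of the 300 Hz high-passed trace. This printed
formula uses the *mean*, whereas the classical robust estimator uses the
*median*; for Gaussian noise the mean variant converges to 1.183 σ and
the median variant to σ. We implement the mean variant as the default
for fidelity and provide `robust = "median"`, with both calibrations
tested. Spikes are negative troughs below −k × floor with k ∈ [4, 6]
(default 5, per-session curation is the user's; values outside the range
warn), one event per excursion with a 1 ms lockout. Events coincident on
≥ 90% of all channels within ±0.5 ms are array-wide artifacts and are
removed (the 90% tolerates dead channels).

Waveforms are 3.5 ms multi-channel snippets aligned with the trough at
1/3 of the window (our choice; nothing pins it). Clustering is PCA on
channel-concatenated waveforms followed by Gaussian-mixture model
selection (BIC over 1–5 components), with a template-similarity merge
pass: mixture fits routinely oversplit one unit when spike collisions
distort a minority of waveforms, so clusters sharing a peak channel
whose mean waveforms correlate above 0.9 at comparable amplitude are
merged. A cluster is accepted as a putative single neuron only if all
four criteria hold simultaneously: (1) a stereotyped, asymmetric
biphasic waveform (dominant negative trough, smaller positive rebound,
mean spike-to-template correlation ≥ 0.6); (2) a refractory period
(< 1% of inter-spike intervals below 2 ms); (3) spatial localization
(amplitude strictly largest on one channel and < 50% of peak beyond
100 µm — point-source decay); (4) separability (mean silhouette ≥ 0.2
against the nearest cluster in PC space). These four acceptance rules,
not any particular sorting implementation, define what counts as a
single unit here; the clustering stage is deliberately simple and
replaceable.

Correlograms bin spike-time differences within ±50 ms at 1 ms; 95%
confidence bands come from surrogates in which one train's spikes are
reassigned to permuted time bins (bin width = lag bin width), which
destroys fine temporal structure while preserving the marginal rate.
1000 surrogates by default, seeded.

## Chronic behavioral analyses

Firing rates are counted in 3 s bins and z-scored across the whole
session; constant series are flagged and given z = 0 rather than NaN.
Bins are labeled pre-meal (the 15 min novel-environment span before
feeding onset), meal, and post-meal; the meal epoch duration is not
fixed by the session design ("free feeding"), so we default it to 5 min
and expose it. The epoch comparison is a Kruskal–Wallis omnibus over the
three per-unit epoch-mean samples with pairwise two-sided Wilcoxon
signed-rank tests, Bonferroni-corrected over the 3-test family.

The stress analysis takes the common-referenced 10 kHz session, cuts it
into 1-minute intervals, and computes per-channel Welch band powers
(bandwidth-normalized), averaged over channels. The configured
1,000,000-sample Welch segment exceeds one minute at 10 kHz (600,000
samples), and both prescriptions cannot hold at once; we cap the segment
at the interval length for per-minute profiles while whole-session PSDs
keep the long segment.

## The synthetic generator

`simulate_session()` renders, per recording site: Poisson spike trains
(dead-time thinning enforces refractoriness) convolved with biphasic
templates placed at sample resolution and scaled across the array by
exp(−distance/λ) (λ default 30 µm, so tetrode mates see ~19% of the
peak — tight single-cell localization); shared sinusoidal background
rhythms in the five bands; synchronized band-limited (5–300 Hz) EMG
bursts with tapered envelopes; 50 Hz mains plus odd harmonics falling
off as 1/order; i.i.d. Gaussian sensor noise; and two-component evoked
responses (a > 300 Hz tapered noise burst and a < 300 Hz positive
half-sine, after a latency), with saline events adding nothing and
repeated drug additions attenuated by desens^(repeat−1). Everything is
seeded from one root seed split per component; output is
bit-reproducible.

`simulate_behavior_session()` adds a ×2-by-default rate step at feeding
onset and a broadband "stress" component whose power decays as
exp(−t/τ) (τ default 300 s) and scales with a per-day attenuation. The
stress component is a frozen-phase flat-spectrum waveform per channel
(phases drawn once from the seed), tiled minute by minute under the
decay envelope. This makes the injected per-minute band power *exactly*
the envelope schedule — the ground truth is exact rather than itself a
noisy estimate — at the cost of a periodic (hence non-ergodic) noise
component; it is a validation instrument, not a biophysical model.

What the generator does **not** emulate: conductance-based neuron or ICC
dynamics, volume conduction beyond exponential decay, electrode drift,
bursting statistics, spike-amplitude adaptation, and nonstationary
mains. Passing tests therefore demonstrate that the analysis chain
recovers known structure of these classes from realistic mixtures — not
that it handles every pathology of in vivo data.

Default amplitudes are free parameters, not claims: the recordings the
package targets do not publish absolute spike-to-background ratios
beyond scale bars, so defaults (e.g. −80 µV peak over 8 µV noise) were
chosen once to sit in the comfortably detectable regime used by the
recovery tests.

## Problem sizes and numerical tolerances in the test suite

The suites run at desk scale, chosen once: sorting recovery uses a
10-minute, 28-channel session at 10 kHz (the full 300–2000 Hz spike band
is retained; 3 units at 3/5/8 Hz, band-passed troughs ≥ 10× floor);
feeding recovery uses 89 units over 200 seeds at the rate level (no
voltage synthesis); stress decay uses 8 channels over 15 minutes;
spectral calibrations use 10²–10⁷ samples as each statistic requires.
Statistical assertions use tolerances derived from the estimator's own
sampling variance (e.g. ±2% on the noise-floor calibration at 10⁶
samples, 15% band-flatness at the 0–0.2 Hz band's degrees of freedom),
never tuned post hoc.

## Known limitations

* The clustering stage targets well-separated units at moderate counts;
  it does not do template matching, drift correction, or collision
  resolution, and very high firing rates inflate collision-induced
  waveform variance.
* The rolling AUC is dB-scale and therefore not additive across
  channels; comparisons are only meaningful within one experiment, which
  is exactly how the normalization uses it.
* Band powers below 0.2 Hz carry few degrees of freedom per minute;
  trends over minutes are reliable, single-minute values are not.
* The raw-segment dialect (float32 + JSON sidecar) deliberately does not
  parse vendor acquisition formats.
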
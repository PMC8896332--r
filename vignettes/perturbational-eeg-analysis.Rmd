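---
title: "Perturbational EEG complexity and spectral state: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Perturbational EEG complexity and spectral state: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(perturbex)
```

## What the package computes

`perturbex` analyses multichannel epidural EEG recorded around direct
cortical electrical stimulation, at two levels:

* **Evoked dynamics.** How complex, how long-lasting, and how widespread is
  the deterministic cortical response to a pulse? The package quantifies
  this with the state-transition perturbational complexity index (PCIst),
  the inter-trial phase clustering (ITPC) drop time, significance-masked
  time-frequency power, and phase-based connectivity (ISPC) with
  volume-conduction screening.
* **Spontaneous state.** What regime is each cortical site in? Per-channel
  periodograms of the pre-stimulus EEG yield the 1/f spectral exponent,
  low- (1-4 Hz) and high- (20-80 Hz) frequency band powers and the HF/LF
  ratio, a proxy for local activation vs. deactivation.

A synthetic session generator with known ground truth exercises every
stage, so the whole chain is testable without animal recordings.

## Preprocessing

Raw records (10-30 kHz) are band-pass filtered 0.5-80 Hz with a
third-order Butterworth and decimated to 500 Hz
(`bandpass_downsample()`). Filtering is zero-phase (forward-backward):
evoked-response latencies must not be shifted, and the filter is applied
in two numerically stable stages — the low-pass edge at the original rate
(doubling as the anti-alias filter), integer decimation, then the
high-pass edge at the target rate. Designing a 0.5 Hz edge directly at
10-30 kHz puts the normalized corner at ~1e-5 where transfer-function
coefficients are ill-conditioned; splitting the stages avoids that
without changing the passband.

Epochs span [-5, 5) s around each stimulus (the sample at t = 0 is the
event sample; half-open windows give unambiguous shapes), are offset
corrected by their [-1, 0) s baseline mean, and screened for artifacts:
a trial is dropped when its baseline exceeds 500 µV absolute voltage or
its baseline peak-to-peak exceeds 6 times the across-trial median. The
absolute threshold and the adaptive factor are declared defaults
(`artifact_rule()`), not values taken from a reference protocol. The
first 90 clean trials are kept in their original temporal order; real
sessions deliver extra stimuli so that a screened session still reaches
the target count, and the generator-based pipeline mirrors this with a
~10% trial margin.

## Time-frequency decomposition

`morlet_tfr()` convolves every trial and channel with unit-energy complex
Morlet wavelets (3 cycles for evoked analyses, 6 for spontaneous
spectra), on a linear 1-80 Hz grid. The Gaussian envelope has SD
`n_cycles / (2 pi f)` in time, so temporal smoothing shrinks with
frequency. Wavelet normalization is irrelevant to everything downstream —
dB normalization and phase statistics cancel any constant — only relative
consistency matters.

Samples within 3 wavelet SDs of an epoch edge are flagged per frequency
and excluded from baseline statistics and from significance masks. At
3 cycles a 5 Hz wavelet has a ~95 ms SD, so short epochs lose their
lowest frequencies entirely; the 10 s epochs of a full-length session
dwarf these edges.

Power is expressed per channel and frequency as
`10 log10(P(t) / P_baseline)` with the baseline mean over -500 to -200 ms
taken across trials (`db_power()`); 0 dB means "at baseline level", and
the map is invariant to rescaling the recording.

## Bootstrap max-statistic masks

Only deviations that beat a resampling null are interpreted
(`bootstrap_mask()`, `itpc_mask()`, and the mask inside `ispc()`). Each
of the (default 500) draws resamples trials with replacement and then
baseline time points within the draw, forming a surrogate baseline map;
the draw's largest and smallest surrogate values per channel and
frequency are recorded. Three design choices matter, and each is the
result of an explicit calibration requirement — the null must control the
any-point family-wise error rate (FWER) on stationary data:

* **Deviations, not raw values.** Surrogate power maps are dB deviations
  of the resampled trial-mean from the observed per-point baseline mean.
  Thresholding raw surrogate baselines anchors the null to the one
  observed baseline extreme and does not approximate the sampling
  distribution of the maximum.
* **Normalization noise.** The per-cell baseline mean is itself
  estimated; its sampling error shifts the whole observed map coherently.
  A second, independent trial resample supplies exactly this term in the
  surrogate.
* **Family scope.** Thresholding each channel/frequency cell at its own
  max-over-time quantile leaves every cell an `alpha` chance of a false
  positive, so the map-wise error grows with the number of cells. The
  default `family = "map"` therefore standardizes each cell's null
  extremes by their own mean and SD (cells differ hugely in null scale
  through wavelet smoothing), pools the per-draw worst standardized
  extreme across cells, and maps a single global quantile back to
  per-cell thresholds. `family = "cell"` retains the literal per-cell
  variant for comparison with per-cell conventions.

Measured on stationary 1/f surrogates with the 90-epoch trial structure,
the any-point FWER is ~0.02-0.05 at `alpha = 0.05` for power and ~0 at
`alpha = 0.01` for ITPC (the resultant-length null is conservative
because bootstrap trial duplication inflates surrogate ITPC). With few
trials (~20-30) the power mask becomes mildly anti-conservative
(any-point rate ~0.1) because bootstrap tails of a mean narrow at small
n; the masks are calibrated for the 90-trial operating point.
Frequencies whose wavelet autocorrelation time approaches the 300 ms
baseline window (a few Hz at 3 cycles) contribute essentially one
independent baseline sample, so no baseline-window resampling scheme can
calibrate them sharply; they are additionally protected by the edge
exclusion in short epochs.

## Phase metrics

ITPC is the resultant length of across-trial unit phase vectors; its
chance level for n trials is `sqrt(pi) / (2 sqrt(n))` (~0.093 at n = 90).
The **drop time** (`itpc_drop_time()`) is the last significant ITPC point
within 800 ms, over 5-80 Hz: the duration of the phase-locked,
deterministic part of the response.

ISPC measures the across-trial consistency of the phase difference
between two channels, baseline-subtracted per frequency and masked by the
two-sided bootstrap. Zero- or pi-lag clustering is the signature of
volume conduction from a shared source, screened with the Gaussian v-test
(`V = mean cos(theta - mu)`, `u = V sqrt(2n)` against the normal upper
quantile, for mu = 0 and pi; `vtest_zero_pi_rejection()`). The test is
applied per retained time-frequency point to the across-trial
phase-difference distribution before band averaging, with `alpha_v =
0.05` per tested direction — both choices are declared defaults because
no reference level or pooling rule is available. Pair means over 5-14 Hz
and 180-400 ms give the connectivity matrix, and each channel's
**degree** is the proportion of partners with a positive mean.

## PCIst

The evoked response (channels x time) is decomposed by SVD on the 0-600
ms response window; the smallest prefix of components explaining 99% of
response variance is kept, then filtered by a signal-to-noise floor of
1.1 (response RMS over baseline RMS). For each retained component the
normalized state-transition count
`NST(eps) = #{(t, t'): |y(t) - y(t')| > eps} / T^2`
is evaluated on 100 thresholds spanning the component's pairwise distance
range, in the response and in the baseline window;
`dNST(eps) = NST_resp - 1.2 NST_base` is maximized over eps, floored at
0, scaled by the number of response samples, and summed over components.
The defaults (k = 1.2, 99% variance, SNR 1.1, 100 steps, no embedding)
follow the rodent perturbational protocol; optional time-delay embedding
is available through `pci_params(embed = c(L, lag))`. The baseline window
defaults to -650 to -50 ms so that baseline and response windows have
equal length with a 50 ms pre-stimulus guard.

PCIst is 0 for a flat ERP, invariant to positive rescaling (thresholds
are scanned relative to each component's own range), and NST is exactly
an exhaustive pair count (a test verifies this against an O(T^2) oracle).
The sliding variant recomputes PCIst in 100 ms windows stepped by 50 ms —
eleven windows over 0-600 ms — against the same baseline, scaling each
window's contributions by its own sample count. Absolute PCIst magnitudes
depend on the pair-count normalization and per-window scaling used here
and are comparable within this package, not across differently scaled
implementations.

## Spontaneous spectra

`prestim_spectra()` averages 6-cycle wavelet power over the pre-stimulus
window, trials, and (for the global periodogram) channels. The spectral
exponent is the least-squares slope of log10 power vs. log10 frequency
over 20-40 Hz. Band powers use the linear scale before any dB conversion,
and the HF/LF ratio is the ratio of linear band means — with 1/f-shaped
backgrounds this lands at the 1e-3 order of magnitude. dB values are
re 1 µV². Edge samples are trimmed from the averaging window per
frequency, but never more than a quarter of the window per side so the
lowest frequencies remain estimable in short epochs (their absolute power
is then biased low by wavelet truncation, consistently across
conditions).

Topographic maps (`topographic_map()`) solve the discrete Laplace
equation anchored at electrode nodes with reflecting boundaries — a
visualization aid only; every statistic consumes channel values.

## Group statistics

Condition effects use one-way repeated-measures ANOVA via the
multivariate linear model, with Mauchly's test (alpha 0.05) triggering
the Greenhouse-Geisser correction; two within-subject factors go through
`car::Anova` type III univariate tables with the same correction rule;
designs with missing cells fall back to ordinary two-way ANOVA
(`repeated = FALSE`). Pairwise contrasts are two-tailed paired t-tests
with explicit handling of zero-variance differences. Multiplicity is
handled two ways at once, since both conventions are in circulation:
step-down Holm adjusted p-values, and the fixed corrected alpha
`alpha / m` (0.01666 for three conditions, 0.00625 for eight areas).
Regional association between spontaneous activation and complexity is a
least-squares fit of PCIst on the channel's HF/LF ratio with R² and the
slope t-test on n - 2 df.

## The synthetic generator

`simulate_background()` shapes Gaussian white noise in the frequency
domain to an exact `f^beta` power law inside 0.5-80 Hz — the analysis
band; content outside it would be removed by the preprocessing filter
anyway — with separate linear gains below and above 20 Hz. Gamma-burst
channels multiply their >= 20 Hz component by a rectified slow cosine and
add a slow wave at the burst rate: slow waves periodically interrupting
enhanced fast activity, which lowers HF/LF on exactly those channels.

`simulate_evoked_session()` adds, per trial: an early broadband transient
(alpha-function, < 50 ms, amplitude decaying with distance from the
stimulation site) and a 10 Hz windowed oscillation on the channels
nearest the stimulation site. The oscillation's envelope is a boxcar with
<= 25 ms ramps rather than an exponentially damped tail: the stated
`evoked_duration` is then the unambiguous support of the response, which
the duration-recovery guarantee (drop time within ±40 ms of truth at
phase jitter <= 0.3 rad) requires; a damped envelope has no single
duration. Each channel has a fixed phase lag drawn once per session from
[0.4, 2.4] rad — away from 0 and pi, so genuine inter-site lags survive
the volume-conduction screen — and a distance-dependent conduction delay
(~2 ms/mm) that is part of the recorded per-channel true duration.
Optionally a 35 Hz burst at 150-450 ms with random phase per trial
models late HF reactivation: a power increase without phase locking.

The three built-in presets emulate wakefulness and two ketamine depths.
Background exponents (-1.8, -1.4, -1.6) and the band-gain steps between
conditions (HF +5.1/+1.6 dB, LF +4.2/+2.0 dB) follow the reported group
means of those regimes; evoked durations (350, 370, 150 ms) mirror the
reported phase-locked response durations; the deep-anaesthesia preset
confines the response to 8 channels, adds across-trial jitter, and gates
the posteromedial (RS/V2) channels with a 1 Hz gamma-burst. Burst rate
and duty cycle are free parameters — no quantitative reference exists —
and evoked amplitudes scale with the condition's background gains
(ketamine scales the whole spectrum up and evoked potentials are not
normalized). What the generator does **not** model: volume-conduction
forward mixing across channels (channels are independent apart from the
deterministic response), biophysical anaesthetic mechanisms, non-
stationary drift within a session, and realistic artifact morphology.
Passing tests therefore demonstrate correctness of the analysis chain on
data with the assumed statistical structure, not performance on real
recordings.

## Problem sizes and determinism

The test suite and the acceptance script run the chain at desk scale,
chosen as the package's own validation conditions: sessions of 30
retained trials (90 for the mask-calibration checks, matching the
90-epoch trial structure of a full session), 16 channels, 500 Hz, epochs
of a few seconds, 150-200 bootstrap draws, 2 Hz wavelet spacing in the
full pipeline, six virtual subjects and three conditions. Every random
stage takes an explicit integer seed; a session is bit-identical given
(preset, seed), and `run_pipeline()` re-runs byte-identically from its
master seed, recording the seed and a configuration hash in its outputs.

## Known limitations

* The power mask is validated at the 90-trial operating point; far below
  it the bootstrap null narrows and the mask over-detects mildly.
* Frequencies with fewer than ~2 wavelet autocorrelation lengths in the
  baseline window cannot be sharply calibrated from that window by any
  resampling scheme.
* The spectral exponent fitted across the 20 Hz gain step of the
  ketamine presets absorbs part of the step (~0.1 flattening); pure
  power-law backgrounds recover within ±0.05.
* PCIst magnitudes are internally consistent but not numerically
  comparable to implementations with different contribution scaling.
* ISPC significance inherits the mask's small-n caveat, and the v-test
  is applied pointwise; pooling phase differences across a band before
  testing would trade sensitivity differently (the pointwise choice is
  configurable at the call site).
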
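# perturbex

Analysis of perturbational EEG in small animals: how complex is the
cortical response to a direct electrical stimulus, how long does its
deterministic (phase-locked) part last, and how does the spontaneous
spectral state of each cortical site relate to that complexity.

The package is written for electrophysiologists studying anaesthesia,
sleep and consciousness who record multichannel epidural EEG around
low-rate cortical stimulation (e.g. 16 screw electrodes over both
hemispheres of a rat, ~100 pulses at 0.1 Hz, conditions such as
wakefulness vs. two depths of ketamine anaesthesia).

## What it computes

**PCIst — state-transition perturbational complexity.** The trial-mean
evoked response (channels × time) is reduced by SVD on the response
window (0–600 ms; components up to 99% response variance, SNR > 1.1).
For each component the normalized state-transition count

    NST(ε) = #{(t, t′) : |y(t) − y(t′)| > ε} / T²

is scanned over 100 thresholds spanning the component's distance range;
the component contributes `max_ε [NST_resp(ε) − k·NST_base(ε)]` (k = 1.2,
floored at 0) scaled by the response sample count, and PCIst is the sum
over components. It is 0 for a flat response, scale-invariant, and also
computed in sliding 100 ms windows (50 ms step: 11 windows over
0–600 ms).

**ITPC and the drop time.** Inter-trial phase clustering
`|mean_trials e^{iφ}|` per channel/frequency/time from 3-cycle Morlet
wavelets; a bootstrap max-statistic threshold (α = 0.01) keeps genuine
phase locking, and the drop time — the last significant point within
800 ms over 5–80 Hz — measures the duration of the deterministic
response.

**Masked time–frequency power and late HF onset.** Power in dB re the
−500…−200 ms baseline, thresholded by a trial-resampling max/min null
(α = 0.05), HF (20–80 Hz) band course and the first late (80–800 ms)
crossing above 0 dB.

**ISPC connectivity with volume-conduction screening.** Phase-difference
consistency per channel pair, baseline-subtracted and masked; points
clustering at 0 or π (Gaussian v-test, `u = V√(2n)`) are zeroed;
band/window means (5–14 Hz, 180–400 ms) give each channel's connectivity
degree.

**Spontaneous spectra.** Per-channel periodograms (6-cycle wavelets,
1–80 Hz) of the pre-stimulus EEG; 1/f spectral exponent (20–40 Hz
log–log slope), LF (1–4 Hz) and HF (20–80 Hz) band powers, and the
per-channel HF/LF activation ratio; Laplace-interpolated topographies
for display.

**Group statistics.** Repeated-measures ANOVA with Greenhouse–Geisser
correction, paired t-tests, Holm–Bonferroni correction (both step-down
adjusted p and the fixed corrected α: 0.05/3 = 0.01666, 0.05/8 =
0.00625), and linear fits with R² and the slope t-test.

**Synthetic sessions.** `simulate_background()` and
`simulate_evoked_session()` generate sessions with exact 1/f exponents,
condition-dependent band gains, gamma-burst gating of chosen channels,
and a phase-locked evoked oscillation of known duration, spread, lag
structure and jitter — the ground truth every stage is tested against.

## A worked example

Simulate a wakefulness-like and a deep-ketamine-like session for the
16-channel rat grid and compare complexity, response duration and
posteromedial activation:

```r
library(perturbex)

lay <- rat_layout()
ps  <- ketamine_presets()

w  <- simulate_evoked_session(lay, ps$W,  n_trials = 30, seed = 11,
                              epoch_window = c(-2.6, 1.2))
k2 <- simulate_evoked_session(lay, ps$K2, n_trials = 30, seed = 11,
                              epoch_window = c(-2.6, 1.2))

ep_w  <- baseline_correct(w$epochs)
ep_k2 <- baseline_correct(k2$epochs)

pci_st(erp_average(ep_w))$value    # 720.4
pci_st(erp_average(ep_k2))$value   # 188.8

tf <- morlet_tfr(subset_epochs(ep_w, channels = "RS/V2 L",
                               window = c(-1.0, 1.1)), freqs = 1:80)
itpc_drop_time(itpc(tf), itpc_mask(tf, seed = 1))$drop_ms   # 314

sp_w  <- prestim_spectra(ep_w,  window = c(-2.6, 0))
sp_k2 <- prestim_spectra(ep_k2, window = c(-2.6, 0))
sp_w$exponent                      # -1.82
1000 * sp_w$hf_lf["RS/V2 L"]       # 4.33
1000 * sp_k2$hf_lf["RS/V2 L"]      # 1.04
```

The deep-ketamine preset cuts the complexity index to roughly a quarter
of the wakefulness value, and its gamma-burst gating of the posteromedial (RS/V2) channels pulls their
HF/LF ratio well below the wakefulness value while the 1/f exponent
stays in the same range — the dissociation the analysis is built to
detect. `run_pipeline()` assembles the same measures for many virtual
rats and conditions into a long-format table plus the inferential layer.

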
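#' @section Background synthesis:
#' Channels are synthesised in the frequency domain: Gaussian white noise is
#' shaped by an amplitude spectrum proportional to f^(beta/2) inside the
#' analysis band (0.5-80 Hz), giving an exact target power-law exponent
#' beta. The < 20 Hz and >= 20 Hz components receive separate linear gains;
#' on gamma-burst channels the >= 20 Hz component is additionally amplitude-
#' gated by a slow rectified-cosine envelope and a slow (burst-rate) wave is
#' added, which jointly lower the channel's HF/LF ratio.
#' @name synthetic-background
#' @keywords internal
NULL

# Frequency-domain shaping vectors for one channel realisation.
# Returns list(low, high): real time series of the <20 Hz and >=20 Hz
# components of unit-scale shaped noise, plus the theoretical sd of their sum.
shaped_noise_parts <- function(n, rate, beta, f_lo = 0.5, f_hi = 80) {
  x <- stats::rnorm(n)
  X <- stats::fft(x)
  f <- abs(seq(0, rate, length.out = n + 1)[seq_len(n)])
  f <- pmin(f, rate - f)                     # two-sided frequency axis
  amp <- rep(0, n)
  inband <- f >= f_lo & f <= min(f_hi, rate / 2)
  amp[inband] <- if (beta == 0) 1 else f[inband]^(beta / 2)
  lowm <- amp * (f < 20)
  highm <- amp * (f >= 20)
  low <- Re(stats::fft(X * lowm, inverse = TRUE)) / n
  high <- Re(stats::fft(X * highm, inverse = TRUE)) / n
  # E[var] of the shaped series (white noise has flat unit spectral density)
  sd_theory <- sqrt(sum(amp^2) / n)
  list(low = low, high = high, sd_theory = sd_theory)
}

# One synthetic background channel (microvolts). Gains and optional
# gamma-burst gating applied on top of the unit-normalised shaped noise.
synth_channel <- function(n, rate, preset, gated) {
  parts <- shaped_noise_parts(n, rate, preset$background_exponent)
  sc <- preset$base_amp_uv / parts$sd_theory
  low <- preset$lf_gain * sc * parts$low
  high <- preset$hf_gain * sc * parts$high
  if (gated && preset$burst_rate > 0) {
    t <- (seq_len(n) - 1) / rate
    env <- (1 + cos(2 * pi * preset$burst_rate * t)) / 2
    slow <- preset$base_amp_uv * preset$lf_gain *
      cos(2 * pi * preset$burst_rate * t)
    low + env * high + slow
  } else {
    low + high
  }
}

#' Simulate spontaneous multichannel background EEG
#'
#' Generates a continuous recording whose channels share a 1/f^|beta|
#' power-law background with per-band gains from the preset; channels listed
#' in `preset$burst_channels` show the gamma-burst regime (slow waves
#' periodically interrupting enhanced HF activity).
#'
#' @param layout a [channel_layout].
#' @param preset a [condition_preset].
#' @param duration_s record duration in seconds (> 0).
#' @param rate_hz sampling rate in Hz (>= 500).
#' @param seed integer seed; identical (preset, seed) gives bit-identical
#'   output.
#' @return A [continuous_recording] with no events.
#' @export
simulate_background <- function(layout, preset, duration_s, rate_hz = 500,
                                seed = 1) {
  stop_if_not_scalar_pos(duration_s, "duration_s")
  if (rate_hz < 500) stop("rate_hz must be >= 500")
  unknown <- setdiff(preset$burst_channels, layout$label)
  if (length(unknown))
    stop("burst_channels not in layout: ", paste(unknown, collapse = ", "))
  n <- round(duration_s * rate_hz)
  with_seed(seed, {
    data <- t(vapply(seq_len(nrow(layout)), function(ci) {
      synth_channel(n, rate_hz, preset,
                    gated = layout$label[ci] %in% preset$burst_channels)
    }, numeric(n)))
  })
  rownames(data) <- layout$label
  continuous_recording(data, rate_hz, layout, events = integer(0))
}

# Evoked-response envelope on [0, dur_s]: sine ramp-up and cosine
# ramp-down of <= 25 ms each around a plateau, so the stated duration is
# the unambiguous support of the response. Zero outside the support.
evoked_envelope <- function(t, dur_s) {
  up <- min(0.025, 0.2 * dur_s)
  down <- min(0.025, 0.2 * dur_s)
  e <- numeric(length(t))
  inside <- t >= 0 & t <= dur_s
  u <- t[inside]
  ev <- rep(1, length(u))
  ev[u < up] <- sin(pi / 2 * u[u < up] / up)
  tail <- u > dur_s - down
  ev[tail] <- cos(pi / 2 * (u[tail] - (dur_s - down)) / down)
  e[inside] <- ev
  e
}

#' Simulate a stimulus-evoked session with known ground truth
#'
#' Each of `n_trials` epochs holds an independent background realisation
#' plus, at t = 0: (i) an early broadband transient (< 50 ms) on every
#' channel, with amplitude decaying with distance from the stimulation site
#' (right rostral M2); and (ii) a windowed oscillation (carrier in the
#' 5-14 Hz band) on the `evoked_spread` channels closest to the stimulation
#' site, lasting `evoked_duration` ms after a small distance-dependent
#' conduction delay. The oscillation's phase is offset per channel by a lag
#' drawn once per session (kept away from 0 and pi so genuine inter-site
#' lags survive volume-conduction screening) and jittered across trials by
#' `phase_jitter` radians.
#'
#' @inheritParams simulate_background
#' @param n_trials number of stimulation epochs (>= 2).
#' @param epoch_window epoch time span (s), half-open, containing 0.
#' @return A list with components `epochs` (an [epoch_set]) and `truth`
#'   (ground-truth list: per-channel true evoked duration in ms including
#'   the conduction delay, phase lags, amplitudes, theoretical band powers,
#'   preset and seed).
#' @export
simulate_evoked_session <- function(layout, preset, n_trials, seed = 1,
                                    rate_hz = 500,
                                    epoch_window = c(-5, 5)) {
  if (n_trials < 2) stop("n_trials must be >= 2")
  n_ch <- nrow(layout)
  if (preset$evoked_spread > n_ch)
    stop("evoked_spread exceeds the number of channels")
  unknown <- setdiff(preset$burst_channels, layout$label)
  if (length(unknown))
    stop("burst_channels not in layout: ", paste(unknown, collapse = ", "))

  n_samp <- round(diff(epoch_window) * rate_hz)
  time <- epoch_window[1] + (seq_len(n_samp) - 1) / rate_hz
  stim <- if ("M2_R R" %in% layout$label) "M2_R R" else layout$label[1]
  dist <- layout_distance(layout, stim)
  dur_s <- preset$evoked_duration / 1000

  with_seed(seed, {
    responsive <- order(dist)[seq_len(preset$evoked_spread)]
    lag <- stats::runif(n_ch, 0.4, 2.4)
    delay <- dist / 1000 * 2                     # ~2 ms per mm propagation
    amp <- preset$evoked_amp_uv * exp(-dist / 20)  # widespread response
    tr_amp <- preset$transient_amp_uv * exp(-dist / 6)
    jitter <- stats::rnorm(n_trials, 0, preset$phase_jitter)

    data <- array(0, dim = c(n_trials, n_ch, n_samp))
    for (tr in seq_len(n_trials)) {
      for (ci in seq_len(n_ch)) {
        x <- synth_channel(n_samp, rate_hz, preset,
                           gated = layout$label[ci] %in% preset$burst_channels)
        tt <- time
        if (preset$evoked_spread > 0) {      # spread 0: purely spontaneous
          trans <- ifelse(tt >= 0 & tt <= 0.05,
                          (tt / 0.008) * exp(1 - tt / 0.008), 0) * tr_amp[ci]
          x <- x + trans
        }
        if (ci %in% responsive && dur_s > 0) {
          u <- tt - delay[ci]
          x <- x + amp[ci] * evoked_envelope(u, dur_s) *
            cos(2 * pi * preset$carrier_hz * u + lag[ci] + jitter[tr])
        }
        if (ci %in% responsive && preset$late_hf_amp_uv > 0) {
          # late HF reactivation: a 35 Hz burst at 150-450 ms whose phase
          # is random per trial -- raises HF power without phase locking
          u <- tt - delay[ci] - 0.15
          x <- x + preset$late_hf_amp_uv * evoked_envelope(u, 0.3) *
            cos(2 * pi * 35 * u + stats::runif(1, -pi, pi))
        }
        data[tr, ci, ] <- x
      }
    }
  })

  # theoretical linear band powers of the background (per channel)
  fgrid <- seq(0.5, 80, by = 0.25)
  dens <- if (preset$background_exponent == 0) rep(1, length(fgrid)) else
    fgrid^preset$background_exponent
  lfm <- fgrid >= 1 & fgrid <= 4
  hfm <- fgrid >= 20 & fgrid <= 80
  gated <- layout$label %in% preset$burst_channels
  lf_pow <- mean(dens[lfm]) * preset$lf_gain^2
  hf_pow <- mean(dens[hfm]) * preset$hf_gain^2
  truth <- list(
    preset = preset, seed = seed,
    responsive = layout$label[sort(responsive)],
    true_evoked_duration_ms = ifelse(seq_len(n_ch) %in% responsive,
                                     preset$evoked_duration + delay * 1000, 0),
    lag_rad = lag, amp_uv = amp,
    true_lf_power = rep(lf_pow, n_ch) * ifelse(gated, 1.5, 1),
    true_hf_power = rep(hf_pow, n_ch) * ifelse(gated, 0.375, 1)
  )
  ep <- epoch_set(data, time, rate_hz, layout,
                  kept_trial_ids = seq_len(n_trials))
  list(epochs = ep, truth = truth)
}

#' Write a session's ground truth as a JSON sidecar
#' @param truth ground-truth list from [simulate_evoked_session()].
#' @param path output file.
#' @export
write_ground_truth <- function(truth, path) {
  truth$preset <- unclass(truth$preset)
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
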
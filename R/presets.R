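#' Condition preset for the synthetic session generator
#'
#' A preset bundles the statistical structure of one recording condition:
#' the background 1/f exponent, linear amplitude gains for the low-
#' (< 20 Hz) and high- (>= 20 Hz) frequency parts of the background, an
#' optional slow "gamma-burst" gating of HF activity on a subset of
#' channels, and the stimulus-evoked response (duration of the phase-locked
#' oscillation, number of responsive channels, across-trial phase jitter).
#'
#' @param name condition name (e.g. "W", "K1", "K2").
#' @param background_exponent spectral exponent beta of the 1/f^|beta|
#'   background (dimensionless, typically negative).
#' @param lf_gain,hf_gain linear amplitude multipliers (> 0) applied to the
#'   < 20 Hz and >= 20 Hz background components.
#' @param burst_rate rate (Hz) of the slow envelope gating HF activity on
#'   `burst_channels`; 0 disables gating.
#' @param burst_channels character vector of channel labels subject to
#'   gamma-burst gating (must be a subset of the layout when used).
#' @param evoked_duration duration (ms) of the stimulus-locked oscillatory
#'   response (>= 0).
#' @param evoked_spread number of responsive channels.
#' @param phase_jitter SD (radians) of the across-trial phase jitter of the
#'   evoked oscillation.
#' @param base_amp_uv broadband RMS amplitude (microvolts) of the background
#'   before band gains.
#' @param evoked_amp_uv peak amplitude (microvolts) of the evoked
#'   oscillation at the stimulation site.
#' @param transient_amp_uv peak amplitude (microvolts) of the early
#'   broadband transient at the stimulation site.
#' @param carrier_hz carrier frequency (Hz) of the evoked oscillation
#'   (5-14 Hz band).
#' @param late_hf_amp_uv amplitude (microvolts) of a late high-frequency
#'   (35 Hz) reactivation burst (150-450 ms post-stimulus) on responsive
#'   channels, with random phase per trial (power increase without phase
#'   locking); 0 disables it.
#' @return An object of class `condition_preset`.
#' @export
condition_preset <- function(name,
                             background_exponent = -2,
                             lf_gain = 1, hf_gain = 1,
                             burst_rate = 0,
                             burst_channels = character(0),
                             evoked_duration = 350,
                             evoked_spread = 16,
                             phase_jitter = 0.2,
                             base_amp_uv = 60,
                             evoked_amp_uv = 35,
                             transient_amp_uv = 220,
                             carrier_hz = 10,
                             late_hf_amp_uv = 0) {
  stop_if_not_scalar_pos(lf_gain, "lf_gain")
  stop_if_not_scalar_pos(hf_gain, "hf_gain")
  if (phase_jitter < 0) stop("phase_jitter must be >= 0")
  if (evoked_duration < 0) stop("evoked_duration must be >= 0")
  if (burst_rate < 0) stop("burst_rate must be >= 0")
  structure(list(
    name = name,
    background_exponent = background_exponent,
    lf_gain = lf_gain, hf_gain = hf_gain,
    burst_rate = burst_rate,
    burst_channels = as.character(burst_channels),
    evoked_duration = evoked_duration,
    evoked_spread = evoked_spread,
    phase_jitter = phase_jitter,
    base_amp_uv = base_amp_uv,
    evoked_amp_uv = evoked_amp_uv,
    transient_amp_uv = transient_amp_uv,
    carrier_hz = carrier_hz,
    late_hf_amp_uv = late_hf_amp_uv
  ), class = "condition_preset")
}

#' Built-in presets for wakefulness and two ketamine depths
#'
#' `W` emulates quiet wakefulness (1/f exponent -1.8, long phase-locked
#' response on all channels). `K1` emulates light ketamine anaesthesia:
#' the whole spectrum scales up (HF +5.1 dB, LF +4.2 dB relative to W,
#' i.e. linear amplitude gains 1.80 and 1.62) while the evoked response
#' stays long-lasting. `K2` emulates deep ketamine anaesthesia: further
#' global power increase, a short evoked response confined to fewer
#' channels, and slow gamma-burst gating of HF activity on the bilateral
#' posteromedial (RS/V2) channels, which lowers their HF/LF ratio.
#'
#' @return Named list of three [condition_preset] objects.
#' @export
ketamine_presets <- function() {
  list(
    W = condition_preset("W",
      background_exponent = -1.8, lf_gain = 1, hf_gain = 1,
      evoked_duration = 350, evoked_spread = 16, phase_jitter = 0.2,
      evoked_amp_uv = 40, late_hf_amp_uv = 30),
    K1 = condition_preset("K1",
      background_exponent = -1.4, lf_gain = 1.62, hf_gain = 1.80,
      evoked_duration = 370, evoked_spread = 15, phase_jitter = 0.2,
      evoked_amp_uv = 60, late_hf_amp_uv = 50),
    K2 = condition_preset("K2",
      background_exponent = -1.6, lf_gain = 2.04, hf_gain = 2.17,
      burst_rate = 1, burst_channels = c("RS/V2 L", "RS/V2 R"),
      evoked_duration = 150, evoked_spread = 8, phase_jitter = 0.3,
      evoked_amp_uv = 65)
  )
}

#' Read condition presets from a YAML file
#'
#' The file maps preset names to fields of [condition_preset()]; missing
#' fields take the constructor defaults.
#'
#' @param path YAML file path.
#' @return Named list of [condition_preset] objects.
#' @export
read_presets <- function(path) {
  raw <- yaml::read_yaml(path)
  out <- lapply(names(raw), function(nm) {
    do.call(condition_preset, c(list(name = nm), raw[[nm]]))
  })
  names(out) <- names(raw)
  out
}
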
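test_that("Morlet convolution is frequency selective with quadratic power", {
  ep <- sine_epochs(10, n_trials = 2, n_ch = 1, rate = 250,
                    window = c(-2, 2))
  tf <- morlet_tfr(ep, freqs = seq(2, 40, 2), n_cycles = 3)
  pw <- colMeans(Mod(tf$coeffs)^2, dims = 1)
  mid <- time_index(tf$time, c(-0.5, 0.5))
  prof <- rowMeans(pw[1, , mid])
  expect_equal(tf$freqs[which.max(prof)], 10)

  ep2 <- sine_epochs(10, n_trials = 2, n_ch = 1, rate = 250,
                     window = c(-2, 2), amp = 2)
  tf2 <- morlet_tfr(ep2, freqs = seq(2, 40, 2), n_cycles = 3)
  pw2 <- colMeans(Mod(tf2$coeffs)^2, dims = 1)
  expect_equal(max(rowMeans(pw2[1, , mid])) / max(prof), 4,
               tolerance = 1e-6)
  expect_error(morlet_tfr(ep, freqs = 1:10, n_cycles = 0.5), "n_cycles")
  expect_error(morlet_tfr(ep, freqs = c(10, 200)), "Nyquist")
})

test_that("wavelet phase advances linearly for a constant-phase tone", {
  rate <- 250
  ep <- sine_epochs(10, n_trials = 1, n_ch = 1, rate = rate,
                    window = c(-2, 2))
  tf <- morlet_tfr(ep, freqs = 10, n_cycles = 3)
  mid <- time_index(tf$time, c(-1, 1))
  ph <- Arg(tf$coeffs[1, 1, 1, mid])
  dph <- diff(ph)
  dph <- (dph + pi) %% (2 * pi) - pi           # unwrap steps
  expect_equal(mean(dph) * rate, 2 * pi * 10, tolerance = 1e-3)
})

test_that("dB normalization is definitional and scale invariant", {
  rate <- 250
  time <- seq(-2, 2 - 1 / rate, by = 1 / rate)
  # amplitude steps by sqrt(10) (x10 power) and sqrt(2) (x2 power) at t=0
  mk <- function(gain) {
    x <- cos(2 * pi * 20 * time) * ifelse(time >= 0, gain, 1)
    epochs_from_list(replicate(3, matrix(x, 1, length(time)),
                               simplify = FALSE), time, rate)
  }
  tf10 <- morlet_tfr(mk(sqrt(10)), freqs = 20, n_cycles = 3)
  pm10 <- db_power(tf10)
  post <- time_index(pm10$time, c(0.3, 1))
  pre <- time_index(pm10$time, c(-0.45, -0.25))
  expect_equal(mean(pm10$values[1, 1, post]), 10, tolerance = 0.3)
  expect_equal(mean(pm10$values[1, 1, pre]), 0, tolerance = 0.3)
  tf2 <- morlet_tfr(mk(sqrt(2)), freqs = 20, n_cycles = 3)
  expect_equal(mean(db_power(tf2)$values[1, 1, post]), 10 * log10(2),
               tolerance = 0.3)

  # rescaling the whole recording leaves dB untouched
  ep <- mk(sqrt(10))
  ep$data <- ep$data * 37.5
  tf_s <- morlet_tfr(ep, freqs = 20, n_cycles = 3)
  expect_equal(db_power(tf_s)$values, pm10$values, tolerance = 1e-9)
})

test_that("mask retains everything at alpha 1 and is monotone in alpha", {
  lay <- two_channel_layout()
  sess <- simulate_evoked_session(lay, null_preset(), 15, seed = 21,
                                  epoch_window = c(-0.9, 0.6))
  ep <- baseline_correct(sess$epochs, c(-0.8, 0))
  tf <- morlet_tfr(subset_epochs(ep, window = c(-0.7, 0.5)),
                   freqs = seq(5, 40, 5), n_cycles = 3)
  m1 <- bootstrap_mask(tf, n_perm = 150, alpha = 1)
  expect_true(all(m1$keep))
  m_lo <- bootstrap_mask(tf, n_perm = 150, alpha = 0.01, seed = 5)
  m_hi <- bootstrap_mask(tf, n_perm = 150, alpha = 0.2, seed = 5)
  expect_true(all(m_hi$keep[m_lo$keep]))       # lowering alpha adds nothing
  expect_warning(bootstrap_mask(tf, n_perm = 50, alpha = 0.05, seed = 1),
                 "unstable")
})

test_that("HF course onset follows the 0 dB crossing rule", {
  freqs <- seq(10, 80, 10)
  time <- seq(-0.5, 1 - 1 / 200, by = 1 / 200)
  vals <- array(0, dim = c(1, length(freqs), length(time)))
  pm <- structure(list(values = vals, freqs = freqs, time = time,
                       labels = "c1"), class = "power_map")
  mask <- full_mask(dim(vals))
  # flat course: no onset
  expect_true(is.na(hf_course_and_late_onset(pm, mask)$onset_ms[1]))
  # crossing at 300 ms in the HF rows
  pm$values[1, freqs >= 20, time >= 0.3] <- 3
  res <- hf_course_and_late_onset(pm, mask)
  expect_equal(unname(res$onset_ms[1]), 300, tolerance = 3)
  # crossing confined to 60 ms only: outside the 80-800 ms search window
  pm$values[] <- 0
  pm$values[1, freqs >= 20, time >= 0.055 & time <= 0.065] <- 3
  expect_true(is.na(hf_course_and_late_onset(pm, mask)$onset_ms[1]))
  # masked-out points count as 0 dB
  pm$values[1, freqs >= 20, time >= 0.3] <- 3
  mask2 <- full_mask(dim(vals))
  mask2$keep[] <- FALSE
  expect_true(is.na(hf_course_and_late_onset(pm, mask2)$onset_ms[1]))
})

test_that("ERP averaging and early RMS follow their closed forms", {
  time <- seq(-1, 1 - 1 / 500, by = 1 / 500)
  v <- matrix(rnorm(length(time)), 1)
  ep <- epochs_from_list(list(v, -v), time, 500)
  expect_true(all(abs(erp_average(ep)) < 1e-12))
  ep2 <- epochs_from_list(list(v, v, v), time, 500)
  expect_equal(unname(erp_average(ep2)[1, ]), v[1, ])

  const <- epochs_from_list(list(matrix(10, 1, length(time))), time, 500)
  expect_equal(early_response_rms(const)$mean, 10)
  # 40 Hz: two full periods in 50 ms -> rms A/sqrt(2)
  x <- 6 * sin(2 * pi * 40 * time)
  sin_ep <- epochs_from_list(list(matrix(x, 1, length(time))), time, 500)
  expect_equal(early_response_rms(sin_ep)$mean, 6 / sqrt(2),
               tolerance = 1e-6)

  # phase-jittered session: trial averaging attenuates the oscillation
  lay <- two_channel_layout()
  p <- condition_preset("j", phase_jitter = 1.2, evoked_duration = 300,
                        evoked_spread = 2, evoked_amp_uv = 300)
  sess <- simulate_evoked_session(lay, p, 20, seed = 3,
                                  epoch_window = c(-1, 1))
  ti <- time_index(sess$epochs$time, c(0.1, 0.25))
  erp_amp <- max(abs(erp_average(sess$epochs)[1, ti]))
  single_amp <- max(abs(sess$epochs$data[1, 1, ti]))
  expect_lt(erp_amp, single_amp)
})

test_that("injected late HF reactivation is detected, absent otherwise", {
  lay <- two_channel_layout()
  with_burst <- condition_preset("w", background_exponent = -1.8,
                                 evoked_duration = 350, evoked_spread = 2,
                                 phase_jitter = 0.2, late_hf_amp_uv = 30)
  without <- condition_preset("k", background_exponent = -1.8,
                              evoked_duration = 350, evoked_spread = 2,
                              phase_jitter = 0.2, late_hf_amp_uv = 0)
  detect <- function(preset, s) {
    sess <- simulate_evoked_session(lay, preset, 30, seed = s,
                                    epoch_window = c(-1.4, 1.2))
    ep <- baseline_correct(sess$epochs)
    tf <- morlet_tfr(subset_epochs(ep, channels = 1,
                                   window = c(-1.0, 1.1)), seq(2, 80, 2), 3)
    hf <- hf_course_and_late_onset(db_power(tf),
                                   bootstrap_mask(tf, n_perm = 150,
                                                  seed = s + 50))
    !is.na(hf$onset_ms[1])
  }
  hits <- vapply(1:10, function(s) detect(with_burst, s), logical(1))
  expect_gte(mean(hits), 0.9)
  misses <- vapply(1:6, function(s) detect(without, s), logical(1))
  expect_lt(mean(misses), mean(hits))
})
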
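test_that("ITPC identity and cancellation are exact", {
  rate <- 250
  time <- seq(-1, 1 - 1 / rate, by = 1 / rate)
  x <- cos(2 * pi * 10 * time)
  same <- epochs_from_list(list(matrix(x, 1), matrix(x, 1), matrix(x, 1)),
                           time, rate)
  m_same <- itpc(morlet_tfr(same, freqs = 10, n_cycles = 3))
  expect_true(all(abs(m_same$values - 1) < 1e-9))

  opp <- epochs_from_list(list(matrix(x, 1), matrix(-x, 1)), time, rate)
  m_opp <- itpc(morlet_tfr(opp, freqs = 10, n_cycles = 3))
  expect_true(all(m_opp$values < 1e-9))
})

test_that("ITPC and ISPC ignore per-channel amplitude rescaling", {
  lay <- two_channel_layout()
  sess <- simulate_evoked_session(lay, condition_preset("x",
    evoked_spread = 2, evoked_duration = 250), 8, seed = 4,
    epoch_window = c(-1, 1))
  ep <- sess$epochs
  sc <- ep
  sc$data[, 1, ] <- sc$data[, 1, ] * 7
  sc$data[, 2, ] <- sc$data[, 2, ] * 0.03
  f <- seq(6, 14, 2)
  t1 <- morlet_tfr(ep, f, 3); t2 <- morlet_tfr(sc, f, 3)
  expect_equal(itpc(t1)$values, itpc(t2)$values, tolerance = 1e-9)
  i1 <- ispc(t1, alpha = 1); i2 <- ispc(t2, alpha = 1)
  expect_equal(i1$change, i2$change, tolerance = 1e-9)
})

test_that("ITPC drop time reads the last significant point", {
  freqs <- seq(5, 40, 5)
  time <- seq(-0.6, 1 - 1 / 500, by = 1 / 500)
  vals <- array(0, dim = c(2, length(freqs), length(time)))
  map <- structure(list(values = vals, freqs = freqs, time = time,
                        labels = c("a", "b")), class = "itpc_map")
  mask <- full_mask(dim(vals))
  mask$keep[] <- FALSE
  mask$keep[1, 2, time > 0 & time <= 0.347] <- TRUE
  d <- itpc_drop_time(map, mask)
  expect_equal(d$drop_ms[1], 347, tolerance = 1.1)
  expect_equal(d$drop_ms[2], 0)                # nothing significant
  # significance beyond the limit is capped
  mask$keep[2, 3, time > 0.9] <- TRUE
  expect_equal(itpc_drop_time(map, mask)$drop_ms[2], 0)
})

test_that("ITPC mask keeps a strong phase-locked response", {
  lay <- two_channel_layout()
  det <- logical(3)
  for (s in 1:3) {
    p <- condition_preset("pl", phase_jitter = 0, evoked_duration = 300,
                          evoked_spread = 2)
    sess <- simulate_evoked_session(lay, p, 20, seed = s,
                                    epoch_window = c(-1, 1))
    tf <- morlet_tfr(baseline_correct(sess$epochs), seq(6, 14, 2), 3)
    msk <- itpc_mask(tf, n_perm = 150, seed = s)
    ti <- time_index(tf$time, c(0.08, 0.25))
    det[s] <- any(msk$keep[, , ti])
  }
  expect_true(all(det))
  tf1 <- morlet_tfr(sine_epochs(10, n_trials = 3), 10, 3)
  expect_true(all(itpc_mask(tf1, alpha = 1)$keep))
})

test_that("ISPC is symmetric, zero-lag pairs are screened out", {
  rate <- 250
  time <- seq(-1, 1 - 1 / rate, by = 1 / rate)
  set.seed(8)
  lay3 <- channel_layout(c("a", "b", "c"), 1:3, rep(0, 3))
  # a and b are duplicates (volume conduction); c lags a by pi/2 at 10 Hz
  trials <- lapply(1:12, function(i) {
    ph <- runif(1, -pi, pi)
    base <- cos(2 * pi * 10 * time + ph)
    lag <- cos(2 * pi * 10 * time + ph - pi / 2)
    rbind(base, base + rnorm(length(time), sd = 0.01), lag)
  })
  data <- array(0, dim = c(12, 3, length(time)))
  for (i in 1:12) data[i, , ] <- trials[[i]]
  ep <- epoch_set(data, time, rate, lay3, 1:12)
  tf <- morlet_tfr(ep, 10, 3)
  res <- ispc(tf, alpha = 1)
  # raw ISPC (pre-subtraction) of the constant-lag pair is 1 away from
  # the wavelet edges
  z <- tf$coeffs / Mod(tf$coeffs)
  cross <- z[, 1, 1, ] * Conj(z[, 3, 1, ])
  interior <- time_index(tf$time, c(-0.5, 0.5))
  expect_true(all(abs(Mod(colMeans(cross[, interior])) - 1) < 1e-6))

  scr <- ispc_apply_vtest(res, tf)
  fi <- 1
  ti <- time_index(tf$time, c(-0.2, 0.5))
  pair_ab <- which(scr$pairs[, 1] == 1 & scr$pairs[, 2] == 2)
  pair_ac <- which(scr$pairs[, 1] == 1 & scr$pairs[, 2] == 3)
  expect_true(all(scr$change[pair_ab, fi, ti] == 0))   # zero lag zeroed
  expect_true(any(scr$change[pair_ac, fi, ti] != 0))   # pi/2 lag kept
  sm <- connectivity_summary(scr, band = c(5, 14), window = c(0, 0.4))
  expect_equal(sm$pair_matrix, t(sm$pair_matrix))
})

test_that("independent channels yield an almost-empty ISPC mask", {
  lay <- two_channel_layout()
  frac <- vapply(1:5, function(s) {
    sess <- simulate_evoked_session(lay, null_preset(), 20, seed = s + 40,
                                    epoch_window = c(-0.9, 0.6))
    ep <- baseline_correct(sess$epochs, c(-0.8, 0))
    tf <- morlet_tfr(subset_epochs(ep, window = c(-0.7, 0.5)),
                     seq(6, 14, 2), 3)
    res <- ispc(tf, n_perm = 150, seed = s)
    ti <- time_index(tf$time, c(0, 0.3))
    mean(res$change[, , ti] != 0)
  }, numeric(1))
  expect_lt(mean(frac), 0.02)
})

test_that("v-test rejects zero lag surely and holds its level on uniform phases", {
  th0 <- matrix(0, 90, 50)
  expect_true(all(vtest_clustered(th0, 0)))
  th_orth <- matrix(pi / 2, 90, 50)
  expect_false(any(vtest_clustered(th_orth, 0)))
  expect_false(any(vtest_clustered(th_orth, pi)))
  vals <- rep(0.5, 50)
  out <- vtest_zero_pi_rejection(th0, vals)
  expect_true(all(out == 0))
  set.seed(12)
  rej <- replicate(500, vtest_clustered(runif(60, -pi, pi), 0, 0.05))
  expect_lt(abs(mean(rej) - 0.05), 0.03)
})

test_that("connectivity degree counts positive couplings", {
  labels <- paste0("e", 1:16)
  pairs <- t(utils::combn(16, 2))
  change <- array(0, dim = c(nrow(pairs), 3, 10))
  freqs <- c(6, 10, 14)
  time <- seq(0.1, 0.46, length.out = 10)
  # channel 1 positively coupled to exactly 3 of its 15 partners
  sel <- which(pairs[, 1] == 1)[1:3]
  change[sel, , ] <- 0.2
  res <- structure(list(change = change, pairs = pairs, freqs = freqs,
                        time = time, labels = labels),
                   class = "ispc_result")
  sm <- connectivity_summary(res, band = c(5, 14), window = c(0.1, 0.47))
  expect_equal(unname(sm$degree[1]), 3 / 15)
  expect_true(all(sm$degree[5:16] == 0))
  # all-zero coupling: degree 0 everywhere
  res$change[] <- 0
  expect_true(all(connectivity_summary(res, band = c(5, 14),
                                       window = c(0.1, 0.47))$degree == 0))
})
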
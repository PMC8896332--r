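make_rec <- function(x, rate, events = integer(0), n_ch = 1) {
  lay <- channel_layout(paste0("c", seq_len(n_ch)), seq_len(n_ch),
                        rep(0, n_ch))
  continuous_recording(matrix(rep(x, each = n_ch), nrow = n_ch),
                       rate, lay, events)
}

test_that("band-pass keeps in-band tones and rejects out-of-band content", {
  rate <- 10000
  t <- seq(0, 20 - 1 / rate, by = 1 / rate)
  x40 <- sin(2 * pi * 40 * t)
  x200 <- sin(2 * pi * 200 * t)
  rec <- make_rec(x40 + x200 + 100, rate, events = c(50000L, 100000L))
  out <- bandpass_downsample(rec, 0.5, 80, 3, 500)
  expect_equal(out$rate, 500)
  expect_equal(out$events, c(2500L, 5000L))
  y <- out$data[1, ]
  n <- length(y)
  sp <- Mod(fft(y))^2 / n
  f <- (seq_len(n) - 1) * 500 / n
  in40 <- sum(sp[abs(f - 40) < 1])
  in200 <- sum(sp[abs(f - 200) < 1 | abs(f - 300) < 1])
  # 40 Hz amplitude preserved within 5%
  mid <- y[round(n / 4):round(3 * n / 4)]
  expect_lt(abs(max(mid) - 1) , 0.05)
  # 200 Hz power below 1% of its input power (0.5 per unit-amp sine)
  expect_lt(in200 / in40, 0.01)
  # DC removed
  expect_lt(abs(mean(y[round(n / 4):round(3 * n / 4)])), 1)
})

test_that("in-band filtering is idempotent within 1%", {
  rate <- 2000
  t <- seq(0, 10 - 1 / rate, by = 1 / rate)
  # content well inside the 0.5-80 Hz passband; close to the band edge a
  # third-order Butterworth attenuates a few percent per pass by design
  x <- sin(2 * pi * 12 * t) + 0.7 * sin(2 * pi * 25 * t) +
    0.5 * sin(2 * pi * 40 * t)
  rec <- make_rec(x, rate)
  once <- bandpass_downsample(rec, 0.5, 80, 3, 1000)
  lay <- once$layout
  twice <- bandpass_downsample(once, 0.5, 80, 3, 1000)
  mid <- seq(round(0.25 * ncol(once$data)), round(0.75 * ncol(once$data)))
  rel <- sqrt(mean((twice$data[1, mid] - once$data[1, mid])^2)) /
    sqrt(mean(once$data[1, mid]^2))
  expect_lt(rel, 0.01)
})

test_that("epoch extraction aligns, skips truncated events, round-trips", {
  rate <- 500
  n <- 30 * rate
  x <- rnorm(n)
  ev <- c(10L, 6L * rate, 12L * rate, 20L * rate)
  x[ev[3]] <- 50                               # impulse at third event
  rec <- make_rec(x, rate, events = ev)
  expect_warning(ep <- extract_epochs(rec, c(-5, 5)), "skipped")
  expect_equal(dim(ep$data), c(3, 1, 5000))
  expect_equal(ep$kept_trial_ids, 2:4)
  i0 <- which(ep$time == 0)
  expect_equal(i0, 2501)
  expect_equal(ep$data[2, 1, i0], 50)          # alignment identity
  # sample-exact round trip of non-overlapping epochs
  expect_equal(ep$data[1, 1, ], x[(6 * rate - 2500):(6 * rate + 2499)])
  expect_equal(ep$data[3, 1, ], x[(20 * rate - 2500):(20 * rate + 2499)])
})

test_that("baseline correction zeroes the baseline mean", {
  time <- seq(-2, 2 - 1 / 100, by = 1 / 100)
  const <- epochs_from_list(list(matrix(7, 1, length(time))), time, 100)
  bc <- baseline_correct(const, c(-1, 0))
  expect_true(all(abs(bc$data) < 1e-12))

  # sinusoid with integer periods in the baseline is unchanged
  x <- sin(2 * pi * 3 * time)
  sin_ep <- epochs_from_list(list(matrix(x, 1, length(time))), time, 100)
  bs <- baseline_correct(sin_ep, c(-1, 0))
  expect_lt(max(abs(bs$data[1, 1, ] - x)), 1e-10)

  set.seed(9)
  rnd <- epochs_from_list(replicate(3, matrix(rnorm(2 * length(time)), 2),
                                    simplify = FALSE), time, 100)
  br <- baseline_correct(rnd, c(-1, 0))
  bi <- time_index(br$time, c(-1, 0))
  expect_lt(max(abs(apply(br$data[, , bi], c(1, 2), mean))), 1e-9)
  expect_error(baseline_correct(rnd, c(-10, -9)), "no samples")
})

test_that("artifact screening removes bad trials and keeps order", {
  time <- seq(-2, 2 - 1 / 100, by = 1 / 100)
  set.seed(2)
  trials <- replicate(95, matrix(rnorm(length(time), sd = 20), 1),
                      simplify = FALSE)
  spike_at <- which(time >= -0.5)[1]           # inside the (-1, 0) baseline
  trials[[7]][1, spike_at] <- 5000
  ep <- epochs_from_list(trials, time, 100)
  res <- reject_and_select(ep, artifact_rule(abs_uv = 500), n_keep = 90)
  expect_true(7 %in% res$report$removed_ids)
  expect_equal(dim(res$epochs$data)[1], 90)
  expect_false(7 %in% res$epochs$kept_trial_ids)
  expect_false(is.unsorted(res$epochs$kept_trial_ids))

  clean_trials <- trials
  clean_trials[[7]] <- matrix(rnorm(length(time), sd = 20), 1)
  clean <- epochs_from_list(clean_trials, time, 100)
  keep <- reject_and_select(clean, artifact_rule(abs_uv = 1e6,
                                                 p2p_factor = 100),
                            n_keep = 90)
  expect_equal(keep$epochs$kept_trial_ids, 1:90)

  small <- epochs_from_list(trials[1:10], time, 100)
  expect_warning(res2 <- reject_and_select(small,
    artifact_rule(abs_uv = 1e6, p2p_factor = 100), n_keep = 90),
    "clean trials")
  expect_equal(res2$report$n_kept, 10)
  expect_true(res2$report$shortfall)
  path <- tempfile(fileext = ".json")
  write_rejection_report(res2$report, path)
  expect_true(file.exists(path))
})

test_that("raw binary + JSON reader and events CSV round-trip", {
  dir <- tempdir()
  data <- matrix(rnorm(3 * 100), 3, 100)
  bin <- file.path(dir, "x.bin")
  writeBin(as.numeric(data), bin, size = 8, endian = "little")
  meta <- file.path(dir, "x.json")
  jsonlite::write_json(list(rate = 500, n_channels = 3,
                            labels = c("a", "b", "c"),
                            ap = c(1, 2, 3), ml = c(0, 0, 0),
                            dtype = "float64", scale_uv = 1,
                            events = c(10, 20)),
                       meta, auto_unbox = TRUE, digits = NA)
  rec <- read_raw_binary(bin, meta)
  expect_equal(rec$data, data, ignore_attr = TRUE)
  expect_equal(rec$events, c(10L, 20L))

  csv <- file.path(dir, "ev.csv")
  write.csv(data.frame(sample = c(30, 10, 20),
                       label = c("stim", "stim", "other")),
            csv, row.names = FALSE)
  expect_equal(read_events_csv(csv, label = "stim"), c(10L, 30L))
})

test_that("presets round-trip through YAML", {
  path <- tempfile(fileext = ".yaml")
  writeLines(c("deep:",
               "  background_exponent: -1.6",
               "  burst_rate: 1.0",
               "  evoked_duration: 150"), path)
  ps <- read_presets(path)
  expect_s3_class(ps$deep, "condition_preset")
  expect_equal(ps$deep$background_exponent, -1.6)
  expect_equal(ps$deep$evoked_duration, 150)
})
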
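#' Pipeline configuration
#'
#' Bundles every parameter of the full analysis run on synthetic sessions.
#' Defaults are desk-scale study conditions: six virtual rats, the three
#' built-in presets, 30 trials per session, 500 Hz, 1-80 Hz wavelet grid.
#'
#' @param presets named list of [condition_preset] objects.
#' @param n_rats number of virtual subjects.
#' @param n_trials trials generated per session (a margin above `n_keep`,
#'   as in a real session where extra stimuli are delivered so the first
#'   `n_keep` clean trials survive screening).
#' @param n_keep trials retained after artifact screening.
#' @param rate sampling rate (Hz).
#' @param epoch_window generated epoch span (s).
#' @param evoked_window epoch span (s) analysed time-frequency-wise; must
#'   cover the baseline window and the 0-800 ms detection range with
#'   wavelet edge margin.
#' @param freqs wavelet frequency grid (Hz).
#' @param n_perm bootstrap draws for the significance masks.
#' @param do_ispc compute pairwise connectivity (the slowest stage).
#' @param ispc_band frequency band (Hz) retained for connectivity.
#' @param seed master integer seed; every stage draws from seeds derived
#'   from it.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(presets = ketamine_presets(), n_rats = 6,
                            n_trials = 34, n_keep = 30, rate = 500,
                            epoch_window = c(-2.6, 1.2),
                            evoked_window = c(-1.0, 1.1),
                            freqs = 1:80, n_perm = 150,
                            do_ispc = TRUE, ispc_band = c(5, 14),
                            seed = 1) {
  structure(as.list(environment()), class = "pipeline_config")
}

# Polynomial rolling hash (mod 2^31 - 1) of the serialized configuration,
# for provenance tracking of pipeline outputs.
config_hash <- function(config) {
  bytes <- as.integer(serialize(unclass(config), NULL))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

# All evoked/spontaneous measures of one session. Channel-wise TFR keeps
# memory bounded; masks reuse per-stage seeds for reproducibility.
session_metrics <- function(ep, config, seed) {
  lay <- ep$layout
  n_ch <- nrow(lay)
  erp <- erp_average(ep)
  early <- early_response_rms(erp)
  pci <- pci_st(erp)
  pci_tc <- pci_st_timecourse(erp)

  drop_ms <- numeric(n_ch)
  onset_ms <- rep(NA_real_, n_ch)
  for (ci in seq_len(n_ch)) {
    tf <- morlet_tfr(subset_epochs(ep, channels = ci,
                                   window = config$evoked_window),
                     config$freqs, n_cycles = 3)
    pm <- db_power(tf)
    pmask <- bootstrap_mask(tf, n_perm = config$n_perm, alpha = 0.05,
                            seed = seed + 31L + ci)
    hf <- hf_course_and_late_onset(pm, pmask)
    onset_ms[ci] <- hf$onset_ms[1]
    imap <- itpc(tf)
    imask <- itpc_mask(tf, n_perm = config$n_perm, alpha = 0.01,
                       seed = seed + 67L + ci)
    drop_ms[ci] <- itpc_drop_time(imap, imask)$drop_ms[1]
  }

  degree <- rep(NA_real_, n_ch)
  if (config$do_ispc) {
    fsel <- config$freqs[config$freqs >= config$ispc_band[1] &
                           config$freqs <= config$ispc_band[2]]
    tf_all <- morlet_tfr(subset_epochs(ep, window = config$evoked_window),
                         fsel, n_cycles = 3)
    conn <- ispc(tf_all, n_perm = config$n_perm, alpha = 0.05,
                 seed = seed + 97L)
    conn <- ispc_apply_vtest(conn, tf_all)
    degree <- connectivity_summary(conn)$degree
  }

  spec <- prestim_spectra(ep, window = c(config$epoch_window[1], 0),
                          freqs = config$freqs)
  list(early_rms = early$mean, pci = pci$value, pci_timecourse = pci_tc,
       drop_ms = drop_ms, onset_ms = onset_ms, degree = degree,
       exponent = spec$exponent, hf_power_db = spec$hf_power_db,
       lf_power_db = spec$lf_power_db, hf_lf = spec$hf_lf)
}

#' Run the full synthetic-study pipeline
#'
#' Generates one session per virtual rat and condition preset, preprocesses
#' it (baseline correction, artifact screening, first-N retention), and
#' computes every measure of the analysis: early-response RMS, PCIst
#' (full window and sliding), significance-masked HF power course with
#' late-onset detection, ITPC drop time, connectivity degree, spontaneous
#' periodogram with spectral exponent, band powers and HF/LF ratio.
#' Group-level statistics (repeated-measures ANOVA across conditions,
#' pairwise paired t-tests with Holm correction, and the HF/LF-vs-PCIst
#' linear fits per channel) are computed on the assembled measure table.
#'
#' @param config a [pipeline_config].
#' @param output_dir optional directory; when given, the measure table and
#'   time courses are written as CSV, tests and provenance as JSON.
#' @return list: `measures` (long data frame: rat, condition, channel,
#'   measure, value), `timecourses`, `tests`, `seed`, `config_hash`.
#' @export
run_pipeline <- function(config = pipeline_config(), output_dir = NULL) {
  lay <- rat_layout()
  conds <- names(config$presets)
  rows <- list()
  tcs <- list()
  base_seed <- config$seed %% 100000L

  for (ri in seq_len(config$n_rats)) {
    for (ci in seq_along(conds)) {
      s <- base_seed * 10000L + ri * 100L + ci
      sess <- simulate_evoked_session(lay, config$presets[[ci]],
                                      n_trials = config$n_trials, seed = s,
                                      rate_hz = config$rate,
                                      epoch_window = config$epoch_window)
      ep <- baseline_correct(sess$epochs)
      ep <- reject_and_select(ep, n_keep = config$n_keep)$epochs
      m <- session_metrics(ep, config, seed = s)
      rat <- paste0("rat", ri)
      glob <- data.frame(
        rat = rat, condition = conds[ci], channel = "global",
        measure = c("pci", "early_rms", "exponent", "itpc_drop_ms",
                    "hf_power_db", "lf_power_db", "late_hf_pct"),
        value = c(m$pci, m$early_rms, m$exponent, mean(m$drop_ms),
                  mean(m$hf_power_db), mean(m$lf_power_db),
                  100 * mean(!is.na(m$onset_ms))),
        stringsAsFactors = FALSE)
      perch <- data.frame(
        rat = rat, condition = conds[ci],
        channel = rep(lay$label, times = 3 + config$do_ispc),
        measure = rep(c("hf_lf", "itpc_drop_ms", "hf_power_db",
                        if (config$do_ispc) "degree"),
                      each = nrow(lay)),
        value = c(m$hf_lf, m$drop_ms, m$hf_power_db,
                  if (config$do_ispc) m$degree),
        stringsAsFactors = FALSE)
      rows[[length(rows) + 1L]] <- rbind(glob, perch)
      tc <- m$pci_timecourse
      tc$rat <- rat; tc$condition <- conds[ci]
      tcs[[length(tcs) + 1L]] <- tc
    }
  }
  measures <- do.call(rbind, rows)
  timecourses <- do.call(rbind, tcs)
  tests <- pipeline_tests(measures, conds)
  out <- list(measures = measures, timecourses = timecourses, tests = tests,
              seed = config$seed, config_hash = config_hash(config))
  if (!is.null(output_dir)) {
    dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(measures, file.path(output_dir, "measures.csv"),
                     row.names = FALSE)
    utils::write.csv(timecourses, file.path(output_dir, "timecourses.csv"),
                     row.names = FALSE)
    jsonlite::write_json(
      list(seed = out$seed, config_hash = out$config_hash,
           tests = lapply(tests, function(x)
             if (is.data.frame(x)) x else unclass(x))),
      file.path(output_dir, "tests.json"), auto_unbox = TRUE, digits = NA,
      force = TRUE)
  }
  out
}

# Group-level inferential layer on the assembled measure table. Tests
# that are infeasible for a degenerate design (single condition, too few
# subjects) are skipped rather than fatal.
pipeline_tests <- function(measures, conds) {
  glob <- function(meas) {
    measures[measures$channel == "global" & measures$measure == meas, ]
  }
  try_test <- function(expr) tryCatch(expr, error = function(e) NULL)
  tests <- list()
  if (length(conds) < 2) return(tests)
  for (meas in c("pci", "itpc_drop_ms", "hf_power_db")) {
    d <- glob(meas)
    tests[[paste0("anova_", meas)]] <- try_test(
      rm_anova(d, dv = "value", subject = "rat", within = "condition"))
    pr <- utils::combn(conds, 2, simplify = FALSE)
    pt <- try_test({
      rows <- lapply(pr, function(p) {
        a <- d$value[d$condition == p[1]][order(d$rat[d$condition == p[1]])]
        b <- d$value[d$condition == p[2]][order(d$rat[d$condition == p[2]])]
        cbind(paired_t(a, b), contrast = paste(p, collapse = " vs "))
      })
      rows <- do.call(rbind, rows)
      hb <- holm_bonferroni(rows$p)
      rows$p_adjusted <- hb$p_adjusted
      rows$correction <- "holm"
      rows
    })
    tests[[paste0("paired_t_", meas)]] <- pt
  }
  # regional activation vs complexity, across rats x conditions
  pci <- glob("pci")
  key <- paste(pci$rat, pci$condition)
  for (ch in c("RS/V2 L", "RS/V2 R", "M2_C R")) {
    hl <- measures[measures$channel == ch & measures$measure == "hf_lf", ]
    hl <- hl[match(key, paste(hl$rat, hl$condition)), ]
    nm <- paste0("linfit_hf_lf_", gsub("[ /]", "_", ch))
    tests[[nm]] <- try_test(linfit_r2_test(hl$value, pci$value))
  }
  tests
}
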
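#' Trial-average event-related potential
#' @param ep an [epoch_set] with at least one trial.
#' @return channels x time matrix of the mean ERP (microvolts), with the
#'   time axis as an attribute.
#' @export
erp_average <- function(ep) {
  stopifnot(dim(ep$data)[1] >= 1)
  erp <- colMeans(ep$data, dims = 1)
  rownames(erp) <- ep$layout$label
  attr(erp, "time") <- ep$time
  erp
}

#' Early-response RMS amplitude
#'
#' Root-mean-square of the mean ERP over the early window, per channel,
#' plus the unweighted cross-channel mean — an index of the initial
#' cortical excitation evoked by the stimulus.
#'
#' @param erp channels x time matrix from [erp_average()] (time attribute
#'   required) or an [epoch_set].
#' @param window seconds pair, default the first 50 ms.
#' @return list with `per_channel` (named numeric, microvolts) and `mean`.
#' @export
early_response_rms <- function(erp, window = c(0, 0.05)) {
  if (inherits(erp, "epoch_set")) erp <- erp_average(erp)
  time <- attr(erp, "time")
  if (is.null(time)) stop("erp must carry a time attribute")
  wi <- time_index(time, window)
  if (!length(wi)) stop("window contains no samples")
  per_ch <- apply(erp[, wi, drop = FALSE], 1, rms)
  list(per_channel = per_ch, mean = mean(per_ch))
}

#' Baseline-normalized spectral power in dB
#'
#' Trial-mean wavelet power divided by its trial-mean baseline power per
#' channel and frequency, in decibels: 0 dB means power equal to the
#' baseline mean. Invariant to rescaling the whole recording by a positive
#' constant.
#'
#' @param tfr a [morlet_tfr()] result.
#' @param baseline seconds pair inside the pre-stimulus epoch
#'   (default -500 to -200 ms).
#' @return An object of class `power_map` (`values`: channels x
#'   frequencies x time, dB).
#' @export
db_power <- function(tfr, baseline = c(-0.5, -0.2)) {
  bi <- time_index(tfr$time, baseline)
  if (!length(bi)) stop("baseline window contains no samples")
  if (baseline[2] > 0) stop("baseline must be pre-stimulus")
  bvi <- baseline_valid_index(tfr, bi)
  pw <- colMeans(Mod(tfr$coeffs)^2, dims = 1)          # ch x f x t
  base <- vapply(seq_along(tfr$freqs), function(fi) {
    rowMeans(pw[, fi, bvi[[fi]], drop = FALSE], dims = 1)
  }, numeric(dim(pw)[1]))
  base <- matrix(base, dim(pw)[1], length(tfr$freqs))
  if (any(base <= 0)) stop("zero baseline power")
  values <- 10 * log10(pw / as.vector(base))
  structure(list(values = values, freqs = tfr$freqs, time = tfr$time,
                 baseline = baseline, labels = tfr$labels,
                 edge_samples = tfr$edge_samples),
            class = "power_map")
}

# n_draw x n_tr matrix of bootstrap trial weights (counts / n_tr).
boot_weights <- function(n_draw, n_tr) {
  W <- matrix(0, n_draw, n_tr)
  for (i in seq_len(n_draw))
    W[i, ] <- tabulate(sample.int(n_tr, n_tr, replace = TRUE), n_tr) / n_tr
  W
}

# Bootstrap null of the max/min of per-draw surrogate baseline maps,
# handled per frequency so each frequency uses only its edge-valid
# baseline samples. `Ms` is a per-frequency list of trials x
# (n_cell * nb_f) matrices (real power, or complex unit phase vectors);
# statf(fi, m) maps a draw's trial-mean matrix (n_cell x nb_f) to
# surrogate values. Each draw resamples trials with replacement (shared
# across frequencies) and then baseline time points within the draw.
# Returns maxs/mins as n_perm x (n_cell * n_freq) matrices, cell fastest.
boot_maxmin_freq <- function(Ms, n_cell, n_perm, statf, chunk = 100L,
                             second_norm = FALSE) {
  n_tr <- nrow(Ms[[1]])
  n_f <- length(Ms)
  maxs <- matrix(NA_real_, n_perm, n_cell * n_f)
  mins <- matrix(NA_real_, n_perm, n_cell * n_f)
  done <- 0L
  while (done < n_perm) {
    k <- min(chunk, n_perm - done)
    W <- boot_weights(k, n_tr)
    W2 <- if (second_norm) boot_weights(k, n_tr)
    for (fi in seq_len(n_f)) {
      R <- W %*% Ms[[fi]]                       # k x (n_cell*nb_f)
      R2 <- if (second_norm) W2 %*% Ms[[fi]]
      nb <- ncol(Ms[[fi]]) / n_cell
      cols <- (fi - 1L) * n_cell + seq_len(n_cell)
      for (i in seq_len(k)) {
        norm <- if (second_norm) rowMeans(matrix(R2[i, ], n_cell, nb))
        vals <- statf(fi, matrix(R[i, ], n_cell, nb), norm)
        ti <- sample.int(nb, nb, replace = TRUE)
        v <- vals[, ti, drop = FALSE]
        maxs[done + i, cols] <- v[cbind(seq_len(n_cell),
                                        max.col(v, ties.method = "first"))]
        mins[done + i, cols] <- -(-v)[cbind(seq_len(n_cell),
                                            max.col(-v, ties.method = "first"))]
      }
    }
    done <- done + k
  }
  list(maxs = maxs, mins = mins)
}

new_significance_mask <- function(keep, alpha, n_perm, tail,
                                  thr_hi = NULL, thr_lo = NULL,
                                  family = "map") {
  structure(list(keep = keep, alpha = alpha, n_permutations = n_perm,
                 tail = tail, thr_hi = thr_hi, thr_lo = thr_lo,
                 family = family),
            class = "significance_mask")
}

# Per-cell thresholds at the requested family scope. "cell": plain
# per-cell quantiles of the per-draw extremes (control over time only,
# per channel/frequency). "map": each cell's null extremes are
# standardized by their own mean and SD (cells differ strongly in null
# scale, e.g. by wavelet temporal smoothing), the per-draw worst
# standardized extreme across cells forms the map-wide null, and its
# quantile is mapped back to a threshold per cell. This controls the
# any-point error over the whole map while letting every cell keep its
# own null scale; unlike remapping extreme per-cell quantiles, the two
# moments per cell are stable at a few hundred draws.
# Returns list(hi, lo): per-cell thresholds (lo = NULL for upper tail).
family_thresholds <- function(mm, alpha, tail, family) {
  p_hi <- if (tail == "two") 1 - alpha / 2 else 1 - alpha
  p_lo <- alpha / 2
  if (family == "cell") {
    hi <- apply(mm$maxs, 2, stats::quantile, probs = p_hi, names = FALSE)
    lo <- if (tail == "two")
      apply(mm$mins, 2, stats::quantile, probs = p_lo, names = FALSE)
    return(list(hi = hi, lo = lo))
  }
  mu_hi <- colMeans(mm$maxs)
  s_hi <- pmax(apply(mm$maxs, 2, stats::sd), .Machine$double.eps)
  u_hi <- apply(scale(mm$maxs, mu_hi, s_hi), 1, max)
  hi <- mu_hi + stats::quantile(u_hi, probs = p_hi, names = FALSE) * s_hi
  lo <- NULL
  if (tail == "two") {
    mu_lo <- colMeans(mm$mins)
    s_lo <- pmax(apply(mm$mins, 2, stats::sd), .Machine$double.eps)
    u_lo <- apply(scale(mm$mins, mu_lo, s_lo), 1, min)
    lo <- mu_lo + stats::quantile(u_lo, probs = p_lo, names = FALSE) * s_lo
  }
  list(hi = hi, lo = lo)
}

#' Bootstrap max/min-statistic significance mask for dB power
#'
#' Builds, per channel and frequency, a null distribution of the largest
#' and smallest surrogate-baseline dB values: each of `n_perm` draws
#' resamples trials with replacement, forms the surrogate dB map over the
#' baseline window (time points resampled within the draw), and records its
#' maximum and minimum. The observed dB map is thresholded at the
#' `alpha/2` upper quantile of the maxima and `alpha/2` lower quantile of
#' the minima (two-sided); values between the thresholds are masked out.
#' Wavelet edge samples are always masked out.
#'
#' @param tfr a [morlet_tfr()] result.
#' @param baseline seconds pair (default -500 to -200 ms).
#' @param n_perm number of bootstrap draws (default 500; < 100 warns).
#' @param alpha family-wise level (default 0.05); `alpha >= 1` retains
#'   everything.
#' @param tail "two" (default) or "upper".
#' @param family scope of the max-statistic family: "map" (default)
#'   pools each draw's extreme over all channels, frequencies and
#'   baseline samples, controlling the any-point error over the whole
#'   map; "cell" thresholds each channel/frequency separately (control
#'   over time only).
#' @param seed optional integer seed for the draws.
#' @return A `significance_mask` with `keep` of shape channels x
#'   frequencies x time.
#' @export
bootstrap_mask <- function(tfr, baseline = c(-0.5, -0.2), n_perm = 500,
                           alpha = 0.05, tail = c("two", "upper"),
                           family = c("map", "cell"), seed = NULL) {
  tail <- match.arg(tail)
  family <- match.arg(family)
  if (n_perm < 100) warning("n_perm < 100: unstable threshold quantiles")
  pm <- db_power(tfr, baseline)
  d <- dim(tfr$coeffs)
  n_tr <- d[1]; n_ch <- d[2]; n_f <- d[3]
  if (alpha >= 1) {
    keep <- array(TRUE, dim = dim(pm$values))
    return(new_significance_mask(keep, alpha, n_perm, tail))
  }
  bi <- time_index(tfr$time, baseline)
  bvi <- baseline_valid_index(tfr, bi)
  # surrogate maps are dB deviations of the resampled trial-mean from the
  # observed per-point baseline mean: a bootstrap of the sampling noise of
  # the baseline map, whose extremes give the max-statistic null
  Ms <- lapply(seq_len(n_f), function(fi) {
    matrix(Mod(tfr$coeffs[, , fi, bvi[[fi]], drop = FALSE])^2,
           n_tr, n_ch * length(bvi[[fi]]))
  })
  obs <- lapply(Ms, function(m) {
    matrix(colMeans(m), n_ch, ncol(m) / n_ch)
  })
  # the second, independent trial resample supplies the sampling noise of
  # the per-cell baseline normalization, which shifts the whole observed
  # map and would otherwise be missing from the pointwise deviations
  obs_norm <- lapply(obs, rowMeans)
  statf <- function(fi, m, norm) {
    10 * log10(m / obs[[fi]]) + 10 * log10(obs_norm[[fi]] / norm)
  }
  run <- function() boot_maxmin_freq(Ms, n_ch, n_perm, statf,
                                     second_norm = TRUE)
  mm <- if (is.null(seed)) run() else with_seed(seed, run())
  thr <- family_thresholds(mm, alpha, tail, family)
  # per-cell thresholds (channel fastest) recycle over time
  keep <- pm$values > array(thr$hi, dim = dim(pm$values))
  if (tail == "two")
    keep <- keep | pm$values < array(thr$lo, dim = dim(pm$values))
  keep <- keep & tfr_valid_samples(tfr)
  new_significance_mask(keep, alpha, n_perm, tail, thr$hi, thr$lo, family)
}

#' HF-band time course and late-onset detection
#'
#' Averages the significance-masked dB power over the high-frequency band
#' (masked-out points contribute 0 dB, i.e. no variation) to obtain a per-
#' channel HF time course, then reports the first time in the search
#' window where the course exceeds 0 dB — the onset of late HF
#' (re)activation; `NA` when the course never crosses 0 dB there.
#'
#' @param pm a [db_power()] map.
#' @param mask the matching `significance_mask`.
#' @param hf frequency band (Hz), default 20-80.
#' @param search onset search window (s), default 80-800 ms.
#' @return list with `course` (channels x time, dB), `time`, and
#'   `onset_ms` (named per-channel onset, ms, NA if none).
#' @export
hf_course_and_late_onset <- function(pm, mask, hf = c(20, 80),
                                     search = c(0.08, 0.8)) {
  fi <- which(pm$freqs >= hf[1] & pm$freqs <= hf[2])
  if (!length(fi)) stop("hf band outside the frequency grid")
  vals <- pm$values
  vals[!mask$keep] <- 0
  course <- apply(vals[, fi, , drop = FALSE], c(1, 3), mean)
  rownames(course) <- pm$labels
  si <- time_index(pm$time, search)
  onset <- apply(course[, si, drop = FALSE], 1, function(x) {
    j <- which(x > 0)
    if (!length(j)) NA_real_ else pm$time[si[j[1]]] * 1000
  })
  list(course = course, time = pm$time, onset_ms = onset)
}
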
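# unit phase vectors of the wavelet coefficients
unit_phase <- function(coeffs) {
  z <- coeffs / Mod(coeffs)
  z[!is.finite(z)] <- 0 + 0i
  z
}

cplx_mean_over_trials <- function(z) {
  colMeans(Re(z), dims = 1) + 1i * colMeans(Im(z), dims = 1)
}

#' Inter-trial phase clustering (ITPC)
#'
#' Resultant length of the across-trial unit phase vectors at every
#' channel, frequency and time point: 1 means perfectly phase-locked
#' trials, values near `sqrt(pi)/(2 sqrt(n))` are the chance level for `n`
#' trials with uniform phases. A phase-only statistic: invariant to any
#' per-channel amplitude rescaling.
#'
#' @param tfr a [morlet_tfr()] result with at least two trials.
#' @return An object of class `itpc_map` (`values` in [0, 1], channels x
#'   frequencies x time).
#' @export
itpc <- function(tfr) {
  stopifnot(dim(tfr$coeffs)[1] >= 2)
  values <- Mod(cplx_mean_over_trials(unit_phase(tfr$coeffs)))
  structure(list(values = values, freqs = tfr$freqs, time = tfr$time,
                 n_trials = dim(tfr$coeffs)[1], labels = tfr$labels,
                 edge_samples = tfr$edge_samples),
            class = "itpc_map")
}

#' Bootstrap max-statistic mask for ITPC
#'
#' Upper-tail analogue of [bootstrap_mask()]: each draw resamples trials
#' with replacement, computes surrogate ITPC over the baseline window
#' (time points resampled within the draw) and records the maximum per
#' channel and frequency; observed ITPC above the `1 - alpha` quantile of
#' these maxima is retained.
#'
#' @inheritParams bootstrap_mask
#' @param alpha level (default 0.01).
#' @return A `significance_mask`.
#' @export
itpc_mask <- function(tfr, baseline = c(-0.5, -0.2), n_perm = 500,
                      alpha = 0.01, family = c("map", "cell"),
                      seed = NULL) {
  family <- match.arg(family)
  if (n_perm < 100) warning("n_perm < 100: unstable threshold quantiles")
  map <- itpc(tfr)
  if (alpha >= 1)
    return(new_significance_mask(array(TRUE, dim = dim(map$values)),
                                 alpha, n_perm, "upper"))
  bi <- time_index(tfr$time, baseline)
  if (baseline[2] > 0) stop("baseline must be pre-stimulus")
  bvi <- baseline_valid_index(tfr, bi)
  d <- dim(tfr$coeffs)
  n_tr <- d[1]; n_ch <- d[2]; n_f <- d[3]
  Ms <- lapply(seq_len(n_f), function(fi) {
    matrix(unit_phase(tfr$coeffs[, , fi, bvi[[fi]], drop = FALSE]),
           n_tr, n_ch * length(bvi[[fi]]))
  })
  statf <- function(fi, m, norm) Mod(m)
  run <- function() boot_maxmin_freq(Ms, n_ch, n_perm, statf)
  mm <- if (is.null(seed)) run() else with_seed(seed, run())
  thr <- family_thresholds(mm, alpha, "upper", family)
  keep <- map$values > array(thr$hi, dim = dim(map$values))
  keep <- keep & tfr_valid_samples(tfr)
  new_significance_mask(keep, alpha, n_perm, "upper", thr_hi = thr$hi,
                        family = family)
}

#' ITPC drop time
#'
#' Latest post-stimulus time (ms) with any significant ITPC in the band,
#' capped at `limit`; 0 when nothing is significant. This is the duration
#' of the deterministic, phase-locked part of the evoked response.
#'
#' @param map an [itpc()] map.
#' @param mask the matching `significance_mask`.
#' @param band frequency band (Hz), default 5-80.
#' @param limit latest time considered (s), default 800 ms.
#' @return data frame with columns `channel` and `drop_ms`.
#' @export
itpc_drop_time <- function(map, mask, band = c(5, 80), limit = 0.8) {
  fi <- which(map$freqs >= band[1] & map$freqs <= band[2])
  if (!length(fi)) stop("band outside the frequency grid")
  ti <- which(map$time > 0 & map$time <= limit + 1e-12)
  drop <- vapply(seq_along(map$labels), function(ci) {
    sig <- mask$keep[ci, fi, ti, drop = FALSE]
    any_t <- apply(sig, 3, any)
    if (!any(any_t)) 0 else map$time[ti[max(which(any_t))]] * 1000
  }, numeric(1))
  data.frame(channel = map$labels, drop_ms = drop, stringsAsFactors = FALSE)
}

#' Inter-site phase clustering (ISPC) change from baseline
#'
#' For every channel pair, the consistency across trials of the phase
#' difference (resultant length of `exp(i(phi_a - phi_b))`), minus its
#' mean over the baseline window per frequency, thresholded by a two-sided
#' bootstrap max/min-statistic null as for power. Sub-threshold values are
#' set to 0. The result is symmetric in the pair by construction.
#'
#' @inheritParams bootstrap_mask
#' @return An object of class `ispc_result`: `change` (pairs x
#'   frequencies x time, masked, 0 where not significant), `pairs`
#'   (2-column index matrix), axes and labels.
#' @export
ispc <- function(tfr, baseline = c(-0.5, -0.2), n_perm = 500, alpha = 0.05,
                 family = c("map", "cell"), seed = NULL) {
  family <- match.arg(family)
  d <- dim(tfr$coeffs)
  n_tr <- d[1]; n_ch <- d[2]; n_f <- d[3]; n_t <- d[4]
  if (n_ch < 2) stop("ISPC needs at least two channels")
  bi <- time_index(tfr$time, baseline)
  bvi <- baseline_valid_index(tfr, bi)
  pairs <- t(utils::combn(n_ch, 2))
  z <- unit_phase(tfr$coeffs)
  valid <- tfr_valid_samples(tfr)[1, , ]                 # f x t, same per ch
  change <- array(0, dim = c(nrow(pairs), n_f, n_t))
  run <- function() {
    for (p in seq_len(nrow(pairs))) {
      a <- pairs[p, 1]; b <- pairs[p, 2]
      cross <- z[, a, , , drop = FALSE] * Conj(z[, b, , , drop = FALSE])
      cross <- array(cross, dim = c(n_tr, n_f, n_t))
      raw <- Mod(cplx_mean_over_trials(cross))           # f x t
      base_mean <- vapply(seq_len(n_f), function(fi) {
        mean(raw[fi, bvi[[fi]]])
      }, numeric(1))
      ch_p <- raw - base_mean
      if (alpha < 1) {
        Ms <- lapply(seq_len(n_f), function(fi) {
          matrix(cross[, fi, bvi[[fi]]], n_tr, length(bvi[[fi]]))
        })
        obs <- lapply(seq_len(n_f), function(fi) {
          matrix(raw[fi, bvi[[fi]]], 1)     # bootstrap of deviations
        })
        statf <- function(fi, m, norm) Mod(m) - obs[[fi]]
        mm <- boot_maxmin_freq(Ms, 1L, n_perm, statf)
        thr <- family_thresholds(mm, alpha, "two", family)
        keep <- (ch_p > thr$hi | ch_p < thr$lo) & valid
        ch_p[!keep] <- 0
      }
      change[p, , ] <- ch_p
    }
    change
  }
  change <- if (is.null(seed)) run() else with_seed(seed, run())
  structure(list(change = change, pairs = pairs, freqs = tfr$freqs,
                 time = tfr$time, labels = tfr$labels, alpha = alpha,
                 n_permutations = n_perm, baseline = baseline),
            class = "ispc_result")
}

#' Gaussian v-test for phase clustering at a known mean direction
#'
#' Tests whether circular observations cluster around `mu` using
#' `V = mean(cos(theta - mu))` and the statistic `u = V * sqrt(2 n)`,
#' compared with the standard normal upper quantile — the large-sample
#' form of the modified Rayleigh test.
#'
#' @param theta numeric vector (or trials x points matrix) of phase
#'   differences in radians.
#' @param mu hypothesised mean direction (radians).
#' @param alpha_v test level.
#' @return Logical (per column for matrix input): TRUE when clustering at
#'   `mu` is significant.
#' @export
vtest_clustered <- function(theta, mu, alpha_v = 0.05) {
  theta <- as.matrix(theta)
  n <- nrow(theta)
  if (n < 2) stop("v-test needs at least two observations")
  V <- colMeans(cos(theta - mu))
  V * sqrt(2 * n) > stats::qnorm(1 - alpha_v)
}

#' Reject zero- or pi-lag (volume-conducted) phase coupling
#'
#' Applies the Gaussian v-test at mean directions 0 and pi to the
#' across-trial phase-difference distribution of each point; points with
#' significant clustering at either direction — the signature of volume
#' conduction from a common source — are set to 0.
#'
#' @param theta trials x points matrix of phase differences (radians).
#' @param values numeric vector of ISPC values at the same points.
#' @param alpha_v level per tested direction (default 0.05).
#' @return `values` with volume-conducted points set to 0; the rejection
#'   flags are returned as attribute `rejected`.
#' @export
vtest_zero_pi_rejection <- function(theta, values, alpha_v = 0.05) {
  rej <- vtest_clustered(theta, 0, alpha_v) |
    vtest_clustered(theta, pi, alpha_v)
  values[rej] <- 0
  attr(values, "rejected") <- rej
  values
}

#' Apply volume-conduction screening to an ISPC result
#'
#' For every pair and every retained (non-zero) time-frequency point, the
#' across-trial phase differences are tested for clustering at 0 or pi
#' with [vtest_zero_pi_rejection()]; clustered points are zeroed.
#'
#' @param res an [ispc()] result.
#' @param tfr the [morlet_tfr()] the result was computed from.
#' @param alpha_v level per tested direction.
#' @return The modified `ispc_result`.
#' @export
ispc_apply_vtest <- function(res, tfr, alpha_v = 0.05) {
  z <- unit_phase(tfr$coeffs)
  d <- dim(tfr$coeffs)
  for (p in seq_len(nrow(res$pairs))) {
    sel <- which(res$change[p, , ] != 0)
    if (!length(sel)) next
    a <- res$pairs[p, 1]; b <- res$pairs[p, 2]
    cross <- array(z[, a, , , drop = FALSE] * Conj(z[, b, , , drop = FALSE]),
                   dim = c(d[1], d[3], d[4]))
    theta <- Arg(matrix(cross, d[1], d[3] * d[4])[, sel, drop = FALSE])
    plane <- res$change[p, , ]
    plane[sel] <- vtest_zero_pi_rejection(theta, plane[sel], alpha_v)
    res$change[p, , ] <- plane
  }
  res
}

#' Pairwise connectivity matrix and per-channel degree
#'
#' Averages the (masked, volume-conduction-screened) ISPC change over a
#' frequency band and post-stimulus window, arranges the means as a
#' symmetric channel x channel matrix, and defines each channel's
#' connectivity degree as the proportion of other channels with a positive
#' mean — the breadth of its significant phase coupling.
#'
#' @param res an [ispc()] (optionally [ispc_apply_vtest()]-screened)
#'   result.
#' @param band frequency band (Hz), default 5-14.
#' @param window post-stimulus window (s), default 180-400 ms.
#' @return An `ispc_summary`: `pair_matrix` (symmetric, zero diagonal) and
#'   `degree` (named, in [0, 1]).
#' @export
connectivity_summary <- function(res, band = c(5, 14),
                                 window = c(0.18, 0.40)) {
  fi <- which(res$freqs >= band[1] & res$freqs <= band[2])
  ti <- time_index(res$time, window)
  if (!length(fi) || !length(ti)) stop("band/window outside the axes")
  n_ch <- length(res$labels)
  pm <- matrix(0, n_ch, n_ch, dimnames = list(res$labels, res$labels))
  for (p in seq_len(nrow(res$pairs))) {
    m <- mean(res$change[p, fi, ti])
    pm[res$pairs[p, 1], res$pairs[p, 2]] <- m
    pm[res$pairs[p, 2], res$pairs[p, 1]] <- m
  }
  degree <- vapply(seq_len(n_ch), function(i) {
    sum(pm[i, -i] > 0) / (n_ch - 1)
  }, numeric(1))
  names(degree) <- res$labels
  structure(list(pair_matrix = pm, degree = degree, band = band,
                 window = window), class = "ispc_summary")
}
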
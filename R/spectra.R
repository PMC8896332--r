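#' Spontaneous-EEG spectral summary from pre-stimulus epochs
#'
#' Morlet wavelet power (default 6 cycles, 80 linearly spaced wavelets,
#' 1-80 Hz) averaged over samples of the pre-stimulus window and over
#' trials, per channel, giving a per-channel periodogram and its channel
#' average (the global periodogram). From these it derives the 20-40 Hz
#' log-log spectral exponent, low- (1-4 Hz) and high- (20-80 Hz) frequency
#' band powers (linear and dB re 1) and the per-channel linear HF/LF
#' ratio, an index of local cortical activation.
#'
#' Wavelet edge samples are trimmed from the averaging window, but at most
#' a quarter of the window per side so very low frequencies remain
#' estimable in short epochs.
#'
#' @param ep an [epoch_set] whose time axis covers the window.
#' @param window pre-stimulus seconds pair (default -5 to 0).
#' @param freqs frequency grid (Hz).
#' @param n_cycles wavelet cycles (default 6).
#' @param hf,lf band limits (Hz) for the activation ratio.
#' @return An object of class `spectrum_summary`.
#' @export
prestim_spectra <- function(ep, window = c(-5, 0), freqs = 1:80,
                            n_cycles = 6, hf = c(20, 80), lf = c(1, 4)) {
  if (window[2] > 0) stop("window must be pre-stimulus")
  d <- dim(ep$data)
  n_tr <- d[1]; n_ch <- d[2]
  wi <- time_index(ep$time, window)
  if (!length(wi)) stop("window contains no samples")
  n_win <- length(wi)
  sigma_t <- n_cycles / (2 * pi * freqs)
  edge <- pmin(ceiling(3 * sigma_t * ep$rate), floor(n_win / 4))
  perio <- matrix(NA_real_, n_ch, length(freqs),
                  dimnames = list(ep$layout$label, NULL))
  for (ci in seq_len(n_ch)) {
    tf <- morlet_tfr(subset_epochs(ep, channels = ci, window = window),
                     freqs, n_cycles)
    pw <- Mod(tf$coeffs)^2
    pw <- array(pw, dim = c(n_tr, length(freqs), n_win))
    perio[ci, ] <- vapply(seq_along(freqs), function(fi) {
      use <- seq.int(edge[fi] + 1L, n_win - edge[fi])
      mean(pw[, fi, use])
    }, numeric(1))
  }
  global <- colMeans(perio)
  lfm <- freqs >= lf[1] & freqs <= lf[2]
  hfm <- freqs >= hf[1] & freqs <= hf[2]
  lf_lin <- rowMeans(perio[, lfm, drop = FALSE])
  hf_lin <- rowMeans(perio[, hfm, drop = FALSE])
  structure(list(
    periodogram = perio, periodogram_db = lin2db(perio),
    global_periodogram = global, freqs = freqs,
    exponent = spectral_exponent(global, freqs),
    lf_power = lf_lin, hf_power = hf_lin,
    lf_power_db = lin2db(lf_lin), hf_power_db = lin2db(hf_lin),
    hf_lf = hf_lin / lf_lin,
    bands = list(lf = lf, hf = hf),
    labels = ep$layout$label
  ), class = "spectrum_summary")
}

#' Spectral exponent: log-log slope of the periodogram
#'
#' Least-squares slope of log10(power) against log10(frequency) over the
#' fitted band (default 20-40 Hz); the exponent of the 1/f background —
#' more negative means steeper spectral decay.
#'
#' @param power linear power values on `freqs` (or a `spectrum_summary`,
#'   whose global periodogram is used).
#' @param freqs frequency grid (Hz).
#' @param band fitted band (Hz).
#' @return The slope (dimensionless).
#' @export
spectral_exponent <- function(power, freqs, band = c(20, 40)) {
  if (inherits(power, "spectrum_summary")) {
    freqs <- power$freqs
    power <- power$global_periodogram
  }
  sel <- freqs >= band[1] & freqs <= band[2]
  if (!any(sel)) stop("band outside the frequency grid")
  if (any(power[sel] <= 0)) stop("non-positive power in the fitted band")
  unname(stats::coef(stats::lm(log10(power[sel]) ~ log10(freqs[sel])))[2])
}

#' Per-channel HF/LF activation ratio
#'
#' Mean linear power in the high-frequency band divided by mean linear
#' power in the low-frequency band, per channel (band means taken on the
#' linear scale, before any dB conversion). Invariant to overall amplitude
#' scaling; drops when a channel's slow activity grows relative to its
#' fast activity — the signature of local cortical deactivation.
#'
#' @param summary a `spectrum_summary` (or a channels x frequencies linear
#'   periodogram matrix, with `freqs`).
#' @param hf,lf band limits (Hz).
#' @param freqs frequency grid, required for matrix input.
#' @return Named per-channel linear ratio.
#' @export
hf_lf_ratio <- function(summary, hf = c(20, 80), lf = c(1, 4),
                        freqs = NULL) {
  if (inherits(summary, "spectrum_summary")) {
    perio <- summary$periodogram
    freqs <- summary$freqs
  } else {
    perio <- summary
    if (is.null(freqs)) stop("freqs required for matrix input")
  }
  lfm <- freqs >= lf[1] & freqs <= lf[2]
  hfm <- freqs >= hf[1] & freqs <= hf[2]
  if (!any(lfm) || !any(hfm)) stop("bands outside the frequency grid")
  lf_lin <- rowMeans(perio[, lfm, drop = FALSE])
  if (any(lf_lin == 0)) stop("zero LF power")
  rowMeans(perio[, hfm, drop = FALSE]) / lf_lin
}

#' Harmonic (Laplace) interpolation of channel values over the skull
#'
#' Solves the discrete Laplace equation on a regular grid covering the
#' electrode positions, with the electrode nodes held at their channel
#' values (Dirichlet anchors) and reflecting (Neumann) outer boundaries.
#' The interpolant is exact at electrode sites and harmonic elsewhere; a
#' constant input yields a constant field, and mirror-symmetric inputs on
#' a mirror-symmetric layout yield a mirror-symmetric field. A
#' visualization aid only — statistics always consume channel values.
#'
#' @param values named per-channel values (names matching the layout) or
#'   a bare numeric vector in layout order.
#' @param layout a [channel_layout].
#' @param n_grid grid resolution along the larger axis (default 41).
#' @param margin border (mm) added around the electrodes.
#' @return list with `field` (matrix over `ml` x `ap` grid), `ap`, `ml`.
#' @export
topographic_map <- function(values, layout, n_grid = 41, margin = 1) {
  if (nrow(layout) < 3) stop("need at least 3 channels")
  if (anyDuplicated(layout[, c("ap", "ml")]))
    stop("duplicate electrode coordinates")
  if (!is.null(names(values))) values <- values[layout$label]
  stopifnot(length(values) == nrow(layout), all(is.finite(values)))

  ml_half <- max(abs(layout$ml)) + margin
  ap_r <- range(layout$ap) + c(-margin, margin)
  n_ml <- if (n_grid %% 2 == 1) n_grid else n_grid + 1   # symmetric about 0
  ml_g <- seq(-ml_half, ml_half, length.out = n_ml)
  n_ap <- n_grid
  ap_g <- seq(ap_r[1], ap_r[2], length.out = n_ap)

  idx <- function(i, j) (j - 1L) * n_ml + i              # i over ml, j over ap
  anchor <- integer(nrow(layout))
  for (e in seq_len(nrow(layout))) {
    i <- which.min(abs(ml_g - layout$ml[e]))
    j <- which.min(abs(ap_g - layout$ap[e]))
    anchor[e] <- idx(i, j)
  }
  if (anyDuplicated(anchor)) stop("grid too coarse: electrodes collide")

  n_node <- n_ml * n_ap
  trip_i <- trip_j <- integer(0)
  trip_x <- numeric(0)
  b <- numeric(n_node)
  is_anchor <- logical(n_node)
  is_anchor[anchor] <- TRUE
  for (j in seq_len(n_ap)) {
    for (i in seq_len(n_ml)) {
      v <- idx(i, j)
      if (is_anchor[v]) {
        trip_i <- c(trip_i, v); trip_j <- c(trip_j, v); trip_x <- c(trip_x, 1)
        b[v] <- values[match(v, anchor)]
      } else {
        nb <- c(if (i > 1) idx(i - 1, j), if (i < n_ml) idx(i + 1, j),
                if (j > 1) idx(i, j - 1), if (j < n_ap) idx(i, j + 1))
        trip_i <- c(trip_i, v, rep(v, length(nb)))
        trip_j <- c(trip_j, v, nb)
        trip_x <- c(trip_x, length(nb), rep(-1, length(nb)))
      }
    }
  }
  A <- Matrix::sparseMatrix(i = trip_i, j = trip_j, x = trip_x,
                            dims = c(n_node, n_node))
  x <- as.numeric(Matrix::solve(A, b))
  list(field = matrix(x, n_ml, n_ap, dimnames = NULL), ml = ml_g, ap = ap_g)
}
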
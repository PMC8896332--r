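#' Morlet wavelet time-frequency decomposition
#'
#' Convolves every trial and channel with complex Morlet wavelets (unit
#' energy, `n_cycles` cycles, Gaussian SD `n_cycles / (2 pi f)` in time),
#' via FFT. Squared magnitude of the coefficients is power; the argument is
#' instantaneous phase. Samples within 3 wavelet SDs of either epoch edge
#' are recorded per frequency (`edge_samples`) and excluded from downstream
#' statistics windows.
#'
#' @param ep an [epoch_set].
#' @param freqs strictly increasing frequency grid (Hz), below Nyquist.
#' @param n_cycles wavelet cycles (>= 1).
#' @return An object of class `tfr`: complex coefficient array
#'   trials x channels x frequencies x time, plus axes and edge widths.
#' @export
morlet_tfr <- function(ep, freqs = 1:80, n_cycles = 3) {
  if (n_cycles < 1) stop("n_cycles must be >= 1")
  if (is.unsorted(freqs, strictly = TRUE))
    stop("freqs must be strictly increasing")
  if (max(freqs) >= ep$rate / 2) stop("max frequency must be below Nyquist")
  d <- dim(ep$data)
  n_tr <- d[1]; n_ch <- d[2]; n_t <- d[3]
  rate <- ep$rate
  sigma_t <- n_cycles / (2 * pi * freqs)
  half <- ceiling(4 * sigma_t * rate)
  nfft <- stats::nextn(n_t + 2 * max(half), 2)

  wf <- matrix(0 + 0i, nfft, length(freqs))
  for (fi in seq_along(freqs)) {
    tv <- (-half[fi]:half[fi]) / rate
    w <- exp(2i * pi * freqs[fi] * tv) * exp(-tv^2 / (2 * sigma_t[fi]^2))
    w <- w / sqrt(sum(Mod(w)^2))
    pad <- complex(nfft)
    pad[seq_along(w)] <- w
    wf[, fi] <- stats::fft(pad)
  }

  coeffs <- array(0 + 0i, dim = c(n_tr, n_ch, length(freqs), n_t))
  xpad <- matrix(0, nfft, n_tr)
  for (ci in seq_len(n_ch)) {
    xpad[] <- 0
    xpad[seq_len(n_t), ] <- t(matrix(ep$data[, ci, ], nrow = n_tr))
    X <- stats::mvfft(xpad)
    for (fi in seq_along(freqs)) {
      y <- stats::mvfft(X * wf[, fi], inverse = TRUE) / nfft
      coeffs[, ci, fi, ] <- t(y[(half[fi] + 1):(half[fi] + n_t), ,
                                drop = FALSE])
    }
  }
  structure(list(coeffs = coeffs, freqs = freqs, n_cycles = n_cycles,
                 time = ep$time, rate = rate,
                 edge_samples = pmin(ceiling(3 * sigma_t * rate), n_t),
                 labels = ep$layout$label, layout = ep$layout),
            class = "tfr")
}

# Per-frequency index vector of baseline samples unaffected by wavelet
# edges; falls back to the full window when the wavelet does not fit (such
# frequencies are edge-masked out of the final result anyway).
baseline_valid_index <- function(tfr, bi) {
  n_t <- length(tfr$time)
  lapply(seq_along(tfr$freqs), function(fi) {
    e <- tfr$edge_samples[fi]
    v <- bi[bi > e & bi <= n_t - e]
    if (length(v) < 2) bi else v
  })
}

# Logical channels x freqs x time array flagging non-edge samples.
tfr_valid_samples <- function(tfr) {
  n_t <- length(tfr$time)
  n_ch <- length(tfr$labels)
  ok <- array(TRUE, dim = c(n_ch, length(tfr$freqs), n_t))
  for (fi in seq_along(tfr$freqs)) {
    e <- tfr$edge_samples[fi]
    if (e > 0) {
      lo <- seq_len(min(e, n_t))
      hi <- seq.int(max(1L, n_t - e + 1L), n_t)
      ok[, fi, c(lo, hi)] <- FALSE
    }
  }
  ok
}
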
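#' Parameters for the state-transition perturbational complexity index
#'
#' Defaults follow the rodent perturbational protocol: 99% of response
#' variance retained, component signal-to-noise floor 1.1, baseline
#' transition weighting k = 1.2, 100 thresholds scanned, no time-delay
#' embedding. The baseline window matches the response window in length
#' (600 ms) with a 50 ms pre-stimulus guard.
#'
#' @param baseline_window pre-stimulus seconds pair.
#' @param response_window post-stimulus seconds pair.
#' @param max_var percentage of response-window variance retained (0-100].
#' @param min_snr component SNR floor (response RMS / baseline RMS).
#' @param k baseline transition weighting (> 0).
#' @param n_steps thresholds scanned per component (>= 2).
#' @param embed optional `c(dimension, lag)` time-delay embedding; `NULL`
#'   (default) disables it.
#' @return An object of class `pci_params`.
#' @export
pci_params <- function(baseline_window = c(-0.65, -0.05),
                       response_window = c(0, 0.6),
                       max_var = 99, min_snr = 1.1, k = 1.2,
                       n_steps = 100, embed = NULL) {
  stopifnot(max_var > 0, max_var <= 100, k > 0, n_steps >= 2,
            baseline_window[2] <= response_window[1],
            baseline_window[2] <= 0)
  structure(list(baseline_window = baseline_window,
                 response_window = response_window,
                 max_var = max_var, min_snr = min_snr, k = k,
                 n_steps = n_steps, embed = embed), class = "pci_params")
}

#' Principal-component decomposition of the evoked response
#'
#' SVD of the response-window ERP (channels x time): components are
#' ordered by singular value; the retained set is the smallest prefix
#' explaining at least `max_var`% of the response-window variance, then
#' filtered by component SNR (response RMS / baseline RMS) above
#' `min_snr`. Retained spatial patterns are projected over the full epoch.
#'
#' @param erp channels x time mean ERP with a `time` attribute, or an
#'   [epoch_set].
#' @param params a [pci_params].
#' @return list: `components` (retained components x time), `singular`
#'   (retained singular values), `snr`, `n_components`, `time`.
#' @export
decompose_response <- function(erp, params = pci_params()) {
  if (inherits(erp, "epoch_set")) erp <- erp_average(erp)
  time <- attr(erp, "time")
  if (is.null(time)) stop("erp must carry a time attribute")
  if (nrow(erp) < 2) stop("need at least two channels")
  ri <- time_index(time, params$response_window)
  bi <- time_index(time, params$baseline_window)
  if (!length(ri) || !length(bi)) stop("degenerate analysis windows")
  resp <- erp[, ri, drop = FALSE]
  empty <- list(components = matrix(0, 0, ncol(erp)), singular = numeric(0),
                snr = numeric(0), n_components = 0L, time = time)
  if (all(abs(resp) < .Machine$double.eps)) return(empty)
  sv <- svd(resp)
  var_exp <- cumsum(sv$d^2) / sum(sv$d^2) * 100
  n_keep <- which(var_exp >= params$max_var)[1]
  comps <- t(sv$u[, seq_len(n_keep), drop = FALSE]) %*% erp  # over full epoch
  snr <- vapply(seq_len(n_keep), function(i) {
    rms(comps[i, ri]) / rms(comps[i, bi])
  }, numeric(1))
  sel <- snr > params$min_snr
  list(components = comps[sel, , drop = FALSE],
       singular = sv$d[seq_len(n_keep)][sel],
       snr = snr[sel], n_components = sum(sel), time = time)
}

#' Normalized state-transition count of a component
#'
#' For each threshold epsilon, the number of sample pairs (t, t') in the
#' window whose absolute amplitude difference exceeds epsilon, normalized
#' by the squared number of window samples. Monotone non-increasing in
#' epsilon; at epsilon = 0 it equals the fraction of unequal pairs.
#'
#' @param x numeric component time course (the window samples, >= 2).
#' @param thresholds numeric vector of epsilon values (>= 0).
#' @return NST values, one per threshold.
#' @export
state_transitions <- function(x, thresholds) {
  n <- length(x)
  if (n < 2) stop("window must have at least 2 samples")
  d <- sort(abs(x[rep(seq_len(n - 1), times = (n - 1):1)] -
                  x[unlist(lapply(seq_len(n - 1), function(i) (i + 1):n))]))
  counts <- length(d) - findInterval(thresholds, d)
  2 * counts / n^2
}

#' State-transition perturbational complexity index (PCIst)
#'
#' Decomposes the ERP into principal components
#' ([decompose_response()]); for each retained component, scans `n_steps`
#' thresholds spanning the component's pairwise-distance range and
#' evaluates `dNST(eps) = NST_response(eps) - k * NST_baseline(eps)`; the
#' component contributes its maximum dNST (floored at 0) scaled by the
#' number of response-window samples. PCIst is the sum of contributions:
#' 0 for a flat ERP, invariant to positive rescaling of the whole ERP.
#'
#' @inheritParams decompose_response
#' @return An object of class `pci_result`: `value`, per-component
#'   diagnostics (`singular`, `snr`, `dnst_max`, `eps_star`), and
#'   `n_components`.
#' @export
pci_st <- function(erp, params = pci_params()) {
  dec <- decompose_response(erp, params)
  time <- dec$time
  ri <- time_index(time, params$response_window)
  bi <- time_index(time, params$baseline_window)
  if (length(ri) < 2 || length(bi) < 2) stop("degenerate analysis windows")
  n_comp <- dec$n_components
  if (n_comp == 0)
    return(structure(list(value = 0, contributions = numeric(0),
                          singular = numeric(0), snr = numeric(0),
                          dnst_max = numeric(0), eps_star = numeric(0),
                          n_components = 0L), class = "pci_result"))
  contributions <- dnst_max <- eps_star <- numeric(n_comp)
  # pairwise distances of (optionally time-delay-embedded) window samples
  pair_dists <- function(y) {
    if (is.null(params$embed)) return(sort(stats::dist(y)))
    L <- params$embed[1]; lag <- params$embed[2]
    if (L < 1 || lag < 1) stop("invalid embedding")
    n <- length(y) - (L - 1) * lag
    if (n < 2) stop("window too short for the requested embedding")
    emb <- vapply(seq_len(L), function(j) y[(1:n) + (j - 1) * lag],
                  numeric(n))
    sort(stats::dist(emb))
  }
  nst_from_dists <- function(d, thresholds) {
    n <- (1 + sqrt(1 + 8 * length(d))) / 2       # window samples
    2 * (length(d) - findInterval(thresholds, d)) / n^2
  }
  for (i in seq_len(n_comp)) {
    y_r <- dec$components[i, ri]
    y_b <- dec$components[i, bi]
    d_r <- pair_dists(y_r)
    d_b <- pair_dists(y_b)
    eps_max <- max(d_r[length(d_r)], d_b[length(d_b)])
    eps <- seq(0, eps_max, length.out = params$n_steps)
    dnst <- nst_from_dists(d_r, eps) - params$k * nst_from_dists(d_b, eps)
    j <- which.max(dnst)
    dnst_max[i] <- max(dnst[j], 0)
    eps_star[i] <- eps[j]
    contributions[i] <- dnst_max[i] * length(ri)
  }
  structure(list(value = sum(contributions), contributions = contributions,
                 singular = dec$singular, snr = dec$snr,
                 dnst_max = dnst_max, eps_star = eps_star,
                 n_components = n_comp), class = "pci_result")
}

#' PCIst time course in sliding response windows
#'
#' Recomputes PCIst in short windows tiling the full response (default
#' 100 ms windows stepping by 50 ms over 0-600 ms, giving 11 windows),
#' against the same pre-stimulus baseline; component contributions are
#' scaled by each window's own sample count, so unequal window lengths
#' are normalized consistently.
#'
#' @inheritParams decompose_response
#' @param win window length (s).
#' @param step window step (s).
#' @return data frame with `t_start`, `t_end` (s) and `pci`.
#' @export
pci_st_timecourse <- function(erp, params = pci_params(), win = 0.1,
                              step = 0.05) {
  r <- params$response_window
  starts <- seq(r[1], r[2] - win + 1e-12, by = step)
  out <- data.frame(t_start = starts, t_end = starts + win, pci = NA_real_)
  for (i in seq_along(starts)) {
    p_i <- params
    p_i$response_window <- c(starts[i], starts[i] + win)
    out$pci[i] <- pci_st(erp, p_i)$value
  }
  out
}
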
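#' Continuous multichannel recording
#'
#' @param data channels x samples voltage matrix (microvolts).
#' @param rate sampling rate (Hz, > 0).
#' @param layout a [channel_layout] matching the rows of `data`.
#' @param events integer vector of stimulus onset sample indices (1-based),
#'   strictly increasing and within the record.
#' @return An object of class `continuous_recording`.
#' @export
continuous_recording <- function(data, rate, layout, events = integer(0)) {
  stopifnot(is.matrix(data), rate > 0, nrow(data) == nrow(layout))
  events <- as.integer(events)
  if (length(events)) {
    if (is.unsorted(events, strictly = TRUE))
      stop("events must be strictly increasing")
    if (min(events) < 1L || max(events) > ncol(data))
      stop("events must lie within the record")
  }
  structure(list(data = data, rate = rate, layout = layout, events = events),
            class = "continuous_recording")
}

#' Stimulus-aligned epoch set
#'
#' @param data trials x channels x time array (microvolts).
#' @param time time axis in seconds, stimulus at 0.
#' @param rate sampling rate (Hz).
#' @param layout a [channel_layout].
#' @param kept_trial_ids sorted unique ids of the retained trials.
#' @return An object of class `epoch_set`.
#' @export
epoch_set <- function(data, time, rate, layout, kept_trial_ids) {
  stopifnot(length(dim(data)) == 3, dim(data)[3] == length(time),
            dim(data)[2] == nrow(layout))
  kept_trial_ids <- as.integer(kept_trial_ids)
  if (anyDuplicated(kept_trial_ids) || is.unsorted(kept_trial_ids))
    stop("kept_trial_ids must be sorted and unique")
  structure(list(data = data, time = time, rate = rate, layout = layout,
                 kept_trial_ids = kept_trial_ids),
            class = "epoch_set")
}

#' Subset an epoch set by trial, channel or time window
#' @param ep an [epoch_set].
#' @param trials,channels indices (channels may be labels).
#' @param window optional half-open time window (s).
#' @return The subsetted [epoch_set].
#' @export
subset_epochs <- function(ep, trials = NULL, channels = NULL, window = NULL) {
  tr <- if (is.null(trials)) seq_len(dim(ep$data)[1]) else trials
  ch <- if (is.null(channels)) seq_len(dim(ep$data)[2]) else channels
  if (is.character(ch)) ch <- match(ch, ep$layout$label)
  ti <- if (is.null(window)) seq_along(ep$time) else time_index(ep$time, window)
  lay <- ep$layout[ch, , drop = FALSE]
  class(lay) <- class(ep$layout)
  epoch_set(ep$data[tr, ch, ti, drop = FALSE], ep$time[ti], ep$rate, lay,
            kept_trial_ids = ep$kept_trial_ids[tr])
}

#' Band-pass filter and downsample a continuous recording
#'
#' Zero-phase (forward-backward) Butterworth filtering of the stated order,
#' applied in two numerically stable stages: the low-pass edge at the
#' original rate (which also serves as the anti-alias filter), integer
#' decimation to `target_rate`, then the high-pass edge at the target rate.
#' Event indices are rescaled onto the decimated grid.
#'
#' @param rec a [continuous_recording].
#' @param low,high band edges in Hz (0 < low < high < Nyquist).
#' @param order Butterworth order (per edge).
#' @param target_rate output rate (Hz); `rec$rate` must be an integer
#'   multiple of it.
#' @return The filtered, decimated [continuous_recording].
#' @export
bandpass_downsample <- function(rec, low = 0.5, high = 80, order = 3,
                                target_rate = 500) {
  stopifnot(low > 0, high > low, target_rate <= rec$rate)
  if (high >= target_rate / 2)
    stop("high edge must be below the Nyquist of target_rate")
  if (high >= rec$rate / 2) stop("high edge must be below the input Nyquist")
  k <- rec$rate / target_rate
  if (abs(k - round(k)) > 1e-9)
    stop("rate must be an integer multiple of target_rate")
  k <- as.integer(round(k))

  lp <- signal::butter(order, high / (rec$rate / 2), type = "low")
  out <- t(apply(rec$data, 1, function(x) signal::filtfilt(lp, x)))
  if (k > 1L) out <- out[, seq(1L, ncol(out), by = k), drop = FALSE]
  hp <- signal::butter(order, low / (target_rate / 2), type = "high")
  out <- t(apply(out, 1, function(x) signal::filtfilt(hp, x)))
  rownames(out) <- rownames(rec$data)
  events <- as.integer(floor((rec$events - 1L) / k) + 1L)
  continuous_recording(out, target_rate, rec$layout, events)
}

#' Extract stimulus-centred epochs
#'
#' One epoch per event over the half-open window `[window[1], window[2])`
#' seconds; the sample at t = 0 is the event sample. Events whose window
#' would be truncated by the record edges are skipped with a warning.
#'
#' @param rec a [continuous_recording] with events.
#' @param window seconds pair, `window[1] <= 0 < window[2]`.
#' @return An [epoch_set]; `kept_trial_ids` are the indices of the used
#'   events.
#' @export
extract_epochs <- function(rec, window = c(-5, 5)) {
  stopifnot(window[1] <= 0, window[2] > 0)
  n_pre <- round(-window[1] * rec$rate)
  n_tot <- round(diff(window) * rec$rate)
  n <- ncol(rec$data)
  ok <- rec$events - n_pre >= 1L & rec$events - n_pre + n_tot - 1L <= n
  if (!all(ok))
    warning(sum(!ok), " event(s) skipped: window extends beyond the record")
  ev <- rec$events[ok]
  if (!length(ev)) stop("no event has a full window inside the record")
  data <- array(0, dim = c(length(ev), nrow(rec$data), n_tot))
  for (i in seq_along(ev)) {
    idx <- (ev[i] - n_pre):(ev[i] - n_pre + n_tot - 1L)
    data[i, , ] <- rec$data[, idx]
  }
  time <- window[1] + (seq_len(n_tot) - 1) / rec$rate
  epoch_set(data, time, rec$rate, rec$layout, kept_trial_ids = which(ok))
}

#' Baseline-correct epochs
#'
#' Subtracts, per trial and channel, the mean voltage over the half-open
#' baseline window.
#'
#' @param ep an [epoch_set].
#' @param baseline seconds pair inside the epoch (default -1 to 0 s).
#' @return The corrected [epoch_set].
#' @export
baseline_correct <- function(ep, baseline = c(-1, 0)) {
  bi <- time_index(ep$time, baseline)
  if (!length(bi)) stop("baseline window contains no samples")
  bl <- apply(ep$data[, , bi, drop = FALSE], c(1, 2), mean)
  ep$data <- ep$data - as.vector(bl)   # recycles over the time dimension
  ep
}

#' Artifact rejection rule
#'
#' A trial is rejected when, in its baseline window on any channel, the
#' absolute voltage exceeds `abs_uv`, or the peak-to-peak amplitude exceeds
#' `p2p_factor` times the median peak-to-peak across trials.
#'
#' @param abs_uv absolute-voltage threshold (microvolts).
#' @param p2p_factor multiple of the across-trial median peak-to-peak.
#' @param baseline baseline window (s) the rule inspects.
#' @return An object of class `artifact_rule`.
#' @export
artifact_rule <- function(abs_uv = 500, p2p_factor = 6, baseline = c(-1, 0)) {
  structure(list(abs_uv = abs_uv, p2p_factor = p2p_factor,
                 baseline = baseline), class = "artifact_rule")
}

#' Reject artifact trials and retain the first clean ones
#'
#' Removes trials whose baseline violates the rule, then keeps the first
#' `n_keep` survivors in their original temporal order. If fewer survive,
#' all are kept and the report is flagged (not an error).
#'
#' @param ep an [epoch_set].
#' @param criterion an [artifact_rule].
#' @param n_keep number of trials to retain (default 90).
#' @return A list with `epochs` (the selected [epoch_set]) and `report`
#'   (removed ids, reasons, shortfall flag).
#' @export
reject_and_select <- function(ep, criterion = artifact_rule(), n_keep = 90) {
  stopifnot(n_keep >= 1)
  bi <- time_index(ep$time, criterion$baseline)
  if (!length(bi)) stop("rule baseline window contains no samples")
  base <- ep$data[, , bi, drop = FALSE]
  n_tr <- dim(base)[1]
  max_abs <- apply(base, 1, function(x) max(abs(x)))
  p2p <- apply(base, 1, function(x) {
    m <- matrix(x, nrow = dim(base)[2])
    max(apply(m, 1, function(ch) diff(range(ch))))
  })
  bad_abs <- max_abs > criterion$abs_uv
  bad_p2p <- p2p > criterion$p2p_factor * stats::median(p2p)
  bad <- bad_abs | bad_p2p
  survivors <- which(!bad)
  kept <- survivors[seq_len(min(n_keep, length(survivors)))]
  reasons <- ifelse(bad_abs[bad], "abs_voltage", "peak_to_peak")
  report <- structure(list(
    removed_ids = ep$kept_trial_ids[which(bad)],
    reasons = reasons,
    n_requested = n_keep,
    n_kept = length(kept),
    shortfall = length(survivors) < n_keep
  ), class = "rejection_report")
  if (report$shortfall)
    warning("only ", length(survivors), " clean trials available (requested ",
            n_keep, ")")
  list(epochs = subset_epochs(ep, trials = kept), report = report)
}

#' Write a rejection report as JSON
#' @param report a `rejection_report`.
#' @param path output file.
#' @export
write_rejection_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a raw binary recording with a JSON metadata sidecar
#'
#' The metadata file must provide `rate`, `n_channels`, channel `labels`,
#' coordinates `ap`/`ml`, the binary sample format (`dtype`:
#' "float64"/"float32"/"int16", `scale_uv` per count) and, optionally,
#' `events` (sample indices). Samples are stored channel-interleaved.
#'
#' @param bin_path binary data file.
#' @param meta_path JSON metadata file.
#' @return A [continuous_recording].
#' @export
read_raw_binary <- function(bin_path, meta_path) {
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  size <- switch(meta$dtype, float64 = 8L, float32 = 4L, int16 = 2L,
                 stop("unsupported dtype: ", meta$dtype))
  what <- if (meta$dtype == "int16") integer() else numeric()
  n_val <- file.size(bin_path) / size
  con <- file(bin_path, "rb")
  on.exit(close(con))
  x <- readBin(con, what, n = n_val, size = size, endian = "little")
  scale <- if (is.null(meta$scale_uv)) 1 else meta$scale_uv
  data <- matrix(as.numeric(x) * scale, nrow = meta$n_channels)
  layout <- channel_layout(meta$labels, meta$ap, meta$ml)
  events <- if (is.null(meta$events)) integer(0) else as.integer(meta$events)
  continuous_recording(data, meta$rate, layout, events)
}

#' Read stimulus events from a two-column CSV (sample, label)
#' @param path CSV file with columns `sample` and `label`.
#' @param label optional label to filter on.
#' @return Integer vector of event sample indices.
#' @export
read_events_csv <- function(path, label = NULL) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("sample", "label") %in% names(tab)))
    stop("events CSV must have columns `sample` and `label`")
  if (!is.null(label)) tab <- tab[tab$label == label, , drop = FALSE]
  sort(as.integer(tab$sample))
}
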
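# Shared fixture builders: everything is generated in code at test time.

two_channel_layout <- function() {
  channel_layout(c("a", "b"), ap = c(0, 0), ml = c(-1, 1))
}

null_preset <- function(...) {
  condition_preset("null", background_exponent = -1.5,
                   evoked_duration = 0, evoked_spread = 0, ...)
}

# epoch_set holding given per-trial channel x time matrices
epochs_from_list <- function(trials, time, rate, layout = NULL) {
  n_ch <- nrow(trials[[1]])
  if (is.null(layout))
    layout <- channel_layout(paste0("ch", seq_len(n_ch)),
                             ap = seq_len(n_ch), ml = rep(0, n_ch))
  data <- array(0, dim = c(length(trials), n_ch, length(time)))
  for (i in seq_along(trials)) data[i, , ] <- trials[[i]]
  epoch_set(data, time, rate, layout, seq_along(trials))
}

# epochs of a pure sinusoid, identical across trials/channels
sine_epochs <- function(freq, n_trials = 4, n_ch = 2, rate = 250,
                       window = c(-1, 1), amp = 1, phase = 0) {
  time <- seq(window[1], window[2] - 1 / rate, by = 1 / rate)
  x <- amp * cos(2 * pi * freq * time + phase)
  epochs_from_list(replicate(n_trials, matrix(x, n_ch, length(time),
                                              byrow = TRUE),
                             simplify = FALSE), time, rate)
}

# hand-built significance mask retaining everything
full_mask <- function(dims) {
  structure(list(keep = array(TRUE, dim = dims), alpha = 1,
                 n_permutations = 0, tail = "two"),
            class = "significance_mask")
}
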
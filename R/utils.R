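#' @keywords internal
"_PACKAGE"

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Indices of time points in the half-open window [w[1], w[2]).
time_index <- function(time, window) {
  stopifnot(length(window) == 2, window[2] > window[1])
  which(time >= window[1] - 1e-12 & time < window[2] - 1e-12)
}

rms <- function(x) sqrt(mean(x^2))

lin2db <- function(x) 10 * log10(x)

stop_if_not_scalar_pos <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0)
    stop(sprintf("`%s` must be a positive finite scalar", name), call. = FALSE)
}
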
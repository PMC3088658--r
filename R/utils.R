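# Internal helpers shared across modules.

# Run `code` under a fixed seed without disturbing the caller's RNG state.
# seed = NULL runs the code as-is.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L)
  withr::with_seed(as.integer(seed), code)
}

# Gaussian differential entropy in bits for variance `v` (units^2).
gaussian_entropy_bits <- function(v) {
  0.5 * log2(2 * pi * exp(1) * v)
}

# Discrete Shannon entropy (bits) of a probability vector; zero bins ignored.
discrete_entropy_bits <- function(p) {
  p <- p[p > 0]
  -sum(p * log2(p))
}

# Half-open binning [lo, hi): index of the bin containing x on a uniform grid.
bin_index <- function(x, width, origin = 0) {
  as.integer(floor((x - origin) / width)) + 1L
}

assert_spikes <- function(spikes) {
  if (!is.data.frame(spikes) || !all(c("trial_id", "time_ms") %in% names(spikes))) {
    abort("spike data must be a data frame with columns `trial_id` and `time_ms`")
  }
  invisible(spikes)
}

spike_duration <- function(spikes, duration_ms = NULL) {
  duration_ms %||% attr(spikes, "duration_ms") %||% max(spikes$time_ms)
}
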
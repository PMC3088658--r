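#' Generate a band-limited Gaussian white-noise stimulus
#'
#' Produces an air-particle-velocity waveform emulating the stimulation used
#' for cercal-system interneurons: Gaussian white noise band-passed to
#' 10--200 Hz and scaled to a target RMS amplitude of ~74 mm/s. Band-limiting
#' is done by frequency-domain masking with a raised-cosine transition of at
#' most 5 Hz on each edge, followed by RMS renormalization, so the marginal
#' stays Gaussian and in-band power is spectrally flat.
#'
#' @param duration_ms Stimulus length in milliseconds (> 0).
#' @param rate_hz Sampling rate in Hz (default 10000).
#' @param band Two-element numeric, pass band in Hz (default `c(10, 200)`).
#' @param rms Target root-mean-square amplitude in mm/s (default 74).
#' @param seed Optional integer seed; the same seed yields the identical
#'   waveform. The caller's RNG state is left untouched.
#'
#' @return An object of class `stimulus`: a list with `samples` (mm/s),
#'   `rate_hz`, `band`, and `rms`.
#' @examples
#' s <- generate_stimulus(1000, seed = 1)
#' sqrt(mean(s$samples^2))
#' @export
generate_stimulus <- function(duration_ms, rate_hz = 10000, band = c(10, 200),
                              rms = 74, seed = NULL) {
  if (!is.numeric(duration_ms) || length(duration_ms) != 1 || duration_ms <= 0) {
    abort("`duration_ms` must be a single positive number")
  }
  if (length(band) != 2 || band[1] <= 0 || band[2] <= band[1] ||
      band[2] >= rate_hz / 2) {
    abort("`band` must satisfy 0 < low < high < rate_hz/2")
  }
  n <- round(duration_ms * rate_hz / 1000)
  if (n < 8) abort("stimulus too short for band-limiting")

  white <- with_seed(seed, rnorm(n))
  samples <- band_limit(white, rate_hz, band, transition_hz = 5)
  samples <- samples * (rms / sqrt(mean(samples^2)))

  structure(
    list(samples = samples, rate_hz = rate_hz, band = band, rms = rms),
    class = "stimulus")
}

# Frequency-domain band-pass with raised-cosine edges (width `transition_hz`,
# placed just outside the pass band so the band itself is untouched).
band_limit <- function(x, rate_hz, band, transition_hz = 5) {
  n <- length(x)
  f <- seq(0, rate_hz, length.out = n + 1)[seq_len(n)]
  f <- pmin(f, rate_hz - f) # two-sided frequency magnitude
  lo <- band[1]; hi <- band[2]; tw <- transition_hz
  mask <- numeric(n)
  mask[f >= lo & f <= hi] <- 1
  rise <- f >= lo - tw & f < lo
  mask[rise] <- 0.5 * (1 + cos(pi * (lo - f[rise]) / tw))
  fall <- f > hi & f <= hi + tw
  mask[fall] <- 0.5 * (1 + cos(pi * (f[fall] - hi) / tw))
  Re(fft(fft(x) * mask, inverse = TRUE)) / n
}

#' @export
print.stimulus <- function(x, ...) {
  cat(sprintf(
    "<stimulus> %.1f s at %d Hz, band %g-%g Hz, RMS %.1f (target %.1f) mm/s\n",
    length(x$samples) / x$rate_hz, x$rate_hz, x$band[1], x$band[2],
    sqrt(mean(x$samples^2)), x$rms))
  invisible(x)
}

#' @method as_tibble stimulus
#' @export
as_tibble.stimulus <- function(x, ...) {
  tibble::tibble(
    time_ms = (seq_along(x$samples) - 1) * 1000 / x$rate_hz,
    velocity = x$samples)
}

#' @rdname generate_stimulus
#' @param object A `stimulus`.
#' @param window_ms Time span to draw (from the start), default 1000 ms.
#' @param ... Unused.
#' @method autoplot stimulus
#' @export
autoplot.stimulus <- function(object, window_ms = 1000, ...) {
  df <- as_tibble.stimulus(object)
  df <- df[df$time_ms <= window_ms, ]
  ggplot2::ggplot(df, ggplot2::aes(.data$time_ms, .data$velocity)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "time (ms)", y = "velocity (mm/s)")
}

# Stimulus value at arbitrary times (ms) by nearest-sample lookup.
stimulus_at <- function(stim, times_ms) {
  idx <- pmin(pmax(round(times_ms * stim$rate_hz / 1000) + 1, 1),
              length(stim$samples))
  stim$samples[idx]
}

#' Resample a stimulus at 1 kHz
#'
#' Takes every k-th sample so that the returned series is sampled at 1 kHz
#' (safe because the waveform is band-limited well below 500 Hz). Used when
#' building pattern-conditioned stimulus models.
#'
#' @param stim A `stimulus`.
#' @return Numeric vector at 1 kHz.
#' @keywords internal
stimulus_1khz <- function(stim) {
  step <- stim$rate_hz / 1000
  if (step != round(step)) abort("rate_hz must be a multiple of 1000")
  stim$samples[seq(1, length(stim$samples), by = step)]
}
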
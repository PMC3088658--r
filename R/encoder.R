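#' Surrogate encoder specification
#'
#' Parameterizes the surrogate spike-generating neuron used throughout the
#' synthetic-data module: a linear filter followed by an exponential rate
#' nonlinearity, sampled as an inhomogeneous renewal process gated by a
#' Normal-CDF refractory recovery (mean 2.5 ms, SD 0.2 ms) with a hard 2 ms
#' floor. With `burst_gain > 0`, a sharp upward deflection of the filtered
#' drive (slope above `burst_threshold` standard deviations) transiently
#' boosts the firing rate for 8 ms, converting such stimulus features into
#' short doublets (ISI roughly 2--8 ms).
#'
#' The exponential nonlinearity makes `burst_gain = 0` an exact
#' linear-superposition null for Gaussian stimuli: the spike-conditioned
#' stimulus ensemble is Gaussian with the ambient covariance and a mean
#' proportional to the (time-reversed) kernel, and multi-spike conditioning
#' adds shifted copies of that mean -- so doublet-conditioned stimuli are
#' statistically indistinguishable from offset singlet stimuli (up to
#' refractory interactions). This is the pipeline's negative control.
#'
#' @param kernel Linear filter, one value per ms over a 50 ms support
#'   (most-recent sample first); default [default_kernel()].
#' @param beta Exponent of the rate nonlinearity
#'   `rate = r0 * exp(beta * drive)` with the drive z-scored; larger values
#'   give sharper stimulus selectivity (default 1.0).
#' @param target_rate_hz Approximate mean firing rate; `r0` is set
#'   analytically from the lognormal mean so the unrefractory rate matches.
#' @param burst_gain Nonnegative strength of the doublet-generating boost
#'   (0 disables it).
#' @param burst_threshold Slope threshold (SD units of the drive derivative)
#'   that triggers the boost.
#' @param recovery Length-2 numeric `(mu_ms, sigma_ms)` of the Normal-CDF
#'   recovery function.
#' @param floor_ms Hard refractory floor in ms.
#' @param jitter_sd_ms SD of additive Gaussian latency noise per spike (ms).
#'
#' @return An `encoder_spec` list.
#' @export
encoder_spec <- function(kernel = default_kernel(),
                         beta = 1.0,
                         target_rate_hz = 35,
                         burst_gain = 0,
                         burst_threshold = 2.2,
                         recovery = c(2.5, 0.2),
                         floor_ms = 2,
                         jitter_sd_ms = 0) {
  stopifnot(burst_gain >= 0, floor_ms > 0, recovery[2] > 0,
            target_rate_hz > 0, jitter_sd_ms >= 0, beta > 0)
  structure(
    list(kernel = kernel, beta = beta,
         target_rate_hz = target_rate_hz, burst_gain = burst_gain,
         burst_threshold = burst_threshold, recovery = recovery,
         floor_ms = floor_ms, jitter_sd_ms = jitter_sd_ms),
    class = "encoder_spec")
}

#' Default 50 ms encoder kernel
#'
#' A Gabor-shaped filter (70 Hz carrier under a 5 ms Gaussian envelope
#' centered 12 ms in the past), parameterized at 1 kHz over 50 ms and
#' normalized to unit norm. Its spectral content lies inside the 10--200 Hz
#' stimulus band.
#'
#' @return Numeric vector of 50 filter taps (lag 0 ms first).
#' @export
default_kernel <- function() {
  lag <- 0:49
  k <- exp(-(lag - 12)^2 / (2 * 5^2)) * sin(2 * pi * 70 * (lag - 12) / 1000)
  k / sqrt(sum(k^2))
}

# Linear drive: stimulus convolved with the kernel (upsampled to the stimulus
# rate), z-scored. Returns list(drive, slope) at the stimulus sampling rate.
encoder_drive <- function(stim, spec) {
  step <- stim$rate_hz / 1000
  lag_ms <- (seq_len(length(spec$kernel) * step) - 1) / step
  k <- stats::approx(seq_along(spec$kernel) - 1, spec$kernel, xout = lag_ms,
                     rule = 2)$y / step
  x <- stim$samples
  if (length(k) > length(x)) abort("kernel support exceeds stimulus length")
  nfft <- nextn(length(x) + length(k) - 1, 2)
  X <- fft(c(x, numeric(nfft - length(x))))
  K <- fft(c(k, numeric(nfft - length(k))))
  y <- Re(fft(X * K, inverse = TRUE))[seq_along(x)] / nfft
  sy <- sd(y)
  if (sy == 0) return(list(drive = numeric(length(x)) - Inf,
                           slope = numeric(length(x))))
  drive <- (y - mean(y)) / sy
  slope <- c(0, diff(drive)) * step # per-ms derivative
  ss <- sd(slope)
  slope <- if (ss > 0) slope / ss else slope
  list(drive = drive, slope = slope)
}

#' Encode a stimulus into a surrogate spike train
#'
#' Filters the stimulus with the encoder kernel, exponentiates the z-scored
#' drive into an instantaneous rate, and samples spikes from that rate
#' modulated by the refractory recovery function; an optional
#' slope-triggered boost produces doublets. Per-spike Gaussian latency
#' noise (`jitter_sd_ms`) is added afterwards and any spike that would
#' violate the hard refractory floor is dropped.
#'
#' @param stim A `stimulus` from [generate_stimulus()].
#' @param spec An [encoder_spec()].
#' @param seed Optional seed for reproducibility.
#' @return A tibble with columns `trial_id`, `time_ms` (sorted), carrying a
#'   `duration_ms` attribute.
#' @examples
#' s <- generate_stimulus(2000, seed = 1)
#' encode(s, encoder_spec(burst_gain = 1.5), seed = 2)
#' @export
encode <- function(stim, spec = encoder_spec(), seed = NULL) {
  stopifnot(inherits(stim, "stimulus"), inherits(spec, "encoder_spec"))
  d <- encoder_drive(stim, spec)
  # E[exp(beta * Z)] = exp(beta^2 / 2) fixes the rate scale.
  rate <- spec$target_rate_hz * exp(spec$beta * d$drive - spec$beta^2 / 2)

  times <- with_seed(seed, {
    t0 <- encode_sample_cpp(
      rate, d$slope, 1000 / stim$rate_hz,
      spec$burst_gain, spec$burst_threshold, 8,
      spec$recovery[1], spec$recovery[2], spec$floor_ms)
    if (spec$jitter_sd_ms > 0 && length(t0) > 0) {
      t0 <- sort(t0 + rnorm(length(t0), 0, spec$jitter_sd_ms))
    }
    t0
  })
  times <- enforce_floor(times, spec$floor_ms)
  duration <- length(stim$samples) * 1000 / stim$rate_hz
  spike_raster(tibble::tibble(trial_id = rep(1L, length(times)),
                              time_ms = times),
               duration_ms = duration)
}

# Drop spikes closer than the hard floor to their predecessor.
enforce_floor <- function(times, floor_ms) {
  if (length(times) < 2) return(times)
  keep <- logical(length(times))
  keep[1] <- TRUE
  last <- times[1]
  for (i in 2:length(times)) {
    if (times[i] - last >= floor_ms) {
      keep[i] <- TRUE
      last <- times[i]
    }
  }
  times[keep]
}

#' Frozen-noise session: repeated trials of one stimulus
#'
#' Encodes the same stimulus `n_repeats` times with independent sampling
#' noise, emulating the frozen-noise protocol of 30--100 repeats of a short
#' segment.
#'
#' @param stim A `stimulus`.
#' @param spec An [encoder_spec()].
#' @param n_repeats Number of trials (>= 2).
#' @param seed Optional seed; trial seeds are derived deterministically.
#' @return A spike raster tibble (`trial_id`, `time_ms`) with attribute
#'   `duration_ms`.
#' @export
frozen_noise_session <- function(stim, spec = encoder_spec(), n_repeats,
                                 seed = NULL) {
  if (n_repeats < 2) abort("`n_repeats` must be >= 2")
  trials <- with_seed(seed, {
    purrr::map(seq_len(n_repeats), function(i) {
      tr <- encode(stim, spec, seed = NULL)
      tr$trial_id <- i
      tr
    })
  })
  duration <- length(stim$samples) * 1000 / stim$rate_hz
  spike_raster(dplyr::bind_rows(trials), duration_ms = duration)
}
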
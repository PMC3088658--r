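#' Discretize spike times into a binary sequence
#'
#' Bins spike times at `bin_width_ms`; bins holding more than one spike are
#' clipped to 1 and the number of clipped spikes is recorded.
#'
#' @param times_ms Spike times (ms) of one train, or a single-trial
#'   `spike_raster`.
#' @param duration_ms Recording length (ms).
#' @param bin_width_ms Bin width (default 1 ms).
#' @return Integer 0/1 vector with attributes `bin_width_ms`, `n_clipped`.
#' @export
binarize_spikes <- function(times_ms, duration_ms = NULL, bin_width_ms = 1) {
  if (is.data.frame(times_ms)) {
    duration_ms <- duration_ms %||% attr(times_ms, "duration_ms")
    times_ms <- times_ms$time_ms
  }
  if (is.null(duration_ms)) duration_ms <- max(times_ms)
  nb <- ceiling(duration_ms / bin_width_ms)
  counts <- tabulate(bin_index(times_ms[times_ms < duration_ms], bin_width_ms),
                     nbins = nb)
  structure(as.integer(counts > 0),
            bin_width_ms = bin_width_ms,
            n_clipped = sum(pmax(counts - 1, 0)))
}

#' Entropy rate of a binary sequence by context-tree weighting
#'
#' Universal compression-based entropy estimate: binary CTW with
#' Krichevsky--Trofimov node estimators and weight 1/2, to context depth
#' `depth` bins. The entropy rate is the ideal code length of the weighted
#' coding probability per symbol.
#'
#' @param seq Integer 0/1 vector (e.g. from [binarize_spikes()]).
#' @param depth Context depth in bins (default 100).
#' @param bin_width_ms Bin width used to convert to bits/s (taken from the
#'   sequence attribute when present).
#' @return List of class `ctw_estimate`: `bits_per_bin`, `bits_per_s`,
#'   `depth`, `bin_width_ms`, `n_symbols`.
#' @export
ctw_entropy_rate <- function(seq, depth = 100, bin_width_ms = NULL) {
  bin_width_ms <- bin_width_ms %||% attr(seq, "bin_width_ms") %||% 1
  if (length(seq) < 1e4) abort("sequence must contain at least 10^4 bins")
  if (depth >= length(seq)) abort("depth must be smaller than the sequence")
  res <- ctw_entropy_cpp(as.integer(seq), as.integer(depth))
  structure(
    list(bits_per_bin = res$bits_per_symbol,
         bits_per_s = res$bits_per_symbol * 1000 / bin_width_ms,
         depth = depth, bin_width_ms = bin_width_ms,
         n_symbols = res$n_symbols),
    class = "ctw_estimate")
}

#' @export
print.ctw_estimate <- function(x, ...) {
  cat(sprintf("<ctw_estimate> %.4f bits/bin (%.1f bits/s), depth %d, %d symbols\n",
              x$bits_per_bin, x$bits_per_s, x$depth, x$n_symbols))
  invisible(x)
}

#' Direct-method information rate
#'
#' Total response entropy is estimated by CTW on the long non-repeated
#' response; the conditional (noise) entropy is estimated from the
#' frozen-noise raster as the time-averaged across-trial Bernoulli entropy
#' per bin (Miller--Madow bias-corrected). Mutual information is their
#' difference.
#'
#' @param long_train Spike raster (1 trial) from a long non-repeated
#'   stimulus.
#' @param frozen_raster Spike raster of repeated trials of one stimulus.
#' @param bin_width_ms Discretization (default 1 ms).
#' @param depth CTW context depth (default 100).
#' @return Tibble with `total_bits_per_s`, `conditional_bits_per_s`,
#'   `mi_bits_per_s`, `n_repeats`, `low_repeat_warning`.
#' @export
direct_information <- function(long_train, frozen_raster, bin_width_ms = 1,
                               depth = 100) {
  seq_total <- binarize_spikes(long_train, bin_width_ms = bin_width_ms)
  total <- ctw_entropy_rate(seq_total, depth = depth,
                            bin_width_ms = bin_width_ms)

  trials <- sort(unique(frozen_raster$trial_id))
  n_tr <- length(trials)
  low <- n_tr < 20
  if (low) warn("fewer than 20 repeats: conditional-entropy estimate is high-variance")
  duration <- attr(frozen_raster, "duration_ms") %||% max(frozen_raster$time_ms)
  nb <- ceiling(duration / bin_width_ms)
  counts <- numeric(nb)
  idx <- bin_index(frozen_raster$time_ms[frozen_raster$time_ms < duration],
                   bin_width_ms)
  for (i in idx) counts[i] <- counts[i] + 1
  p <- pmin(counts / n_tr, 1)
  h <- ifelse(p > 0 & p < 1, -p * log2(p) - (1 - p) * log2(1 - p), 0)
  # Miller-Madow: + (K-1)/(2 N ln 2) with K = 2 observable states per bin
  mm <- ifelse(p > 0 & p < 1, 1 / (2 * n_tr * log(2)), 0)
  cond_per_bin <- mean(h + mm)
  cond_rate <- cond_per_bin * 1000 / bin_width_ms

  tibble::tibble(
    total_bits_per_s = total$bits_per_s,
    conditional_bits_per_s = cond_rate,
    mi_bits_per_s = total$bits_per_s - cond_rate,
    n_repeats = n_tr,
    low_repeat_warning = low)
}

# Sine multitapers (Riedel & Sidorenko): closed-form taper family.
sine_tapers <- function(n, k) {
  vapply(seq_len(k), function(j) {
    sqrt(2 / (n + 1)) * sin(pi * j * seq_len(n) / (n + 1))
  }, numeric(n))
}

#' Linear (coherence lower-bound) information rate
#'
#' Bins the spike train at the stimulus rate, computes the multitaper
#' magnitude-squared coherence between stimulus and response on overlapping
#' segments, and integrates `-log2(1 - gamma(f))` over the stimulus band:
#' the stimulus-reconstruction lower bound on the information rate.
#'
#' @param stim A `stimulus`.
#' @param response Spike raster (1 trial) recorded simultaneously, or a
#'   numeric response series already sampled at the stimulus rate.
#' @param n_tapers Number of sine tapers (default 8).
#' @param segment_length Samples per segment (default `2^14`), 50% overlap.
#' @param band Integration band in Hz (default: the stimulus band).
#' @return List of class `coherence_info`: tibble `spectrum`
#'   (`freq_hz`, `coherence`), `info_bits_per_s`, `band`.
#' @export
coherence_information <- function(stim, response, n_tapers = 8,
                                  segment_length = 2^14, band = NULL) {
  stopifnot(inherits(stim, "stimulus"))
  band <- band %||% stim$band
  if (band[2] >= stim$rate_hz / 2) abort("band exceeds the Nyquist frequency")
  x <- stim$samples
  dt_ms <- 1000 / stim$rate_hz
  y <- if (is.data.frame(response)) {
    as.numeric(binarize_spikes(response, duration_ms = length(x) * dt_ms,
                               bin_width_ms = dt_ms))
  } else {
    as.numeric(response)
  }
  n <- min(length(x), length(y))
  if (n < segment_length) abort("recording shorter than one segment")
  x <- x[seq_len(n)] - mean(x)
  y <- y[seq_len(n)] - mean(y)

  tap <- sine_tapers(segment_length, n_tapers)
  starts <- seq(1, n - segment_length + 1, by = segment_length %/% 2)
  nfreq <- segment_length %/% 2
  sxx <- syy <- numeric(nfreq)
  sxy <- complex(nfreq)
  for (s in starts) {
    xi <- x[s:(s + segment_length - 1)]
    yi <- y[s:(s + segment_length - 1)]
    for (k in seq_len(n_tapers)) {
      X <- fft(xi * tap[, k])[seq_len(nfreq)]
      Y <- fft(yi * tap[, k])[seq_len(nfreq)]
      sxx <- sxx + Mod(X)^2
      syy <- syy + Mod(Y)^2
      sxy <- sxy + X * Conj(Y)
    }
  }
  coh <- Mod(sxy)^2 / (sxx * syy)
  freq <- (seq_len(nfreq) - 1) * stim$rate_hz / segment_length
  df <- stim$rate_hz / segment_length
  sel <- freq >= band[1] & freq <= band[2]
  info <- -sum(log2(1 - pmin(coh[sel], 1 - 1e-12))) * df
  structure(
    list(spectrum = tibble::tibble(freq_hz = freq, coherence = coh),
         info_bits_per_s = info, band = band,
         n_tapers = n_tapers, segment_length = segment_length,
         n_segments = length(starts)),
    class = "coherence_info")
}

#' @export
print.coherence_info <- function(x, ...) {
  cat(sprintf(
    "<coherence_info> %.1f bits/s over %g-%g Hz (%d tapers x %d segments)\n",
    x$info_bits_per_s, x$band[1], x$band[2], x$n_tapers, x$n_segments))
  invisible(x)
}

#' @method autoplot coherence_info
#' @export
autoplot.coherence_info <- function(object, ...) {
  sp <- object$spectrum
  sp <- sp[sp$freq_hz <= 1.5 * object$band[2], ]
  ggplot2::ggplot(sp, ggplot2::aes(.data$freq_hz, .data$coherence)) +
    ggplot2::geom_line() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "frequency (Hz)", y = expression(gamma^2))
}
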
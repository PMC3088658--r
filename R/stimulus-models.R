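#' Pattern-conditioned Gaussian stimulus model
#'
#' A Gaussian description of the stimulus ensemble conditioned on a response
#' pattern: mean vector and covariance over a 50-sample window at 1 kHz
#' covering the 50 ms before the pattern-defining spike. Sample `k` of the
#' window is `(k + 1)` ms before that spike (so sample 1 is 1 ms before it,
#' sample 50 is 50 ms before).
#'
#' @param mu Mean stimulus vector (mm/s).
#' @param C Covariance matrix (mm^2/s^2).
#' @param label Model label (e.g. `"DTSM"`, `"STSM"`, `"sDTSM"`).
#' @param isi_ms ISI of the conditioning doublet (NA for singlet models).
#' @param n_events Number of events behind the estimate.
#' @return Object of class `gsm`.
#' @export
gaussian_stimulus_model <- function(mu, C, label = "model", isi_ms = NA_real_,
                                    n_events = NA_integer_) {
  mu <- as.numeric(mu)
  C <- as.matrix(C)
  stopifnot(length(mu) == nrow(C), nrow(C) == ncol(C))
  if (max(abs(C - t(C))) > 1e-8 * max(1, max(abs(C)))) {
    abort("covariance must be symmetric")
  }
  C <- (C + t(C)) / 2
  structure(list(mu = mu, C = C, label = label, isi_ms = isi_ms,
                 n_events = n_events),
            class = "gsm")
}

#' @export
print.gsm <- function(x, ...) {
  cat(sprintf("<gsm %s> dim %d, isi %s ms, n = %s\n", x$label, length(x$mu),
              format(x$isi_ms), format(x$n_events)))
  invisible(x)
}

#' @method tidy gsm
#' @export
tidy.gsm <- function(x, ...) {
  tibble::tibble(lag_ms = seq_along(x$mu), mean = x$mu,
                 var = diag(x$C))
}

#' @method autoplot gsm
#' @export
autoplot.gsm <- function(object, ...) {
  d <- tidy.gsm(object)
  ggplot2::ggplot(d, ggplot2::aes(-.data$lag_ms, .data$mean)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - sqrt(.data$var),
                                      ymax = .data$mean + sqrt(.data$var)),
                         alpha = 0.25) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time before pattern-defining spike (ms)",
                  y = "velocity (mm/s)", title = object$label)
}

#' Collect isolated pattern-conditioned stimulus ensembles
#'
#' Finds isolated single spikes and isolated doublets (no other spikes
#' within `isolation_ms` before the first or after the last spike of the
#' pattern) in a long recording and collects the 50-sample, 1 kHz stimulus
#' window preceding the pattern-defining spike (the spike itself for
#' singlets, the second spike for doublets). Doublets are grouped by ISI in
#' `isi_bin_ms` bins; ensembles with fewer than `min_events` members are
#' dropped. Each retained ensemble is assigned balanced test folds for
#' cross-validation.
#'
#' @param spikes Spike raster (1 trial) recorded with `stim`.
#' @param stim The `stimulus` presented.
#' @param isolation_ms Isolation window (default 20 ms).
#' @param isi_bin_ms ISI grouping resolution (default 1 ms; doublet ISIs are
#'   assigned to bins by rounding to the nearest ms).
#' @param max_isi_ms Largest doublet ISI collected (default 30 ms).
#' @param window_ms Stimulus window length (default 50 ms).
#' @param min_events Minimum ensemble size (default 80).
#' @param n_folds Cross-validation folds (default 10).
#' @param seed Seed for fold assignment.
#' @return A list of class `pattern_ensembles` with elements `singlet`
#'   (matrix + folds) and `doublet` (named list by ISI, each matrix + folds).
#' @export
collect_isolated_patterns <- function(spikes, stim, isolation_ms = 20,
                                      isi_bin_ms = 1, max_isi_ms = 30,
                                      window_ms = 50, min_events = 80,
                                      n_folds = 10, seed = 1) {
  assert_spikes(spikes)
  stopifnot(inherits(stim, "stimulus"))
  x1k <- stimulus_1khz(stim)
  duration <- length(stim$samples) * 1000 / stim$rate_hz
  t <- sort(spikes$time_ms)
  n <- length(t)
  if (n < 3) abort("too few spikes")
  gap_prev <- c(Inf, diff(t))
  gap_next <- c(diff(t), Inf)

  seg_at <- function(spike_ms) {
    # samples (k+1) ms before the defining spike, k = 0..window_ms-1
    idx <- round(spike_ms) - seq_len(window_ms)
    if (idx[window_ms] < 1 || idx[1] > length(x1k)) return(NULL)
    x1k[idx]
  }

  # isolated singlets: no neighbors within isolation_ms on either side
  singlet_idx <- which(gap_prev >= isolation_ms & gap_next >= isolation_ms &
                       t >= window_ms + 1 & t <= duration)
  singlets <- purrr::compact(purrr::map(t[singlet_idx], seg_at))
  singlet <- if (length(singlets)) do.call(rbind, singlets) else NULL

  # isolated doublets: consecutive pair, isolated around the pair
  first_i <- which(gap_next < max_isi_ms + isi_bin_ms / 2 &
                   gap_prev >= isolation_ms)
  first_i <- first_i[first_i + 1 <= n]
  ok <- gap_next[first_i + 1] >= isolation_ms
  first_i <- first_i[ok]
  doublet_tbl <- tibble::tibble(
    t1 = t[first_i], t2 = t[first_i + 1],
    isi_bin = round((t[first_i + 1] - t[first_i]) / isi_bin_ms) * isi_bin_ms)
  doublet_tbl <- doublet_tbl[doublet_tbl$isi_bin >= 2 &
                             doublet_tbl$isi_bin <= max_isi_ms, ]

  doublet <- list()
  for (isi in sort(unique(doublet_tbl$isi_bin))) {
    sub <- doublet_tbl[doublet_tbl$isi_bin == isi, ]
    segs <- purrr::compact(purrr::map(sub$t2, seg_at))
    if (length(segs) < min_events) next
    doublet[[as.character(isi)]] <- list(
      segments = do.call(rbind, segs), isi_ms = isi,
      folds = assign_folds(length(segs), n_folds, seed + isi))
  }

  singlet_ok <- !is.null(singlet) && nrow(singlet) >= min_events
  structure(
    list(
      singlet = if (singlet_ok)
        list(segments = singlet, isi_ms = NA_real_,
             folds = assign_folds(nrow(singlet), n_folds, seed)) else NULL,
      doublet = doublet,
      window_ms = window_ms, isolation_ms = isolation_ms,
      min_events = min_events, n_folds = n_folds),
    class = "pattern_ensembles")
}

# Balanced random fold labels 1..k.
assign_folds <- function(n, k, seed) {
  with_seed(seed, sample(rep_len(seq_len(k), n)))
}

#' @export
print.pattern_ensembles <- function(x, ...) {
  ns <- if (is.null(x$singlet)) 0 else nrow(x$singlet$segments)
  cat(sprintf("<pattern_ensembles> %d singlets; doublet ISIs: %s\n", ns,
              paste(names(x$doublet), collapse = ", ")))
  invisible(x)
}

#' Fit a Gaussian stimulus model to an ensemble
#'
#' Sample mean and covariance of the (training) stimulus segments.
#'
#' @param segments Matrix of stimulus segments (rows = events).
#' @param label,isi_ms Metadata for the resulting model.
#' @return A [gaussian_stimulus_model()].
#' @export
fit_gaussian_model <- function(segments, label = "model", isi_ms = NA_real_) {
  stopifnot(is.matrix(segments), nrow(segments) >= 2)
  gaussian_stimulus_model(colMeans(segments), cov(segments),
                          label = label, isi_ms = isi_ms,
                          n_events = nrow(segments))
}

# Shift a vector/covariance toward the past by `k` samples with zero padding:
# index i of the shifted copy corresponds to index i - k of the original
# (the first-spike copy of a doublet sits ISI samples deeper in the past).
shift_mu <- function(mu, k) shift_vec(mu, k)

# Covariance of the time-shifted singlet copy: the in-range block is the
# original covariance moved along both axes; entries whose source indices
# fall outside the singlet window are filled by stationary extension (the
# diagonal mean of the original at the same lag). Zero-filling that band
# instead would assert half the ambient stimulus variance in the last ISI
# ms of the window, which even a linear encoder violates.
shift_cov <- function(C, k, pad = c("stationary", "zero")) {
  pad <- match.arg(pad)
  n <- nrow(C)
  out <- matrix(0, n, n)
  if (pad == "stationary") {
    lagmean <- vapply(0:(n - 1), function(l) {
      mean(C[cbind(seq_len(n - l), seq_len(n - l) + l)])
    }, numeric(1))
    out <- lagmean[abs(outer(seq_len(n), seq_len(n), "-")) + 1]
    dim(out) <- c(n, n)
  }
  if (k >= 0) {
    if (k < n) out[(1 + k):n, (1 + k):n] <- C[1:(n - k), 1:(n - k)]
  } else {
    if (-k < n) out[1:(n + k), 1:(n + k)] <- C[(1 - k):n, (1 - k):n]
  }
  out
}

#' Synthesize a doublet model from the singlet model
#'
#' Builds the synthetic doublet-triggered stimulus model (sDTSM) for a given
#' ISI under the linear-superposition hypothesis: the mean is the singlet
#' mean plus a copy of itself shifted `ISI` ms deeper into the past
#' (zero-padded, truncated to the 50 ms window ending at the second spike);
#' the covariance is the sum of the singlet covariance and its
#' doubly-shifted copy, rescaled by a scalar `k` so that the generalized
#' variance (product of eigenvalues) in the reduced space matches that of
#' the data doublet model -- the synthetic model then occupies approximately
#' the same stimulus-space volume as the data model. Cross-covariance
#' between the two summed copies is deliberately omitted: that omission is
#' the independence assumption under test.
#'
#' @param stsm Singlet model (`gsm`).
#' @param isi_ms Target ISI (rounded to the nearest whole ms); may be
#'   negative (a `-k` ms offset equals a `+k` ms pattern with `k` ms extra
#'   latency) but must be smaller than the window length in magnitude.
#' @param dtsm_for_scaling Data doublet model whose reduced-space
#'   generalized variance fixes the scale `k`.
#' @param reduced_space A [fit_reduced_space()] basis in which the volume
#'   matching is imposed.
#' @return A `gsm` labeled `"sDTSM"` (attribute `scale_k` records `k`).
#' @export
synthesize_doublet_model <- function(stsm, isi_ms, dtsm_for_scaling,
                                     reduced_space) {
  stopifnot(inherits(stsm, "gsm"), inherits(dtsm_for_scaling, "gsm"))
  k_shift <- round(isi_ms)
  nw <- length(stsm$mu)
  if (abs(k_shift) >= nw) abort("|ISI| must be smaller than the window length")

  mu_sd <- stsm$mu + shift_mu(stsm$mu, k_shift)
  C_sum <- stsm$C + shift_cov(stsm$C, k_shift)

  B <- reduced_space$basis
  ev_sum <- eigen(crossprod(B, C_sum %*% B), symmetric = TRUE,
                  only.values = TRUE)$values
  ev_d <- eigen(crossprod(B, dtsm_for_scaling$C %*% B), symmetric = TRUE,
                only.values = TRUE)$values
  d <- length(ev_sum)
  scale_k <- exp((sum(log(ev_d)) - sum(log(ev_sum))) / d)

  out <- gaussian_stimulus_model(mu_sd, scale_k * C_sum, label = "sDTSM",
                                 isi_ms = isi_ms, n_events = stsm$n_events)
  attr(out, "scale_k") <- scale_k
  out
}

#' Reduced stimulus space for band-limited stimuli
#'
#' Band-limited stimuli have (numerically) rank-deficient windowed
#' covariances; likelihoods are therefore computed in the span of the
#' leading eigenvectors of the unconditioned stimulus covariance over the
#' model window. Eigenvectors with eigenvalue at least `eig_threshold`
#' times the largest are retained; for a 10--200 Hz band and a 50 ms window
#' the retained dimension is ~19--20 (the 2BT count).
#'
#' @param stim A `stimulus`, or a matrix of unconditioned stimulus segments
#'   (rows = segments at 1 kHz).
#' @param window_ms Window length in ms (default 50).
#' @param eig_threshold Relative eigenvalue cutoff (default 0.01).
#' @return List of class `reduced_space`: `basis` (columns orthonormal),
#'   `eigenvalues`, `d`, `eig_threshold`.
#' @export
fit_reduced_space <- function(stim, window_ms = 50, eig_threshold = 0.01) {
  C <- if (inherits(stim, "stimulus")) {
    x <- stimulus_1khz(stim)
    # stationary covariance from the autocovariance sequence
    ac <- stats::acf(x, lag.max = window_ms - 1, type = "covariance",
                     plot = FALSE, demean = TRUE)$acf[, 1, 1]
    stats::toeplitz(ac)
  } else {
    stopifnot(is.matrix(stim), nrow(stim) >= 500)
    cov(stim)
  }
  e <- eigen(C, symmetric = TRUE)
  keep <- e$values >= eig_threshold * e$values[1]
  structure(
    list(basis = e$vectors[, keep, drop = FALSE],
         eigenvalues = e$values, d = sum(keep),
         eig_threshold = eig_threshold),
    class = "reduced_space")
}

#' @export
print.reduced_space <- function(x, ...) {
  cat(sprintf("<reduced_space> d = %d of %d (threshold %g)\n",
              x$d, length(x$eigenvalues), x$eig_threshold))
  invisible(x)
}

#' Project a Gaussian model (or segments) into a reduced space
#'
#' @param model A `gsm`, or a matrix of segments (rows).
#' @param reduced_space A [fit_reduced_space()] result.
#' @return Projected `gsm` (or matrix). A projected model whose covariance
#'   is not positive definite is flagged via the `usable` attribute.
#' @export
project_model <- function(model, reduced_space) {
  B <- reduced_space$basis
  if (is.matrix(model)) return(model %*% B)
  stopifnot(inherits(model, "gsm"))
  mu <- drop(crossprod(B, model$mu))
  C <- crossprod(B, model$C %*% B)
  out <- gaussian_stimulus_model(mu, C, label = model$label,
                                 isi_ms = model$isi_ms,
                                 n_events = model$n_events)
  ev <- eigen(out$C, symmetric = TRUE, only.values = TRUE)$values
  attr(out, "usable") <- min(ev) > 0
  attr(out, "scale_k") <- attr(model, "scale_k")
  out
}
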
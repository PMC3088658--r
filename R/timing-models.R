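#' Doublet timing-variability model specification
#'
#' Three models of within-doublet timing variability for a doublet of given
#' mean ISI, all with the first spike centered at t = 0:
#' \describe{
#'   \item{independent (model 1)}{first and second spike times drawn
#'     independently from Normals with SD `onset_sigma_ms` (1.3 ms, the
#'     measured single-spike jitter); the earlier draw is always relabeled
#'     as the first spike.}
#'   \item{refractory (model 2)}{as model 1, but a second spike falling
#'     within the refractory window is redrawn displaced from the first by
#'     a Gaussian shaped by the Normal-CDF recovery function.}
#'   \item{matched (model 3)}{data-matched: the first-spike SD is the fitted
#'     onset-jitter curve evaluated at the ISI, and the second spike is
#'     `ISI + R*t1 + eps` with `R` the fitted correlation curve and
#'     `eps ~ N(0, sigma0^2 (1 - R^2))`, which preserves the unconditioned
#'     second-spike variance while correlating the two spikes.}
#' }
#'
#' @param kind One of `"independent"`, `"refractory"`, `"matched"`.
#' @param onset_sigma_ms First-spike SD for models 1--2 (default 1.3 ms).
#' @param recovery `(mu_ms, sigma_ms)` of the recovery function (model 2).
#' @param refractory_window_ms Upper edge of the window within which model 2
#'   redraws the second spike (default 3 ms).
#' @param jitter_params,correlation_params Exponential-model parameters for
#'   model 3 (defaults: pooled-data best fits).
#' @return A `timing_model_spec` list.
#' @export
timing_model_spec <- function(kind = c("independent", "refractory", "matched"),
                              onset_sigma_ms = 1.3,
                              recovery = c(2.5, 0.2),
                              refractory_window_ms = 3,
                              jitter_params = reference_timing_params()$jitter,
                              correlation_params = reference_timing_params()$correlation) {
  kind <- match.arg(kind)
  structure(
    list(kind = kind, onset_sigma_ms = onset_sigma_ms, recovery = recovery,
         refractory_window_ms = refractory_window_ms,
         jitter_params = jitter_params,
         correlation_params = correlation_params),
    class = "timing_model_spec")
}

# First-spike SD used by a model at a given ISI.
model_sigma0 <- function(spec, isi_ms) {
  if (spec$kind == "matched") {
    pmax(eval_jitter_model(isi_ms, spec$jitter_params), 1e-6)
  } else {
    rep(spec$onset_sigma_ms, length(isi_ms))
  }
}

#' Sample doublet trials from a timing model
#'
#' Draws `n_trials` two-spike trials for a doublet of mean ISI `mean_isi_ms`
#' under the given timing model (see [timing_model_spec()]). Times are in ms
#' with the nominal first spike centered at 0.
#'
#' @param spec A [timing_model_spec()].
#' @param mean_isi_ms Mean ISI of the doublet (>= 2 ms).
#' @param n_trials Number of trials (>= 2).
#' @param seed Optional seed.
#' @return Tibble with columns `trial_id`, `t_first`, `t_second` (two spikes
#'   per trial, `t_first <= t_second`).
#' @export
sample_doublets <- function(spec, mean_isi_ms, n_trials, seed = NULL) {
  stopifnot(inherits(spec, "timing_model_spec"))
  if (mean_isi_ms < 2) abort("`mean_isi_ms` must be >= 2 ms")
  if (n_trials < 2) abort("`n_trials` must be >= 2")
  with_seed(seed, {
    if (spec$kind == "matched") {
      s0 <- model_sigma0(spec, mean_isi_ms)
      r <- eval_correlation_model(mean_isi_ms, spec$correlation_params)
      t1 <- rnorm(n_trials, 0, s0)
      eps <- rnorm(n_trials, 0, s0 * sqrt(max(1 - r^2, 0)))
      t2 <- mean_isi_ms + r * t1 + eps
    } else {
      s0 <- spec$onset_sigma_ms
      t1 <- rnorm(n_trials, 0, s0)
      t2 <- rnorm(n_trials, mean_isi_ms, s0)
      if (spec$kind == "refractory") {
        viol <- (t2 - t1) < spec$refractory_window_ms
        if (any(viol)) {
          disp <- abs(rnorm(sum(viol), spec$recovery[1], spec$recovery[2]))
          t2[viol] <- t1[viol] + disp
        }
      }
    }
    # earliest spike is always attributed to the first-spike distribution
    first <- pmin(t1, t2)
    second <- pmax(t1, t2)
    tibble::tibble(trial_id = seq_len(n_trials),
                   t_first = first, t_second = second)
  })
}

#' @rdname sample_doublets
#' @param isi_ms Mean ISI (alias used by the synthetic-data module).
#' @export
simulate_ground_truth_doublets <- function(isi_ms, n_trials, spec, seed = NULL) {
  sample_doublets(spec, isi_ms, n_trials, seed = seed)
}

#' Monte-Carlo correlation curve of a timing model
#'
#' First/second spike-time correlation of sampled doublets as a function of
#' ISI. The matched model reproduces the fitted correlation curve by
#' construction (within sampling error); the independent model shows only a
#' small ordering-induced correlation at very short ISIs.
#'
#' @param spec A [timing_model_spec()].
#' @param isi_grid ISIs to evaluate (ms), within `[2, 65]`.
#' @param n_per_isi Trials per ISI (default 10000).
#' @param seed Optional seed.
#' @return Tibble with `isi_ms`, `r`, `onset_jitter_ms`, `isi_sd_ms`.
#' @export
model_correlation_curve <- function(spec, isi_grid, n_per_isi = 10000,
                                    seed = NULL) {
  with_seed(seed, {
    purrr::map_dfr(isi_grid, function(isi) {
      d <- sample_doublets(spec, isi, n_per_isi, seed = NULL)
      tibble::tibble(
        isi_ms = isi,
        r = cor(d$t_first, d$t_second),
        onset_jitter_ms = sd(d$t_first),
        isi_sd_ms = sd(d$t_second - d$t_first))
    })
  })
}

#' Conditional (noise) entropy of a doublet pattern
#'
#' Entropy of the response pattern conditioned on the stimulus, treating the
#' total pattern variability as Gaussian: the conditional ISI variance
#' `sigma0^2 (1 - R^2)` (the within-doublet noise term, with `sigma0` the
#' single-spike jitter) plus the squared onset jitter appropriate to the
#' model (1.3 ms for models 1--2, the fitted onset-jitter curve for the
#' matched model). Returns the differential entropy in bits of the Normal
#' with that total variance.
#'
#' @param spec A [timing_model_spec()].
#' @param mean_isi_ms Mean ISI (ms).
#' @param r Optional correlation override; by default the model's
#'   correlation at this ISI (Monte-Carlo for models 1--2, the fitted curve
#'   for the matched model).
#' @param n_mc Monte-Carlo trials for correlation estimation (models 1--2).
#' @param seed Seed for the Monte-Carlo correlation (models 1--2).
#' @return Conditional entropy in bits (per doublet event).
#' @export
conditional_entropy <- function(spec, mean_isi_ms, r = NULL, n_mc = 100000,
                                seed = 1) {
  stopifnot(inherits(spec, "timing_model_spec"))
  v <- conditional_variance(spec, mean_isi_ms, r = r, n_mc = n_mc, seed = seed)
  gaussian_entropy_bits(v)
}

# Total conditioned-pattern variance (ms^2): conditional ISI variance plus
# squared onset jitter.
conditional_variance <- function(spec, mean_isi_ms, r = NULL, n_mc = 100000,
                                 seed = 1) {
  vapply(mean_isi_ms, function(isi) {
    rr <- r %||% model_r(spec, isi, n_mc = n_mc, seed = seed)
    base_sd <- spec$onset_sigma_ms # single-spike jitter scale (1.3 ms)
    onset <- if (spec$kind == "matched") {
      eval_jitter_model(isi, spec$jitter_params)
    } else {
      spec$onset_sigma_ms
    }
    base_sd^2 * (1 - rr^2) + onset^2
  }, numeric(1))
}

model_r <- function(spec, isi_ms, n_mc = 100000, seed = 1) {
  if (spec$kind == "matched") {
    return(eval_correlation_model(isi_ms, spec$correlation_params))
  }
  if (spec$kind == "independent") return(0)
  d <- sample_doublets(spec, isi_ms, n_mc, seed = seed)
  cor(d$t_first, d$t_second)
}

#' Entropy and information rates from an ISI distribution
#'
#' Converts per-pattern entropies into rates: the conditional entropy rate
#' is the ISI-probability-weighted mean of the per-ISI conditional entropy
#' times the rate of ISI occurrence (`(n_spikes - 1) / duration`); the total
#' entropy rate is the discrete entropy of the ISI histogram times the same
#' rate; mutual information is their difference.
#'
#' @param spec A [timing_model_spec()].
#' @param hist An [isi_histogram()] giving the ISI probabilities.
#' @param n_spikes Number of spikes in the recording.
#' @param duration_s Recording length in seconds.
#' @param min_isi_ms ISIs below this are excluded from the conditional term
#'   (default 2 ms, the model domain floor).
#' @param hc_bits Optional override: per-bin conditional entropies (bits) on
#'   the histogram's retained bins (recycled), e.g. 0 for a deterministic
#'   responder.
#' @return Tibble of class `entropy_rates` with `total_bits_per_s`,
#'   `conditional_bits_per_s`, `mutual_info_bits_per_s`, `isi_rate_per_s`.
#' @export
entropy_rates <- function(spec, hist, n_spikes, duration_s, min_isi_ms = 2,
                          hc_bits = NULL) {
  stopifnot(inherits(hist, "isi_histogram"))
  p <- hist$prob
  if (sum(p) <= 0) abort("empty ISI histogram")
  isi_rate <- (n_spikes - 1) / duration_s
  total_bits <- discrete_entropy_bits(p / sum(p))

  sel <- p > 0 & hist$bin_mid >= min_isi_ms
  w <- p[sel] / sum(p[sel])
  hc <- hc_bits %||% conditional_entropy(spec, hist$bin_mid[sel])
  cond_bits <- sum(w * hc)

  tibble::tibble(
    total_bits_per_s = total_bits * isi_rate,
    conditional_bits_per_s = cond_bits * isi_rate,
    mutual_info_bits_per_s = (total_bits - cond_bits) * isi_rate,
    isi_rate_per_s = isi_rate)
}
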
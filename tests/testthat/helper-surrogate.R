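# Shared synthetic sessions, built once per test run and cached. The study
# conditions mirror the recording protocol the analysis assumes: a 30 min
# non-repeated 10-200 Hz Gaussian-noise stimulus driving a ~35 Hz surrogate
# interneuron, in a bursty (burst_gain = 3) and a linear-control
# (burst_gain = 0) configuration.

.cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .cache)) assign(key, force(expr), envir = .cache)
  get(key, envir = .cache)
}

long_stimulus <- function() {
  cached("stim_long", generate_stimulus(1800 * 1000, seed = 101))
}

surrogate_session <- function(burst_gain) {
  key <- paste0("session_bg", burst_gain)
  cached(key, {
    stim <- long_stimulus()
    train <- encode(stim, encoder_spec(burst_gain = burst_gain), seed = 202)
    ens <- collect_isolated_patterns(train, stim)
    list(train = train, ensembles = ens,
         stsm = fit_gaussian_model(ens$singlet$segments, "STSM"))
  })
}

shared_reduced_space <- function() {
  cached("reduced", fit_reduced_space(long_stimulus()))
}

# DTSM-vs-sDTSM cross-validated LLR table for one surrogate session.
session_llr_table <- function(burst_gain) {
  key <- paste0("llr_bg", burst_gain)
  cached(key, {
    ses <- surrogate_session(burst_gain)
    rs <- shared_reduced_space()
    purrr::map_dfr(ses$ensembles$doublet, function(eb) {
      res <- llr_test(
        eb$segments, eb$folds,
        fit_a = function(tr) fit_gaussian_model(tr, "DTSM", eb$isi_ms),
        fit_b = function(tr) synthesize_doublet_model(
          ses$stsm, eb$isi_ms, fit_gaussian_model(tr, "DTSM", eb$isi_ms), rs),
        reduced_space = rs, isi_ms = eb$isi_ms)
      tidy(res)
    })
  })
}

# Constructed frozen-noise raster with one reliable doublet event at
# 100 / (100 + isi) ms plus background spikes, for event-detection tests.
constructed_doublet_raster <- function(n_trials = 60, isi = 2.6,
                                       sd1 = 0.3, sd2 = 0.5,
                                       n_background = 8, duration = 1000,
                                       seed = 1) {
  withr::with_seed(seed, {
    rows <- purrr::map(seq_len(n_trials), function(i) {
      bg <- sort(runif(n_background, 300, duration - 10))
      bg <- bg[c(TRUE, diff(bg) > 25)]
      tibble::tibble(
        trial_id = i,
        time_ms = c(100 + rnorm(1, 0, sd1), 100 + isi + rnorm(1, 0, sd2), bg))
    })
    spike_raster(dplyr::bind_rows(rows), duration_ms = duration)
  })
}

# Band-limited unit-RMS pulse at 10 kHz used as a dejittering template.
dejitter_template <- function(len = 5000) {
  x <- numeric(len)
  i <- seq_len(500)
  x[2000 + i] <- exp(-(i - 250)^2 / (2 * 60^2)) * sin(2 * pi * 70 * i / 10000)
  k <- doubletcode:::band_limit(x, 10000, c(10, 200))
  k / sqrt(mean(k^2))
}
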
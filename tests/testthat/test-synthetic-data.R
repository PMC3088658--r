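test_that("generated stimulus is band-limited, Gaussian and RMS-calibrated", {
  s <- generate_stimulus(10000, rms = 74, seed = 1)
  rms <- sqrt(mean(s$samples^2))
  expect_gt(rms, 72.5)
  expect_lt(rms, 75.5)

  # Gaussian marginal: small excess kurtosis at 10 s
  k <- mean(s$samples^4) / mean(s$samples^2)^2 - 3
  expect_lt(abs(k), 0.1)

  # out-of-band power < 1% (two-sided periodogram)
  p <- Mod(fft(s$samples))^2
  f <- seq(0, s$rate_hz, length.out = length(p) + 1)[seq_along(p)]
  f <- pmin(f, s$rate_hz - f)
  expect_lt(sum(p[f >= 300 & f <= 500]) / sum(p), 0.01)
  expect_lt(sum(p[f < 5 | f > 220]) / sum(p), 0.01)

  # determinism under seed
  expect_identical(s$samples, generate_stimulus(10000, rms = 74, seed = 1)$samples)
})

test_that("stimulus is spectrally flat within the pass band", {
  s <- generate_stimulus(60000, seed = 2)
  sp <- stats::spec.pgram(stats::ts(s$samples, frequency = s$rate_hz),
                          spans = 101, plot = FALSE, taper = 0)
  sel <- sp$freq >= 20 & sp$freq <= 190
  expect_lt(max(sp$spec[sel]) / min(sp$spec[sel]), 3)
})

test_that("invalid stimulus requests are rejected", {
  expect_error(generate_stimulus(-5), "positive")
  expect_error(generate_stimulus(1000, band = c(200, 10)), "band")
  expect_error(generate_stimulus(1000, rate_hz = 300, band = c(10, 200)),
               "band")
})

test_that("encoder respects the refractory floor and empty-stimulus limit", {
  s <- generate_stimulus(30000, seed = 3)
  tr <- encode(s, encoder_spec(burst_gain = 3), seed = 4)
  expect_gte(min(isis(tr)), 2)
  expect_true(all(diff(tr$time_ms) > 0))

  # constant (zero) stimulus drives no spikes
  s0 <- s
  s0$samples <- numeric(length(s$samples))
  expect_equal(nrow(encode(s0, encoder_spec(), seed = 5)), 0)
})

test_that("burst gain controls the short-ISI doublet fraction", {
  s <- generate_stimulus(120000, seed = 6)
  t0 <- encode(s, encoder_spec(burst_gain = 0), seed = 7)
  t1 <- encode(s, encoder_spec(burst_gain = 3), seed = 7)
  expect_lt(mean(isis(t0) < 3), mean(isis(t1) < 3))
  # mean rate in the sustained-firing range
  expect_gt(nrow(t1) / 120, 20)
  expect_lt(nrow(t1) / 120, 40)
})

test_that("frozen-noise sessions are reproducible and shaped correctly", {
  s <- generate_stimulus(5000, seed = 8)
  r1 <- frozen_noise_session(s, encoder_spec(burst_gain = 3), 2, seed = 9)
  expect_equal(sort(unique(r1$trial_id)), 1:2)
  r2 <- frozen_noise_session(s, encoder_spec(burst_gain = 3), 2, seed = 9)
  expect_identical(r1$time_ms, r2$time_ms)
  expect_error(frozen_noise_session(s, encoder_spec(), 1), "n_repeats")
})

test_that("encoder latency-noise parameter is recovered from frozen rasters", {
  # sharply selective sparse encoder: reliable isolated spike events whose
  # residual sampling jitter can be subtracted in quadrature
  s <- generate_stimulus(30000, seed = 10)
  spec0 <- encoder_spec(beta = 3.5, target_rate_hz = 8, jitter_sd_ms = 0)
  spec3 <- encoder_spec(beta = 3.5, target_rate_hz = 8, jitter_sd_ms = 0.3)
  r0 <- frozen_noise_session(s, spec0, 85, seed = 11)
  r3 <- frozen_noise_session(s, spec3, 85, seed = 11)
  ev <- raster_jitter(r0, max_missing = 0.3)$events
  sd_at <- function(r, t_star) {
    sel <- r[r$time_ms >= t_star - 5 & r$time_ms <= t_star + 5, ]
    cnt <- table(factor(sel$trial_id, levels = 1:85))
    keep <- as.integer(names(cnt)[cnt == 1])
    sd(sel$time_ms[sel$trial_id %in% keep])
  }
  rec <- vapply(ev$t_mean, function(t_star) {
    sqrt(max(sd_at(r3, t_star)^2 - sd_at(r0, t_star)^2, 0))
  }, numeric(1))
  expect_gt(length(rec), 10)
  expect_gt(median(rec), 0.2)
  expect_lt(median(rec), 0.5)
})

test_that("ground-truth doublet simulation delegates to the timing models", {
  spec <- timing_model_spec("matched")
  d <- simulate_ground_truth_doublets(2.6, 85, spec, seed = 12)
  expect_equal(nrow(d), 85)
  expect_true(all(d$t_second >= d$t_first))
  # with R > 0.5 at short ISIs, ISI SD < first-spike SD (var(ISI) = 2 s0^2 (1-R))
  big <- simulate_ground_truth_doublets(2.6, 20000, spec, seed = 13)
  expect_lt(sd(big$t_second - big$t_first), sd(big$t_first))
  # long-ISI independence: negligible correlation
  far <- sample_doublets(timing_model_spec("independent"), 40, 10000, seed = 14)
  expect_lt(abs(cor(far$t_first, far$t_second)), 0.05)
})
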
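test_that("a reliable doublet is identified with the expected ISI", {
  r <- constructed_doublet_raster(n_trials = 60, isi = 2.6)
  ev <- identify_events(r)
  expect_equal(length(unique(ev$event_id)), 1L)
  pr <- event_precision(ev)
  expect_equal(pr$isi_ms, 2.6, tolerance = 0.15)
  expect_gt(pr$n_trials, 40)
})

test_that("contaminated windows are rejected by the 20% rule", {
  r <- constructed_doublet_raster(n_trials = 60, seed = 2)
  # extra spike inside the event window for 30% of mid-session trials
  extra <- tibble::tibble(trial_id = 21:38, time_ms = 101.3)
  r2 <- spike_raster(dplyr::bind_rows(as.data.frame(r), extra),
                     duration_ms = 1000)
  ev <- identify_events(r2)
  expect_equal(nrow(ev), 0L)
})

test_that("leading high-rate trials are excluded before the PSTH", {
  r <- constructed_doublet_raster(n_trials = 60, seed = 3)
  # first five trials at far higher rate (adaptation phase)
  burst <- tibble::tibble(trial_id = rep(1:5, each = 30),
                          time_ms = rep(seq(300, 880, by = 20), 5))
  r2 <- spike_raster(dplyr::bind_rows(as.data.frame(r), burst),
                     duration_ms = 1000)
  ev <- identify_events(r2)
  expect_gt(nrow(ev), 0)
  expect_false(any(ev$trial_id %in% 1:5))
})

test_that("event precision matches the quadrature identity", {
  # independent 0.6 / 0.5 ms spikes: independent-prediction ISI SD is 0.8 ms
  expect_equal(round(independent_isi_sd(0.6, 0.5), 1), 0.8)

  withr::with_seed(5, {
    ev <- tibble::tibble(event_id = 1,
                         trial_id = 1:5000,
                         t_first = 100 + rnorm(5000, 0, 0.6),
                         t_second = 106.5 + rnorm(5000, 0, 0.5))
  })
  pr <- event_precision(ev)
  expect_equal(pr$isi_sd_ms, 0.78, tolerance = 0.03)
  expect_lt(abs(pr$r), 0.05)
  # internal consistency: var(ISI) = var(t1) + var(t2) - 2 cov
  v <- var(ev$t_second - ev$t_first)
  expect_equal(v, var(ev$t_first) + var(ev$t_second) -
                 2 * cov(ev$t_first, ev$t_second), tolerance = 1e-12)

  # perfectly correlated pairs: ISI SD 0, R = 1
  ev2 <- tibble::tibble(event_id = 1, trial_id = 1:50,
                        t_first = 100 + rnorm(50, 0, 0.4))
  ev2$t_second <- ev2$t_first + 2.6
  pr2 <- event_precision(ev2)
  expect_equal(pr2$isi_sd_ms, 0)
  expect_equal(pr2$r, 1)
})

test_that("correlation is recovered from correlated samples", {
  withr::with_seed(6, {
    t1 <- rnorm(20000, 0, 0.3)
    t2 <- 5 + 0.8 * (0.5 / 0.3) * t1 + rnorm(20000, 0, 0.5 * sqrt(1 - 0.64))
    pr <- event_precision(tibble::tibble(event_id = 1, trial_id = 1:20000,
                                         t_first = t1, t_second = t2))
  })
  expect_gt(pr$r, 0.75)
  expect_lt(pr$r, 0.85)
})

test_that("raster jitter estimates latency SD and is translation invariant", {
  withr::with_seed(7, {
    lat <- purrr::map(1:50, function(e) 100 + e * 60 + rnorm(85, 0, 1.3))
    r <- spike_raster(
      tibble::tibble(trial_id = rep(rep(1:85, 50)), time_ms = unlist(lat)),
      duration_ms = 60 * 52)
  })
  j <- raster_jitter(r)
  expect_equal(j$jitter_ms, 1.3, tolerance = 0.1)

  r2 <- r
  r2$time_ms <- r2$time_ms + 7
  attr(r2, "duration_ms") <- attr(r, "duration_ms") + 7
  expect_equal(raster_jitter(r2)$jitter_ms, j$jitter_ms, tolerance = 1e-12)

  # zero-noise generator
  r0 <- spike_raster(tibble::tibble(trial_id = rep(1:30, 5),
                                    time_ms = rep(c(50, 100, 150, 200, 250),
                                                  each = 30)),
                     duration_ms = 300)
  expect_equal(raster_jitter(r0)$jitter_ms, 0)
})

test_that("dejittering recovers applied latency shifts", {
  kern <- dejitter_template()
  withr::with_seed(8, {
    shifts <- rnorm(400, 0, 2.1)
    segs <- t(vapply(shifts, function(sh) {
      doubletcode:::shift_vec(kern, round(sh * 10)) +
        rnorm(length(kern), 0, sqrt(1 / 3))
    }, numeric(length(kern))))
  })
  dj <- dejitter_latencies(segs)
  expect_true(dj$converged)
  expect_equal(dj$jitter_ms, 2.1, tolerance = 0.25)
  # recovered shifts track the true ones
  expect_gt(cor(dj$shifts_ms, shifts), 0.95)

  # zero applied shifts -> near-zero jitter
  withr::with_seed(9, {
    segs0 <- t(vapply(1:200, function(i) {
      kern + rnorm(length(kern), 0, sqrt(1 / 3))
    }, numeric(length(kern))))
  })
  expect_lt(dejitter_latencies(segs0)$jitter_ms, 0.3)
})
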
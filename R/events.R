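#' Identify repeatable doublet events in a frozen-noise raster
#'
#' Event identification for repeated-stimulus rasters: (1) leading trials
#' whose firing rate exceeds `adaptation_factor` times the grand mean rate
#' are dropped (adaptation rule); (2) a PSTH at `psth_bin_ms` resolution is
#' thresholded at `psth_threshold` times the session mean rate; (3)
#' contiguous supra-threshold bins, padded by 1 ms on each side, delimit
#' candidate event windows; (4) windows in which at least
#' `1 - contamination_max` of trials contain exactly two spikes are kept;
#' (5) per-trial first/second spike times are extracted from those clean
#' trials.
#'
#' @param raster A `spike_raster` with >= 20 trials.
#' @param psth_bin_ms PSTH bin width (default 1 ms).
#' @param adaptation_factor Leading-trial exclusion factor (default 1.2).
#' @param contamination_max Maximum tolerated fraction of trials whose
#'   window content is not exactly two spikes (default 0.2).
#' @param psth_threshold Event threshold as a multiple of the session mean
#'   rate (default 2).
#' @param min_trials Minimum clean trials per retained event (default 20).
#' @return Tibble with columns `event_id`, `trial_id`, `t_first`, `t_second`
#'   (empty if no event qualifies).
#' @export
identify_events <- function(raster, psth_bin_ms = 1, adaptation_factor = 1.2,
                            contamination_max = 0.2, psth_threshold = 2,
                            min_trials = 20) {
  assert_spikes(raster)
  duration <- spike_duration(raster)
  trials <- sort(unique(raster$trial_id))
  if (length(trials) < 20) abort("need a raster with at least 20 trials")

  counts <- purrr::map_dbl(trials,
                           function(tr) sum(raster$trial_id == tr))
  grand <- mean(counts)
  # drop only the leading run of over-adapted trials
  over <- counts > adaptation_factor * grand
  n_drop <- if (any(!over)) which(!over)[1] - 1 else length(trials)
  keep_trials <- trials[setdiff(seq_along(trials), seq_len(n_drop))]
  r <- raster[raster$trial_id %in% keep_trials, ]
  n_tr <- length(keep_trials)

  nb <- ceiling(duration / psth_bin_ms)
  psth <- tabulate(bin_index(r$time_ms, psth_bin_ms), nbins = nb) / n_tr
  mean_per_bin <- nrow(r) / n_tr / nb
  above <- psth > psth_threshold * mean_per_bin

  # contiguous supra-threshold runs -> windows padded by 1 ms
  runs <- rle(above)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  win <- tibble::tibble(
    lo = (starts[runs$values] - 1) * psth_bin_ms - 1,
    hi = ends[runs$values] * psth_bin_ms + 1)
  if (nrow(win) == 0) return(empty_events())

  out <- purrr::imap(seq_len(nrow(win)), function(w, id) {
    lo <- win$lo[w]; hi <- win$hi[w]
    sel <- r[r$time_ms >= lo & r$time_ms < hi, ]
    per <- split(sel$time_ms, factor(sel$trial_id, levels = keep_trials))
    nsp <- lengths(per)
    clean <- nsp == 2
    if (mean(!clean & nsp > 0) > contamination_max) return(NULL)
    if (sum(clean) < max(min_trials, 2) ||
        sum(clean) < (1 - contamination_max) * n_tr) return(NULL)
    tibble::tibble(
      trial_id = keep_trials[clean],
      t_first = purrr::map_dbl(per[clean], 1),
      t_second = purrr::map_dbl(per[clean], 2))
  })
  out <- purrr::compact(out)
  if (!length(out)) return(empty_events())
  dplyr::bind_rows(purrr::imap(out, function(d, i) {
    d$event_id <- i
    d[, c("event_id", "trial_id", "t_first", "t_second")]
  }))
}

empty_events <- function() {
  tibble::tibble(event_id = integer(), trial_id = integer(),
                 t_first = numeric(), t_second = numeric())
}

#' Per-event timing precision
#'
#' Summarizes each doublet event: mean ISI, onset jitter (SD of the first
#' spike time across trials), ISI SD, Pearson correlation R between first
#' and second spike times, and the ISI SD predicted if the two spikes were
#' independent (`sqrt(sd1^2 + sd2^2)`).
#'
#' @param events Event table from [identify_events()] (columns `event_id`,
#'   `t_first`, `t_second`).
#' @return Tibble with one row per event: `event_id`, `n_trials`, `isi_ms`,
#'   `onset_jitter_ms`, `second_sd_ms`, `isi_sd_ms`, `isi_sd_indep_ms`, `r`.
#'   Degenerate events (zero variance in either spike) get an `NA`
#'   correlation.
#' @export
event_precision <- function(events) {
  stopifnot(all(c("event_id", "t_first", "t_second") %in% names(events)))
  dplyr::summarise(
    dplyr::group_by(tibble::as_tibble(events), .data$event_id),
    n_trials = dplyr::n(),
    isi_ms = mean(.data$t_second - .data$t_first),
    onset_jitter_ms = sd(.data$t_first),
    second_sd_ms = sd(.data$t_second),
    isi_sd_ms = sd(.data$t_second - .data$t_first),
    isi_sd_indep_ms = sqrt(sd(.data$t_first)^2 + sd(.data$t_second)^2),
    r = if (dplyr::n() >= 2 && sd(.data$t_first) > 0 && sd(.data$t_second) > 0)
          cor(.data$t_first, .data$t_second) else NA_real_,
    .groups = "drop")
}

#' ISI standard deviation predicted under spike independence
#'
#' Quadrature combination of the two spike-time SDs: for SDs of 0.6 and
#' 0.5 ms this gives 0.8 ms.
#'
#' @param sd_first,sd_second Spike-time SDs in ms.
#' @return `sqrt(sd_first^2 + sd_second^2)` (ms).
#' @export
independent_isi_sd <- function(sd_first, sd_second) {
  sqrt(sd_first^2 + sd_second^2)
}

#' Convert between ISI and instantaneous firing rate
#'
#' `isi_to_rate(44)` is ~23 Hz; the inverse maps rates back to ISIs.
#'
#' @param isi_ms ISI in ms.
#' @param rate_hz Rate in Hz.
#' @return Rate in Hz (or ISI in ms).
#' @export
isi_to_rate <- function(isi_ms) 1000 / isi_ms

#' @rdname isi_to_rate
#' @export
rate_to_isi <- function(rate_hz) 1000 / rate_hz

#' Raster-based jitter of isolated single spikes
#'
#' Pools spikes across trials, clusters them into events separated by at
#' least `isolation_ms` of pooled silence, keeps events in which (nearly)
#' every trial contributes exactly one spike, and returns the mean across
#' events of the across-trial SD of the spike latency.
#'
#' @param raster A `spike_raster` from repeated (frozen-noise) trials.
#' @param isolation_ms Minimum pooled gap separating events (default 20 ms).
#' @param max_missing Maximum fraction of trials allowed to deviate from
#'   exactly one spike per event (default 0.1).
#' @return List with `jitter_ms` (the estimate), `n_events`, and the
#'   per-event tibble `events`.
#' @export
raster_jitter <- function(raster, isolation_ms = 20, max_missing = 0.1) {
  assert_spikes(raster)
  trials <- sort(unique(raster$trial_id))
  n_tr <- length(trials)
  t_all <- sort(raster$time_ms)
  if (length(t_all) < n_tr) abort("no isolated single-spike events found")
  grp <- cumsum(c(1, diff(t_all) >= isolation_ms))
  per <- purrr::map(split(t_all, grp), range)

  ev <- purrr::compact(purrr::map(per, function(rg) {
    sel <- raster[raster$time_ms >= rg[1] & raster$time_ms <= rg[2], ]
    nsp <- tabulate(factor(sel$trial_id, levels = trials), nbins = n_tr)
    if (mean(nsp != 1) > max_missing) return(NULL)
    lat <- sel$time_ms[sel$trial_id %in% trials[nsp == 1]]
    ok <- sel$trial_id %in% trials[which(nsp == 1)]
    tibble::tibble(n_trials = sum(nsp == 1),
                   t_mean = mean(sel$time_ms[ok]),
                   latency_sd = sd(sel$time_ms[ok]))
  }))
  if (!length(ev)) abort("no isolated single-spike events found")
  events <- dplyr::bind_rows(ev)
  list(jitter_ms = mean(events$latency_sd), n_events = nrow(events),
       events = events)
}

#' Dejittering estimate of single-spike temporal uncertainty
#'
#' Iteratively aligns spike-conditioned stimulus segments to their ensemble
#' mean: each iteration computes the mean template, shifts every segment
#' (bounded by `max_shift_ms`) to maximize its inner product with the
#' template, and repeats until the mean absolute shift update falls below
#' 0.05 ms or `max_iter` iterations. The jitter estimate is the SD of the
#' final per-segment shifts.
#'
#' @param segments Numeric matrix, one stimulus segment per row, all sampled
#'   at `rate_hz`.
#' @param rate_hz Sampling rate of the segments (default 10000).
#' @param max_shift_ms Shift bound per segment (default 5 ms).
#' @param max_iter Iteration cap (default 50).
#' @return List with `jitter_ms`, `shifts_ms`, `template`, `iterations`,
#'   `converged`.
#' @export
dejitter_latencies <- function(segments, rate_hz = 10000, max_shift_ms = 5,
                               max_iter = 50) {
  stopifnot(is.matrix(segments), nrow(segments) >= 2)
  n <- nrow(segments)
  len <- ncol(segments)
  dt <- 1000 / rate_hz
  max_k <- round(max_shift_ms / dt)
  shifts <- integer(n) # in samples; positive = segment is late
  converged <- FALSE

  # Template candidates: template shifted by every allowed lag, as columns.
  lags <- -max_k:max_k
  iter_done <- 0
  for (it in seq_len(max_iter)) {
    iter_done <- it
    aligned <- shift_rows(segments, -shifts)
    template <- colMeans(aligned)
    tmat <- vapply(lags, function(l) shift_vec(template, l), numeric(len))
    score <- segments %*% tmat            # n x n_lags inner products
    best <- lags[max.col(score, ties.method = "first")]
    delta <- best - shifts
    shifts <- best
    if (mean(abs(delta)) * dt < 0.05) { converged <- TRUE; break }
  }
  shifts_ms <- shifts * dt
  shifts_ms <- shifts_ms - mean(shifts_ms)
  if (!converged) {
    warn("dejittering did not converge; returning last iterate")
  }
  list(jitter_ms = sd(shifts_ms), shifts_ms = shifts_ms,
       template = colMeans(shift_rows(segments, -shifts)),
       iterations = iter_done, converged = converged)
}

# Shift a vector by k samples (positive = delay), zero-padding the ends.
shift_vec <- function(x, k) {
  n <- length(x)
  out <- numeric(n)
  if (k >= 0) out[(1 + k):n] <- x[1:(n - k)] else out[1:(n + k)] <- x[(1 - k):n]
  out
}

shift_rows <- function(m, ks) {
  out <- m
  for (i in seq_len(nrow(m))) out[i, ] <- shift_vec(m[i, ], ks[i])
  out
}
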
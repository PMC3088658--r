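#' Spike rasters as tibbles
#'
#' Spike data travel through the package as tibbles with columns `trial_id`
#' and `time_ms` (sorted within trial), plus a `duration_ms` attribute. A
#' single spike train is a raster with one trial.
#'
#' @param spikes Data frame with columns `trial_id`, `time_ms`.
#' @param duration_ms Recording length per trial in ms (all trials share it).
#' @return A tibble of class `spike_raster`.
#' @export
spike_raster <- function(spikes, duration_ms) {
  assert_spikes(spikes)
  spikes <- dplyr::arrange(tibble::as_tibble(spikes),
                           .data$trial_id, .data$time_ms)
  if (any(spikes$time_ms < 0) || any(spikes$time_ms > duration_ms)) {
    abort("spike times must lie in [0, duration_ms]")
  }
  structure(spikes, duration_ms = duration_ms,
            class = c("spike_raster", class(spikes)))
}

#' @rdname spike_raster
#' @param times_ms Sorted spike times of a single train.
#' @export
spike_train <- function(times_ms, duration_ms = max(times_ms, 0)) {
  spike_raster(tibble::tibble(trial_id = rep(1L, length(times_ms)),
                              time_ms = as.numeric(times_ms)),
               duration_ms = duration_ms)
}

#' @export
print.spike_raster <- function(x, ...) {
  nt <- dplyr::n_distinct(x$trial_id)
  cat(sprintf("<spike_raster> %d spikes, %d trial(s), %.1f s each\n",
              nrow(x), nt, attr(x, "duration_ms") / 1000))
  NextMethod()
}

#' Consecutive interspike intervals of one or more trains
#'
#' @param spikes A spike raster; ISIs are computed within each trial.
#' @return Numeric vector of ISIs in ms.
#' @export
isis <- function(spikes) {
  assert_spikes(spikes)
  unlist(lapply(split(spikes$time_ms, spikes$trial_id), diff),
         use.names = FALSE)
}

#' Raster plot
#'
#' @param object A `spike_raster`.
#' @param ... Unused.
#' @method autoplot spike_raster
#' @export
autoplot.spike_raster <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$time_ms, .data$trial_id)) +
    ggplot2::geom_point(shape = "|", size = 2) +
    ggplot2::labs(x = "time (ms)", y = "trial")
}
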
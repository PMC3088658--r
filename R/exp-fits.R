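# Exponential-decay fits shared by the jitter-vs-ISI, correlation-vs-ISI and
# LLR-decay analyses. Parameterization, by model order (number of free
# parameters):
#   2: y = x1 * exp(-ISI/x2)
#   3: y = x1 * exp(-ISI/x2) + x3
#   4: y = x1 * exp(-ISI/x2) + x3 * exp(-ISI/x4)
# Order is selected by AIC unless a single order is requested.

exp_form <- function(order) {
  switch(as.character(order),
    "2" = function(isi, p) p[1] * exp(-isi / p[2]),
    "3" = function(isi, p) p[1] * exp(-isi / p[2]) + p[3],
    "4" = function(isi, p) p[1] * exp(-isi / p[2]) + p[3] * exp(-isi / p[4]),
    abort("order must be 2, 3 or 4"))
}

exp_gradient <- function(order, isi, p) {
  e1 <- exp(-isi / p[2])
  g <- cbind(e1, p[1] * e1 * isi / p[2]^2)
  if (order == 3) g <- cbind(g, 1)
  if (order == 4) {
    e2 <- exp(-isi / p[4])
    g <- cbind(g, e2, p[3] * e2 * isi / p[4]^2)
  }
  g
}

fit_one_order <- function(isi, y, order, weights = NULL) {
  rng <- diff(range(isi))
  tail_y <- mean(y[isi >= quantile(isi, 0.7)])
  head_y <- y[which.min(isi)]
  starts <- list()
  for (tau in c(rng / 10, rng / 3, 2)) {
    p0 <- switch(as.character(order),
      "2" = c(x1 = head_y, x2 = tau),
      "3" = c(x1 = head_y - tail_y, x2 = tau, x3 = tail_y),
      "4" = c(x1 = head_y - tail_y, x2 = tau, x3 = tail_y, x4 = 5 * tau))
    starts[[length(starts) + 1]] <- p0
  }
  w <- weights %||% rep(1, length(y))
  lower <- rep(-Inf, order)
  lower[2] <- 0.05
  if (order == 4) lower[4] <- 0.05
  best <- NULL
  for (p0 in starts) {
    f <- exp_form(order)
    fit <- tryCatch(
      minpack.lm::nls.lm(
        par = p0, lower = lower,
        fn = function(p) sqrt(w) * (y - f(isi, p)),
        control = minpack.lm::nls.lm.control(maxiter = 500)),
      error = function(e) NULL)
    if (is.null(fit)) next
    ssr <- sum(fit$fvec^2)
    if (is.null(best) || ssr < best$ssr) best <- list(fit = fit, ssr = ssr)
  }
  if (is.null(best)) return(NULL)
  fit <- best$fit
  n <- length(y)
  k <- order
  sigma2 <- best$ssr / n
  aic <- n * log(sigma2) + 2 * (k + 1)
  # asymptotic covariance of the estimates
  vc <- tryCatch({
    h <- fit$hessian
    s2 <- best$ssr / (n - k)
    2 * s2 * solve(h)
  }, error = function(e) matrix(NA_real_, k, k))
  par <- fit$par
  # double exponential components are exchangeable: report the faster first
  if (order == 4 && is.finite(par[4]) && par[4] < par[2]) {
    perm <- c(3, 4, 1, 2)
    par <- setNames(par[perm], c("x1", "x2", "x3", "x4"))
    vc <- vc[perm, perm]
  }
  list(par = par, vcov = vc, ssr = best$ssr, aic = aic, order = order,
       n = n, df = n - k)
}

#' Fit an exponential-decay model of a quantity vs ISI
#'
#' Least-squares (Levenberg--Marquardt) fit of `y ~ f(ISI)` where `f` is an
#' exponential of 2, 3 or 4 parameters (see Details); when several orders are
#' allowed, the one with the lowest AIC is kept. Returns point estimates,
#' 95% confidence intervals from the asymptotic covariance, and a
#' prediction-band evaluator.
#'
#' @details Orders: 2 = `x1*exp(-ISI/x2)`; 3 adds a constant plateau `x3`;
#'   4 = `x1*exp(-ISI/x2) + x3*exp(-ISI/x4)` (double exponential).
#'
#' @param data Data frame with the ISI column `isi_ms` and a response column.
#' @param response Name of the response column.
#' @param orders Candidate model orders (subset of 2:4).
#' @param weights Optional per-point weights.
#' @return Object of class `exp_fit` with elements `params`, `ci` (95%),
#'   `vcov`, `aic`, `order`, `data`.
#' @export
fit_exp_decay <- function(data, response, orders = c(2, 3, 4),
                          weights = NULL) {
  stopifnot(is.data.frame(data), "isi_ms" %in% names(data),
            response %in% names(data))
  ok <- complete.cases(data[, c("isi_ms", response)])
  isi <- data$isi_ms[ok]
  y <- data[[response]][ok]
  if (length(unique(isi)) < 5) abort("need at least 5 distinct ISI values")
  fits <- purrr::compact(purrr::map(orders, function(o) {
    if (length(y) <= o) return(NULL)
    fit_one_order(isi, y, o, weights)
  }))
  if (!length(fits)) abort("all exponential fits failed")
  best <- fits[[which.min(purrr::map_dbl(fits, "aic"))]]
  se <- sqrt(pmax(diag(best$vcov), 0))
  tq <- qt(0.975, best$df)
  ci <- cbind(lower = best$par - tq * se, upper = best$par + tq * se)
  structure(
    list(params = best$par, se = se, ci = ci, vcov = best$vcov,
         aic = best$aic, order = best$order, ssr = best$ssr,
         df = best$df, response = response,
         data = tibble::tibble(isi_ms = isi, y = y),
         aic_all = setNames(purrr::map_dbl(fits, "aic"),
                            purrr::map_dbl(fits, "order"))),
    class = "exp_fit")
}

#' Evaluate an exponential fit (with 95% confidence band)
#'
#' @param object An `exp_fit`.
#' @param isi_ms ISIs at which to evaluate.
#' @param ... Unused.
#' @return Tibble with `isi_ms`, `fit`, `lower`, `upper` (95% band of the
#'   fitted curve, delta method).
#' @export
predict.exp_fit <- function(object, isi_ms, ...) {
  f <- exp_form(object$order)
  val <- unname(f(isi_ms, object$params))
  g <- exp_gradient(object$order, isi_ms, object$params)
  v <- rowSums((g %*% object$vcov) * g)
  half <- qt(0.975, object$df) * sqrt(pmax(v, 0))
  tibble::tibble(isi_ms = isi_ms, fit = val,
                 lower = val - half, upper = val + half)
}

#' @export
print.exp_fit <- function(x, ...) {
  p <- paste(sprintf("%s=%.3g", names(x$params), x$params), collapse = ", ")
  cat(sprintf("<exp_fit> order %d (%s): %s | AIC %.1f\n",
              x$order, x$response, p, x$aic))
  invisible(x)
}

#' @method tidy exp_fit
#' @export
tidy.exp_fit <- function(x, ...) {
  tibble::tibble(term = names(x$params), estimate = unname(x$params),
                 std.error = x$se,
                 conf.low = x$ci[, "lower"], conf.high = x$ci[, "upper"])
}

#' @method glance exp_fit
#' @export
glance.exp_fit <- function(x, ...) {
  tibble::tibble(order = x$order, AIC = x$aic, ssr = x$ssr,
                 nobs = nrow(x$data))
}

#' @method autoplot exp_fit
#' @export
autoplot.exp_fit <- function(object, ...) {
  grid <- seq(min(object$data$isi_ms), max(object$data$isi_ms),
              length.out = 200)
  band <- predict(object, grid)
  ggplot2::ggplot(object$data, ggplot2::aes(.data$isi_ms, .data$y)) +
    ggplot2::geom_ribbon(data = band,
                         ggplot2::aes(x = .data$isi_ms, ymin = .data$lower,
                                      ymax = .data$upper),
                         inherit.aes = FALSE, alpha = 0.25) +
    ggplot2::geom_line(data = band,
                       ggplot2::aes(.data$isi_ms, .data$fit),
                       inherit.aes = FALSE) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "ISI (ms)", y = object$response)
}

#' Printed best-fit coefficients of the pooled-data timing fits
#'
#' Reference parameter sets for the onset-jitter and spike-correlation
#' exponential models fitted to 7753 pooled doublet events: jitter
#' `(-1.0, 4.8, 1.1)` (simple exponential with plateau, ms) and correlation
#' `(2.3, 1.7, 0.2, 28.9)` (double exponential).
#'
#' @return Named list with `jitter` and `correlation` parameter vectors.
#' @export
reference_timing_params <- function() {
  list(jitter = c(x1 = -1.0, x2 = 4.8, x3 = 1.1),
       correlation = c(x1 = 2.3, x2 = 1.7, x3 = 0.2, x4 = 28.9))
}

#' Onset jitter and within-doublet correlation model curves
#'
#' Evaluate the exponential timing models at given ISIs. `eval_jitter_model`
#' is the 3-parameter form `x1*exp(-ISI/x2) + x3` (ms); `eval_correlation_model`
#' is the double exponential `x1*exp(-ISI/x2) + x3*exp(-ISI/x4)`, optionally
#' clamped to `[-1, 1]` for use as a correlation coefficient.
#'
#' @param isi_ms ISIs (ms).
#' @param params Parameter vector (defaults: pooled-data best fits, see
#'   [reference_timing_params()]).
#' @param clamp Clamp correlations into `[-1, 1]` (default TRUE).
#' @return Numeric vector.
#' @export
eval_jitter_model <- function(isi_ms,
                              params = reference_timing_params()$jitter) {
  unname(params[1] * exp(-isi_ms / params[2]) + params[3])
}

#' @rdname eval_jitter_model
#' @export
eval_correlation_model <- function(isi_ms,
                                   params = reference_timing_params()$correlation,
                                   clamp = TRUE) {
  r <- params[1] * exp(-isi_ms / params[2]) + params[3] * exp(-isi_ms / params[4])
  if (clamp) r <- pmin(pmax(r, -1), 1)
  unname(r)
}

#' Fit onset jitter as a function of ISI
#'
#' Exponential model of pooled per-event onset jitter vs mean ISI (simple
#' exponential with plateau; order selected by AIC among 2--4 parameters).
#'
#' @param events Data frame with columns `isi_ms` and `onset_jitter_ms`
#'   (e.g. from [event_precision()], pooled across events).
#' @param orders Candidate orders, default `c(2, 3, 4)`.
#' @return An `exp_fit`.
#' @export
fit_jitter_vs_isi <- function(events, orders = c(2, 3, 4)) {
  fit_exp_decay(events, "onset_jitter_ms", orders = orders)
}

#' Fit first/second-spike correlation as a function of ISI
#'
#' Double-exponential model of the Pearson correlation between first and
#' second spike times of pooled doublet events vs mean ISI.
#'
#' @param events Data frame with columns `isi_ms` and `r`.
#' @param orders Candidate orders, default 4 (double exponential).
#' @return An `exp_fit`.
#' @export
fit_correlation_vs_isi <- function(events, orders = 4) {
  fit_exp_decay(events, "r", orders = orders)
}
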
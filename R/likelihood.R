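#' Multivariate Gaussian log-likelihood
#'
#' `L = -1/2 [ n log(2*pi) + log|C| + (x - mu)' C^{-1} (x - mu) ]` (natural
#' log), evaluated via the Cholesky factor of `C`.
#'
#' @param x Numeric vector, or matrix with one sample per row.
#' @param model A `gsm` with positive-definite covariance.
#' @return Numeric vector of log-likelihoods (one per sample).
#' @export
gaussian_loglik <- function(x, model) {
  stopifnot(inherits(model, "gsm"))
  if (!is.matrix(x)) x <- matrix(x, nrow = 1)
  n <- length(model$mu)
  stopifnot(ncol(x) == n)
  ch <- tryCatch(chol(model$C), error = function(e) {
    abort(sprintf("covariance of model '%s' is singular", model$label))
  })
  logdet <- 2 * sum(log(diag(ch)))
  z <- backsolve(ch, t(x) - model$mu, transpose = TRUE)
  maha <- colSums(z^2)
  -0.5 * (n * log(2 * pi) + logdet + maha)
}

#' Cross-validated log-likelihood-ratio test between two stimulus models
#'
#' For each cross-validation fold, both models are fit on the training
#' segments and evaluated on the held-out segments; the per-sample LLR
#' `L_a - L_b` is pooled over folds, outliers beyond three SDs of the mean
#' are removed, and the mean with its 95% confidence interval is reported.
#' Positive values favor model builder `a`.
#'
#' Because the two models are typically estimated from very different
#' numbers of events (a per-ISI doublet ensemble vs thousands of singlets),
#' the raw held-out LLR carries a finite-sample bias of about `p/(2n)` nats
#' per model (`p` free Gaussian parameters, `n` training events): the model
#' with fewer events is penalized even when both hypotheses are true. With
#' `bias_correction = TRUE` (default) this first-order term is added back
#' for each model, centring the null at zero. A model whose `n_events` is
#' `NA` (an analytically specified model) gets no correction.
#'
#' @param segments Matrix of stimulus segments (rows), in the original
#'   50-sample space.
#' @param folds Integer fold labels (length `nrow(segments)`).
#' @param fit_a,fit_b Functions `(train_segments) -> gsm` building the two
#'   models from a training set (already-projected models may be returned;
#'   both must live in `reduced_space`).
#' @param reduced_space The [fit_reduced_space()] basis used for evaluation.
#' @param isi_ms Metadata: the test ensemble's ISI.
#' @param bias_correction Apply the first-order estimation-bias correction
#'   (default TRUE).
#' @return A list of class `llr_result`: `llr` (per-sample values after
#'   outlier removal), `mean`, `ci` (95%), `n_used`, `n_outliers_removed`,
#'   `isi_ms`, `bias_correction_nats` (mean correction applied).
#' @export
llr_test <- function(segments, folds, fit_a, fit_b, reduced_space,
                     isi_ms = NA_real_, bias_correction = TRUE) {
  stopifnot(is.matrix(segments), length(folds) == nrow(segments))
  corr_used <- numeric(0)
  vals <- purrr::map(sort(unique(folds)), function(f) {
    train <- segments[folds != f, , drop = FALSE]
    test <- segments[folds == f, , drop = FALSE]
    if (nrow(test) == 0) return(NULL)
    ma <- project_if_needed(fit_a(train), reduced_space)
    mb <- project_if_needed(fit_b(train), reduced_space)
    xt <- project_model(test, reduced_space)
    llr <- gaussian_loglik(xt, ma) - gaussian_loglik(xt, mb)
    if (bias_correction) {
      corr <- estimation_bias_nats(ma) - estimation_bias_nats(mb)
      corr_used <<- c(corr_used, rep(corr, length(llr)))
      llr <- llr + corr
    }
    llr
  })
  llr <- unlist(purrr::compact(vals))
  out <- summarize_llr(llr, isi_ms)
  out$bias_correction_nats <- if (bias_correction) mean(corr_used) else 0
  out
}

# Expected held-out log-likelihood deficit of a Gaussian fit by sample mean
# and (n-1)-divisor sample covariance, under Gaussian truth (exact Wishart
# expectations):
#   E[KL] = 1/2 [ E ln|S_hat / V| + (d(n-1)/(n-d-2))(1 + 1/n) - d ]
# with E ln|S_hat / V| = sum_i psi((n-i)/2) + d ln 2 - d ln(n-1) (a negative
# quantity). Falls back to first-order p/(2n) when n is too small.
estimation_bias_nats <- function(model) {
  n <- model$n_events
  if (is.null(n) || is.na(n) || n <= 0) return(0)
  d <- length(model$mu)
  # models that inherit only part of their parameters from the n-event fit
  # (e.g. a subspace-modified synthetic model) carry an effective count
  p_eff <- attr(model, "p_eff")
  if (!is.null(p_eff)) return(p_eff / (2 * n))
  if (n <= d + 2) return(d * (d + 3) / 2 / (2 * n))
  eld <- sum(digamma((n - seq_len(d)) / 2)) + d * log(2) - d * log(n - 1)
  0.5 * (eld + d * (n - 1) / (n - d - 2) * (1 + 1 / n) - d)
}

project_if_needed <- function(model, reduced_space) {
  if (length(model$mu) == ncol(reduced_space$basis)) model
  else project_model(model, reduced_space)
}

summarize_llr <- function(llr, isi_ms = NA_real_) {
  m0 <- mean(llr); s0 <- sd(llr)
  keep <- abs(llr - m0) <= 3 * s0 | s0 == 0
  removed <- sum(!keep)
  llr <- llr[keep]
  n <- length(llr)
  se <- sd(llr) / sqrt(n)
  half <- qt(0.975, n - 1) * se
  structure(
    list(llr = llr, mean = mean(llr),
         ci = c(lower = mean(llr) - half, upper = mean(llr) + half),
         n_used = n, n_outliers_removed = removed, isi_ms = isi_ms),
    class = "llr_result")
}

#' @export
print.llr_result <- function(x, ...) {
  cat(sprintf("<llr_result> mean %.3f [%.3f, %.3f], n = %d (%d outliers removed)\n",
              x$mean, x$ci[1], x$ci[2], x$n_used, x$n_outliers_removed))
  invisible(x)
}

#' @method tidy llr_result
#' @export
tidy.llr_result <- function(x, ...) {
  tibble::tibble(isi_ms = x$isi_ms, mean = x$mean,
                 ci_lo = x$ci[["lower"]], ci_hi = x$ci[["upper"]],
                 n = x$n_used, n_outliers_removed = x$n_outliers_removed)
}

#' Fit the LLR-vs-ISI decay
#'
#' Double-exponential least-squares fit (AIC order selection) of mean LLR
#' against ISI, reporting also the smallest ISI at which the fitted curve's
#' 95% band first includes zero -- beyond it the synthetic model is
#' statistically indistinguishable from the data model.
#'
#' @param llr_by_isi Data frame with columns `isi_ms` and `mean` (e.g.
#'   stacked `tidy()` rows of `llr_result` objects).
#' @param orders Candidate orders (default `c(2, 3, 4)`).
#' @param grid_ms Grid on which the zero-crossing is searched.
#' @return An `exp_fit` with extra element `zero_isi_ms`.
#' @export
fit_llr_decay <- function(llr_by_isi, orders = c(2, 3, 4),
                          grid_ms = seq(2, 40, by = 0.1)) {
  d <- tibble::tibble(isi_ms = llr_by_isi$isi_ms, llr = llr_by_isi$mean)
  fit <- fit_exp_decay(d, "llr", orders = orders)
  band <- predict(fit, grid_ms)
  inc <- is.na(band$lower) | (band$lower <= 0 & band$upper >= 0)
  fit$zero_isi_ms <- if (any(inc)) grid_ms[which(inc)[1]] else NA_real_
  fit
}

#' Offset scan: which synthetic model best explains each doublet ensemble
#'
#' Builds synthetic doublet models over a grid of offsets and, for every
#' test-ISI ensemble, computes the per-sample posterior over offset models
#' (uniform prior, Gaussian likelihoods in the reduced space), averages
#' posteriors over samples, and column-normalizes. The compressive
#' nonlinearity appears as a peak at offset 0 for the shortest ISIs.
#'
#' @param ensembles Named list of test ensembles (name = ISI), each with
#'   `segments` and `isi_ms` (e.g. `collect_isolated_patterns()$doublet`).
#' @param stsm Singlet model in the original space.
#' @param dtsms Named list of data doublet models (by ISI) supplying the
#'   volume scaling for each synthesized model; matched to each test ISI,
#'   falling back to the nearest available ISI.
#' @param offsets Offset grid in ms (default -3..29).
#' @param reduced_space The shared reduced space.
#' @return List of class `offset_scan`: `P` (matrix offsets x test ISIs,
#'   columns sum to 1), `peak` (tibble `isi_ms`, `peak_offset_ms`),
#'   `offsets`.
#' @export
offset_scan <- function(ensembles, stsm, dtsms, offsets = -3:29,
                        reduced_space) {
  isi_names <- names(ensembles)
  P <- matrix(NA_real_, length(offsets), length(isi_names),
              dimnames = list(offsets, isi_names))
  for (j in seq_along(isi_names)) {
    ens <- ensembles[[j]]
    scale_ref <- dtsms[[nearest_name(names(dtsms), ens$isi_ms)]]
    models <- purrr::map(offsets, function(o) {
      project_model(
        synthesize_doublet_model(stsm, o, scale_ref, reduced_space),
        reduced_space)
    })
    xt <- project_model(ens$segments, reduced_space)
    ll <- vapply(models, function(m) gaussian_loglik(xt, m),
                 numeric(nrow(xt)))
    if (!is.matrix(ll)) ll <- matrix(ll, nrow = 1)
    post <- t(apply(ll, 1, function(l) {
      w <- exp(l - max(l)); w / sum(w)
    }))
    pj <- colMeans(post)
    P[, j] <- pj / sum(pj)
  }
  peak <- tibble::tibble(
    isi_ms = as.numeric(isi_names),
    peak_offset_ms = offsets[apply(P, 2, which.max)])
  structure(list(P = P, peak = peak, offsets = offsets),
            class = "offset_scan")
}

nearest_name <- function(nms, isi) {
  vals <- as.numeric(nms)
  nms[which.min(abs(vals - isi))]
}

#' @export
print.offset_scan <- function(x, ...) {
  cat("<offset_scan> peak offsets by test ISI:\n")
  print(x$peak, n = nrow(x$peak))
  invisible(x)
}

#' @method autoplot offset_scan
#' @export
autoplot.offset_scan <- function(object, ...) {
  d <- tibble::as_tibble(as.table(object$P), .name_repair = "minimal")
  names(d) <- c("offset_ms", "isi_ms", "p")
  d$offset_ms <- as.numeric(as.character(d$offset_ms))
  d$isi_ms <- as.numeric(as.character(d$isi_ms))
  ggplot2::ggplot(d, ggplot2::aes(.data$isi_ms, .data$offset_ms,
                                  fill = .data$p)) +
    ggplot2::geom_raster() +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         color = "white") +
    ggplot2::labs(x = "test ISI (ms)", y = "model offset (ms)",
                  fill = "P(model)")
}

#' Build the compressed synthetic doublet model (csDTSM)
#'
#' The synthetic doublet model rebuilt at the offset that best explains the
#' test ensemble of a given ISI (the peak of the offset scan) rather than
#' at the nominal ISI itself.
#'
#' @param stsm Singlet model (original space).
#' @param test_isi_ms Test ensemble ISI.
#' @param scan An [offset_scan()] result.
#' @param dtsm_for_scaling Data doublet model fixing the volume scale.
#' @param reduced_space Shared reduced space.
#' @return A `gsm` labeled `"csDTSM"`.
#' @export
build_csdtsm <- function(stsm, test_isi_ms, scan, dtsm_for_scaling,
                         reduced_space) {
  stopifnot(inherits(scan, "offset_scan"))
  row <- scan$peak[scan$peak$isi_ms == test_isi_ms, ]
  if (nrow(row) != 1) abort("test ISI not present in the offset scan")
  out <- synthesize_doublet_model(stsm, row$peak_offset_ms, dtsm_for_scaling,
                                  reduced_space)
  out$label <- "csDTSM"
  out$isi_ms <- test_isi_ms
  attr(out, "offset_ms") <- row$peak_offset_ms
  out
}
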
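# iSTAC: the subspace that preserves the most Kullback-Leibler divergence
# between two Gaussian stimulus models (comparison vs base).

# Symmetric inverse square root of a positive-definite matrix.
inv_sqrtm <- function(C) {
  e <- eigen((C + t(C)) / 2, symmetric = TRUE)
  if (min(e$values) <= 0) abort("base covariance is not positive definite")
  e$vectors %*% (t(e$vectors) / sqrt(e$values))
}

sqrtm_sym <- function(C) {
  e <- eigen((C + t(C)) / 2, symmetric = TRUE)
  e$vectors %*% (t(e$vectors) * sqrt(pmax(e$values, 0)))
}

#' Whiten a comparison model against a base model
#'
#' Affine transform sending the base model to (0, I):
#' `mu_W = C_b^{-1/2} (mu_c - mu_b)`, `C_W = C_b^{-1/2} C_c C_b^{-1/2}`
#' (symmetric square root). KL divergences computed from the whitened pair
#' equal those of the raw pair.
#'
#' @param base,comparison `gsm` models in the same space; the base
#'   covariance must be positive definite.
#' @return List of class `whitened_model`: `mu_w`, `C_w`, `n`.
#' @export
whiten <- function(base, comparison) {
  stopifnot(inherits(base, "gsm"), inherits(comparison, "gsm"),
            length(base$mu) == length(comparison$mu))
  W <- inv_sqrtm(base$C)
  mu_w <- drop(W %*% (comparison$mu - base$mu))
  C_w <- W %*% comparison$C %*% W
  structure(list(mu_w = mu_w, C_w = (C_w + t(C_w)) / 2, n = length(mu_w)),
            class = "whitened_model")
}

#' Gaussian KL divergence of a whitened model (optionally in a subspace)
#'
#' In the whitened coordinates the KL divergence from the base (0, I) to
#' the comparison `(mu_W, C_W)` is
#' `D = [Tr(C_W) + mu_W' mu_W - n - ln|C_W|] / (2 ln 2)` bits. Supplying an
#' orthonormal basis `B` restricts the divergence to that subspace (the
#' same formula on `B' C_W B` and `B' mu_W`).
#'
#' @param wm A [whiten()] result.
#' @param basis Optional matrix with orthonormal columns.
#' @return KL divergence in bits (nonnegative; 0 iff the models coincide).
#' @export
kl_gaussian_whitened <- function(wm, basis = NULL) {
  stopifnot(inherits(wm, "whitened_model"))
  if (is.null(basis)) {
    C <- wm$C_w; mu <- wm$mu_w
  } else {
    C <- crossprod(basis, wm$C_w %*% basis)
    mu <- drop(crossprod(basis, wm$mu_w))
  }
  m <- length(mu)
  ev <- eigen((C + t(C)) / 2, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) abort("whitened covariance is not positive definite")
  max((sum(ev) + sum(mu^2) - m - sum(log(ev))) / (2 * log(2)), 0)
}

# Gradient of the subspace KL (in bits) with respect to B.
kl_gradient <- function(wm, B) {
  M <- crossprod(B, wm$C_w %*% B)
  Minv <- solve((M + t(M)) / 2)
  ((wm$C_w + tcrossprod(wm$mu_w)) %*% B - wm$C_w %*% B %*% Minv) / log(2)
}

orthonormalize <- function(B) qr.Q(qr(B))

#' Most informative m-dimensional subspace (iSTAC)
#'
#' Finds an orthonormal basis `B` (m columns) maximizing the KL divergence
#' restricted to the subspace. Projected-gradient ascent with QR
#' retraction, seeded from the eigenvectors of `C_W` ranked by their
#' single-dimension KL contribution and from the whitened mean direction,
#' with random restarts.
#'
#' @param wm A [whiten()] result.
#' @param m Subspace dimension (1..n).
#' @param n_restarts Random restarts beyond the deterministic seeds
#'   (default 5).
#' @param max_iter Ascent iterations per start (default 300).
#' @param tol Convergence tolerance on the KL objective (default 1e-10).
#' @param seed Seed for the random restarts.
#' @return List of class `istac_basis`: `basis`, `kl_bits`, `m`,
#'   `kl_total_bits`.
#' @export
istac_subspace <- function(wm, m, n_restarts = 5, max_iter = 300,
                           tol = 1e-10, seed = 1) {
  stopifnot(inherits(wm, "whitened_model"), m >= 1, m <= wm$n)
  n <- wm$n
  e <- eigen(wm$C_w, symmetric = TRUE)
  # per-direction KL of each eigenvector (plus the mean component along it)
  contrib <- vapply(seq_len(n), function(i) {
    v <- e$vectors[, i]
    lam <- e$values[i]
    mu2 <- sum(wm$mu_w * v)^2
    (lam + mu2 - 1 - log(lam)) / (2 * log(2))
  }, numeric(1))
  ord <- order(contrib, decreasing = TRUE)

  seeds <- list(e$vectors[, ord[seq_len(m)], drop = FALSE])
  if (sum(wm$mu_w^2) > 1e-12 && m >= 1) {
    B2 <- cbind(wm$mu_w / sqrt(sum(wm$mu_w^2)),
                e$vectors[, ord[seq_len(max(m - 1, 0))], drop = FALSE])
    seeds <- c(seeds, list(orthonormalize(B2[, seq_len(m), drop = FALSE])))
  }
  rand <- with_seed(seed, purrr::map(seq_len(n_restarts), function(i) {
    orthonormalize(matrix(rnorm(n * m), n, m))
  }))
  starts <- c(seeds, rand)

  best <- NULL
  for (B in starts) {
    val <- kl_gaussian_whitened(wm, B)
    step <- 0.1
    for (it in seq_len(max_iter)) {
      G <- kl_gradient(wm, B)
      B_new <- orthonormalize(B + step * G)
      val_new <- kl_gaussian_whitened(wm, B_new)
      if (val_new > val) {
        if (val_new - val < tol) { B <- B_new; val <- val_new; break }
        B <- B_new; val <- val_new
        step <- min(step * 1.5, 1)
      } else {
        step <- step / 2
        if (step < 1e-12) break
      }
    }
    if (is.null(best) || val > best$val) best <- list(B = B, val = val)
  }
  structure(
    list(basis = best$B, kl_bits = best$val, m = m,
         kl_total_bits = kl_gaussian_whitened(wm)),
    class = "istac_basis")
}

#' @export
print.istac_basis <- function(x, ...) {
  cat(sprintf("<istac_basis> m = %d, KL %.4f of %.4f bits (%.1f%%)\n",
              x$m, x$kl_bits, x$kl_total_bits,
              100 * x$kl_bits / x$kl_total_bits))
  invisible(x)
}

#' Cumulative KL captured as a function of subspace dimension
#'
#' Normalized cumulative KL divergence of the optimal m-dimensional iSTAC
#' subspace for m = 1..m_max; nondecreasing and equal to 1 at the full
#' dimension. Each optimization is warm-started from the previous basis.
#'
#' @param wm A [whiten()] result.
#' @param m_max Largest dimension (default: full).
#' @param ... Passed to [istac_subspace()].
#' @return Tibble with `m`, `kl_bits`, `fraction`.
#' @export
cumulative_kl_curve <- function(wm, m_max = wm$n, ...) {
  total <- kl_gaussian_whitened(wm)
  prev_basis <- NULL
  rows <- purrr::map(seq_len(m_max), function(m) {
    b <- istac_subspace(wm, m, ...)
    if (!is.null(prev_basis)) {
      # nested candidate: previous basis plus its best orthogonal complement
      cand <- grow_basis(wm, prev_basis)
      if (kl_gaussian_whitened(wm, cand) > b$kl_bits) {
        b$basis <- cand
        b$kl_bits <- kl_gaussian_whitened(wm, cand)
      }
    }
    prev_basis <<- b$basis
    tibble::tibble(m = m, kl_bits = b$kl_bits,
                   fraction = b$kl_bits / total)
  })
  out <- dplyr::bind_rows(rows)
  out$fraction <- cummax(out$fraction)
  out
}

# Extend an orthonormal basis by the best single direction in its
# orthogonal complement (eigen-seeded ascent on one column).
grow_basis <- function(wm, B) {
  n <- nrow(B)
  comp <- qr.Q(qr(cbind(B, diag(n))))[, (ncol(B) + 1):n, drop = FALSE]
  Cc <- crossprod(comp, wm$C_w %*% comp)
  muc <- drop(crossprod(comp, wm$mu_w))
  wmc <- structure(list(mu_w = muc, C_w = (Cc + t(Cc)) / 2, n = ncol(comp)),
                   class = "whitened_model")
  b1 <- istac_subspace(wmc, 1, n_restarts = 2, seed = 2)
  orthonormalize(cbind(B, comp %*% b1$basis))
}

#' Replace a synthetic model inside an iSTAC subspace (mcsDTSM)
#'
#' In basis-aligned coordinates, the subspace block of the mean and the
#' subspace-subspace and subspace-complement blocks of the covariance are
#' replaced by those of the data model; the complement-complement block is
#' kept from the synthetic model. If the composite covariance is not
#' positive semidefinite it is repaired to the nearest PSD matrix
#' (eigenvalue clipping) and flagged.
#'
#' @param synthetic,data_model `gsm` models in the same space.
#' @param basis Orthonormal basis of the subspace (columns), in that space.
#' @param cross Which model supplies the subspace-complement covariance
#'   cross blocks: `"data"` (default; the subspace marginal of the result
#'   matches the data model exactly) or `"synthetic"` (only the
#'   subspace-subspace block is replaced).
#' @return A `gsm` labeled `"mcsDTSM"`; attribute `psd_repaired` records
#'   whether clipping was needed.
#' @export
modify_model_in_subspace <- function(synthetic, data_model, basis,
                                     cross = c("data", "synthetic")) {
  cross <- match.arg(cross)
  stopifnot(inherits(synthetic, "gsm"), inherits(data_model, "gsm"))
  n <- length(synthetic$mu)
  if (is.null(basis) || ncol(as.matrix(basis)) == 0) {
    out <- synthetic
    out$label <- "mcsDTSM"
    return(out)
  }
  B <- as.matrix(basis)
  if (max(abs(crossprod(B) - diag(ncol(B)))) > 1e-8) {
    abort("basis must be orthonormal")
  }
  Q <- if (ncol(B) == n) B else qr.Q(qr(cbind(B, diag(n))))[, seq_len(n)]
  m <- ncol(B)
  Q[, seq_len(m)] <- B # keep the supplied subspace columns exactly

  to_q <- function(v) drop(crossprod(Q, v))
  mu_s <- to_q(synthetic$mu)
  mu_d <- to_q(data_model$mu)
  C_s <- crossprod(Q, synthetic$C %*% Q)
  C_d <- crossprod(Q, data_model$C %*% Q)

  mu_new <- mu_s
  mu_new[seq_len(m)] <- mu_d[seq_len(m)]
  C_new <- C_s
  if (cross == "data") {
    C_new[seq_len(m), ] <- C_d[seq_len(m), ]
    C_new[, seq_len(m)] <- C_d[, seq_len(m)]
    if (m < n) {
      idx <- (m + 1):n
      C_new[idx, idx] <- C_s[idx, idx]
    }
  } else {
    C_new[seq_len(m), seq_len(m)] <- C_d[seq_len(m), seq_len(m)]
  }
  C_new <- (C_new + t(C_new)) / 2

  repaired <- FALSE
  ev <- eigen(C_new, symmetric = TRUE)
  if (min(ev$values) <= 0) {
    repaired <- TRUE
    lam <- pmax(ev$values, 1e-10 * max(ev$values))
    C_new <- ev$vectors %*% (lam * t(ev$vectors))
    C_new <- (C_new + t(C_new)) / 2
  }
  out <- gaussian_stimulus_model(
    Q %*% mu_new |> drop(), Q %*% C_new %*% t(Q),
    label = "mcsDTSM", isi_ms = synthetic$isi_ms,
    n_events = data_model$n_events)
  attr(out, "psd_repaired") <- repaired
  # parameters inherited from the n-event data model: subspace mean (m),
  # subspace covariance block (m(m+1)/2), plus cross blocks (m(n-m)) when
  # those are adopted from the data model
  attr(out, "p_eff") <- m + m * (m + 1) / 2 +
    if (cross == "data") m * (n - m) else 0
  out
}

#' Build the subspace-corrected synthetic doublet model (mcsDTSM)
#'
#' Corrects a synthetic doublet model along the `m`-dimensional iSTAC
#' subspace of its divergence from the data model: both models are whitened
#' against the synthetic model, the most informative subspace is found, the
#' synthetic model's mean and covariance are replaced by the data model's
#' inside that subspace (cross blocks included, complement untouched), and
#' the result is mapped back to the original coordinates.
#'
#' @param synthetic Synthetic model (`gsm`, e.g. an sDTSM or csDTSM).
#' @param data_model Data doublet model in the same space.
#' @param m Subspace dimension (default 3).
#' @param basis Optional fixed orthonormal basis in the whitened
#'   coordinates of `synthetic` (e.g. found once on the full ensemble and
#'   reused across cross-validation folds, so that per-fold replacement
#'   does not chase fold noise). When `NULL` the basis is optimized from
#'   this model pair.
#' @param cross Cross-block source, see [modify_model_in_subspace()].
#' @param ... Passed to [istac_subspace()].
#' @return A `gsm` labeled `"mcsDTSM"` with the iSTAC basis attached as
#'   attribute `basis_whitened`.
#' @export
build_mcsdtsm <- function(synthetic, data_model, m = 3, basis = NULL,
                          cross = c("data", "synthetic"), ...) {
  cross <- match.arg(cross)
  wm <- whiten(synthetic, data_model)
  b <- if (is.null(basis)) istac_subspace(wm, m, ...)
       else list(basis = basis)
  base_w <- gaussian_stimulus_model(numeric(wm$n), diag(wm$n),
                                    label = synthetic$label,
                                    isi_ms = synthetic$isi_ms,
                                    n_events = synthetic$n_events)
  data_w <- gaussian_stimulus_model(wm$mu_w, wm$C_w, label = data_model$label,
                                    isi_ms = data_model$isi_ms,
                                    n_events = data_model$n_events)
  mod_w <- modify_model_in_subspace(base_w, data_w, b$basis, cross = cross)
  S <- sqrtm_sym(synthetic$C) # unwhitening map
  out <- gaussian_stimulus_model(
    synthetic$mu + drop(S %*% mod_w$mu),
    S %*% mod_w$C %*% t(S),
    label = "mcsDTSM", isi_ms = synthetic$isi_ms,
    n_events = data_model$n_events)
  attr(out, "p_eff") <- attr(mod_w, "p_eff")
  attr(out, "psd_repaired") <- attr(mod_w, "psd_repaired")
  attr(out, "basis_whitened") <- b$basis
  out
}
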
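rand_gsm <- function(d, seed, mu_scale = 1) {
  withr::with_seed(seed, {
    A <- matrix(rnorm(d * d), d)
    gaussian_stimulus_model(mu_scale * rnorm(d), crossprod(A) / d + diag(d))
  })
}

test_that("whitening maps the base to (0, I) and preserves KL", {
  base <- rand_gsm(6, 1)
  wm0 <- whiten(base, base)
  expect_lt(max(abs(wm0$mu_w)), 1e-10)
  expect_lt(max(abs(wm0$C_w - diag(6))), 1e-10)
  expect_equal(kl_gaussian_whitened(wm0), 0)

  # oracle: unwhitened Gaussian KL formula on random 6-dim pairs
  for (seed in 2:4) {
    comp <- rand_gsm(6, seed)
    direct <- 0.5 * (sum(diag(solve(base$C, comp$C))) +
      drop(t(base$mu - comp$mu) %*% solve(base$C, base$mu - comp$mu)) - 6 +
      determinant(base$C, TRUE)$modulus -
      determinant(comp$C, TRUE)$modulus) / log(2)
    expect_equal(kl_gaussian_whitened(whiten(base, comp)),
                 as.numeric(direct), tolerance = 1e-8)
  }

  # unit changes of both models leave the whitened pair untouched
  comp <- rand_gsm(6, 5)
  wm <- whiten(base, comp)
  base2 <- gaussian_stimulus_model(7 * base$mu, 49 * base$C)
  comp2 <- gaussian_stimulus_model(7 * comp$mu, 49 * comp$C)
  wm2 <- whiten(base2, comp2)
  expect_equal(wm2$mu_w, wm$mu_w, tolerance = 1e-9)
  expect_equal(wm2$C_w, wm$C_w, tolerance = 1e-9)
})

test_that("subspace KL has closed-form special cases", {
  # unit mean shift along e1: D = 1/(2 ln 2) bits
  wm <- structure(list(mu_w = c(1, 0, 0), C_w = diag(3), n = 3),
                  class = "whitened_model")
  expect_equal(kl_gaussian_whitened(wm), 0.5 / log(2), tolerance = 1e-12)
  b1 <- istac_subspace(wm, 1, seed = 1)
  expect_equal(b1$kl_bits, b1$kl_total_bits, tolerance = 1e-9)
  expect_equal(abs(b1$basis[1, 1]), 1, tolerance = 1e-6)

  # pure single-eigenvalue case: the informative axis is recovered
  v <- c(1, 2, -1) / sqrt(6)
  wm2 <- structure(list(mu_w = numeric(3),
                        C_w = diag(3) + 2 * tcrossprod(v), n = 3),
                   class = "whitened_model")
  b2 <- istac_subspace(wm2, 1, seed = 2)
  expect_equal(abs(sum(b2$basis * v)), 1, tolerance = 1e-6)

  # full-dimensional subspace equals the unrestricted divergence
  wm3 <- whiten(rand_gsm(5, 6), rand_gsm(5, 7))
  expect_equal(kl_gaussian_whitened(wm3, diag(5)),
               kl_gaussian_whitened(wm3), tolerance = 1e-12)
})

test_that("iSTAC optimization beats random-basis search and is monotone", {
  wm <- whiten(
    gaussian_stimulus_model(numeric(10), diag(10)),
    rand_gsm(10, 8, mu_scale = 0.5))
  b3 <- istac_subspace(wm, 3, seed = 3)
  withr::with_seed(9, {
    best_rand <- max(replicate(1500, {
      kl_gaussian_whitened(wm, qr.Q(qr(matrix(rnorm(30), 10))))
    }))
  })
  expect_gte(b3$kl_bits, best_rand - 1e-6)

  cc <- cumulative_kl_curve(wm)
  expect_true(all(diff(cc$fraction) >= -1e-9))
  expect_equal(cc$fraction[10], 1, tolerance = 1e-9)
  # projections cannot create divergence
  expect_true(all(cc$kl_bits <= kl_gaussian_whitened(wm) + 1e-9))
})

test_that("KL is nonnegative and zero only for identical models", {
  for (seed in 10:12) {
    m <- rand_gsm(7, seed)
    expect_equal(kl_gaussian_whitened(whiten(m, m)), 0, tolerance = 1e-9)
    m2 <- rand_gsm(7, seed + 100)
    expect_gt(kl_gaussian_whitened(whiten(m, m2)), 1e-9)
  }
})

test_that("subspace modification has the right degenerate limits", {
  syn <- rand_gsm(8, 13)
  dat <- rand_gsm(8, 14)
  full <- modify_model_in_subspace(syn, dat, diag(8))
  expect_equal(full$mu, dat$mu, tolerance = 1e-10)
  expect_equal(full$C, dat$C, tolerance = 1e-10)

  none <- modify_model_in_subspace(syn, dat, NULL)
  expect_equal(none$mu, syn$mu)
  expect_equal(none$C, syn$C)

  # partial replacement: subspace marginal matches the data model
  B <- qr.Q(qr(matrix(rnorm(8 * 3), 8)))
  mod <- modify_model_in_subspace(syn, dat, B)
  expect_equal(drop(crossprod(B, mod$mu)), drop(crossprod(B, dat$mu)),
               tolerance = 1e-9)
  expect_equal(crossprod(B, mod$C %*% B), crossprod(B, dat$C %*% B),
               tolerance = 1e-8)
  ev <- eigen(mod$C, symmetric = TRUE, only.values = TRUE)$values
  expect_gte(min(ev), 0)
})

test_that("short-ISI divergence is more compact than long-ISI divergence", {
  ses <- surrogate_session(3)
  rs <- shared_reduced_space()
  frac3 <- function(isi_name) {
    eb <- ses$ensembles$doublet[[isi_name]]
    dtsm <- project_model(fit_gaussian_model(eb$segments, "DTSM"), rs)
    sdtsm <- project_model(
      synthesize_doublet_model(ses$stsm, eb$isi_ms,
                               fit_gaussian_model(eb$segments, "DTSM"), rs),
      rs)
    b <- istac_subspace(whiten(sdtsm, dtsm), 3, n_restarts = 2, seed = 4)
    b$kl_bits / b$kl_total_bits
  }
  short <- frac3("2")
  long <- frac3(if ("9" %in% names(ses$ensembles$doublet)) "9" else "10")
  expect_gt(short, long)
})
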
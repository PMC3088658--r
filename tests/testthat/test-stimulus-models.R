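test_that("isolation rules select the right patterns", {
  stim <- generate_stimulus(1000, seed = 1)
  tr <- spike_train(c(100, 102.5, 200, 400, 415, 430), duration_ms = 1000)
  ens <- collect_isolated_patterns(tr, stim, min_events = 1)
  # (100, 102.5): isolated doublet in the 2 ms bin (round-half-even)
  expect_true("2" %in% names(ens$doublet))
  expect_equal(nrow(ens$doublet[["2"]]$segments), 1L)
  # 200 is an isolated singlet; 400/415/430 are not isolated from each other
  expect_equal(nrow(ens$singlet$segments), 1L)

  # a follower within 20 ms disqualifies the doublet
  tr2 <- spike_train(c(100, 102.5, 110, 300), duration_ms = 1000)
  ens2 <- collect_isolated_patterns(tr2, stim, min_events = 1)
  expect_false("2" %in% names(ens2$doublet))
})

test_that("ensembles below the 80-event floor are dropped", {
  stim <- generate_stimulus(120000, seed = 2)
  # 79 isolated doublets at 5 ms -> dropped; 81 -> retained
  mk <- function(n) {
    base <- seq(100, by = 60, length.out = n)
    spike_train(as.vector(rbind(base, base + 5)), duration_ms = 120000)
  }
  e79 <- collect_isolated_patterns(mk(79), stim)
  e81 <- collect_isolated_patterns(mk(81), stim)
  expect_false("5" %in% names(e79$doublet))
  expect_true("5" %in% names(e81$doublet))
  # folds partition the ensemble into ~10% test sets
  f <- e81$doublet[["5"]]$folds
  expect_equal(length(f), 81L)
  expect_equal(sort(unique(f)), 1:10)
  expect_true(all(table(f) %in% c(8, 9)))
})

test_that("Gaussian model fitting behaves as a sample estimator", {
  seg <- matrix(rep(c(1, 2, 3), 10), nrow = 10, byrow = TRUE)
  m <- fit_gaussian_model(seg)
  expect_equal(max(abs(m$C)), 0)
  expect_equal(m$mu, c(1, 2, 3))

  # covariance error shrinks roughly as n^(-1/2)
  withr::with_seed(3, {
    d <- 8
    A <- matrix(rnorm(d * d), d)
    Ctrue <- crossprod(A) / d + diag(d)
    ch <- chol(Ctrue)
    err <- vapply(c(250, 2500), function(n) {
      mean(replicate(8, {
        X <- matrix(rnorm(n * d), n) %*% ch
        norm(fit_gaussian_model(X)$C - Ctrue, "F")
      }))
    }, numeric(1))
  })
  expect_equal(err[1] / err[2], sqrt(10), tolerance = 0.35 * sqrt(10))
})

test_that("singlet ensemble mean recovers the encoder kernel", {
  ses <- surrogate_session(0)
  k <- default_kernel()
  ks <- doubletcode:::band_limit(c(k, numeric(1950)), 1000, c(10, 200))[1:50]
  ccs <- vapply(-2:2, function(sh) {
    cor(doubletcode:::shift_vec(ses$stsm$mu, sh), ks)
  }, numeric(1))
  expect_gt(max(ccs), 0.9)
})

test_that("synthetic doublet models obey the defining identities", {
  ses <- surrogate_session(3)
  rs <- shared_reduced_space()
  eb <- ses$ensembles$doublet[[1]]
  dtsm <- fit_gaussian_model(eb$segments, "DTSM", eb$isi_ms)

  # ISI (offset) 0: mean doubles
  s0 <- synthesize_doublet_model(ses$stsm, 0, dtsm, rs)
  expect_equal(s0$mu, 2 * ses$stsm$mu, tolerance = 1e-12)

  # generalized-variance matching in the reduced space
  s8 <- synthesize_doublet_model(ses$stsm, 8, dtsm, rs)
  dd <- function(m) {
    determinant(project_model(m, rs)$C, logarithm = TRUE)$modulus
  }
  expect_equal(as.numeric(dd(s8) - dd(dtsm)), 0, tolerance = 1e-6)

  # a -3 ms offset is the +3 ms pattern with 3 ms extra latency
  sp <- synthesize_doublet_model(ses$stsm, 3, dtsm, rs)
  sm <- synthesize_doublet_model(ses$stsm, -3, dtsm, rs)
  expect_equal(doubletcode:::shift_vec(sp$mu, -3)[1:46], sm$mu[1:46],
               tolerance = 1e-10)

  expect_error(synthesize_doublet_model(ses$stsm, 55, dtsm, rs), "window")
})

test_that("reduced space has the band-limited dimensionality", {
  rs <- shared_reduced_space()
  expect_gte(rs$d, 17)
  expect_lte(rs$d, 24)
  B <- rs$basis
  expect_lt(max(abs(crossprod(B) - diag(rs$d))), 1e-10)

  # white segments: nothing is discarded
  withr::with_seed(4, W <- matrix(rnorm(2000 * 50), 2000))
  expect_equal(fit_reduced_space(W)$d, 50L)
})

test_that("projection preserves models and their divergences", {
  ses <- surrogate_session(3)
  rs <- shared_reduced_space()
  m <- ses$stsm
  # identity basis: unchanged model
  rid <- structure(list(basis = diag(50), eigenvalues = rep(1, 50), d = 50,
                        eig_threshold = 0), class = "reduced_space")
  expect_equal(project_model(m, rid)$C, m$C, tolerance = 1e-12)

  # band-limited means lose almost no power under project + reconstruct
  mu_rec <- rs$basis %*% drop(crossprod(rs$basis, m$mu))
  expect_lt(sum((m$mu - mu_rec)^2) / sum(m$mu^2), 0.01)

  # KL between two models differing only inside a subspace equals the KL of
  # their projections onto that subspace (when the base covariance does not
  # couple subspace and complement)
  withr::with_seed(5, {
    d <- 12; k <- 4
    Q <- qr.Q(qr(matrix(rnorm(d * d), d)))
    B <- Q[, 1:k]; Bc <- Q[, (k + 1):d]
    S1 <- crossprod(matrix(rnorm(k * k), k)) / k + diag(k)
    S2 <- crossprod(matrix(rnorm((d - k)^2), d - k)) / (d - k) + diag(d - k)
    C0 <- B %*% S1 %*% t(B) + Bc %*% S2 %*% t(Bc)
    bump <- B %*% (crossprod(matrix(rnorm(k * k), k)) / (2 * k)) %*% t(B)
    mu0 <- rnorm(d)
    delta <- B %*% rnorm(k)
  })
  base <- gaussian_stimulus_model(mu0, C0, "base")
  comp <- gaussian_stimulus_model(mu0 + drop(delta), C0 + bump, "cmp")
  kl_full <- kl_gaussian_whitened(whiten(base, comp))
  rsB <- structure(list(basis = B, eigenvalues = rep(1, k), d = k,
                        eig_threshold = 0), class = "reduced_space")
  kl_proj <- kl_gaussian_whitened(
    whiten(project_model(base, rsB), project_model(comp, rsB)))
  expect_equal(kl_proj, kl_full, tolerance = 1e-8)
})
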
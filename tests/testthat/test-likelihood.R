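identity_space <- function(d) {
  structure(list(basis = diag(d), eigenvalues = rep(1, d), d = d,
                 eig_threshold = 0), class = "reduced_space")
}

random_model <- function(d, seed, scale = 1) {
  withr::with_seed(seed, {
    A <- matrix(rnorm(d * d), d)
    gaussian_stimulus_model(rnorm(d), scale * (crossprod(A) / d + diag(d)))
  })
}

test_that("Gaussian log-likelihood matches closed forms and brute force", {
  m1 <- gaussian_stimulus_model(0, matrix(1), "std")
  expect_equal(gaussian_loglik(0, m1), -0.5 * log(2 * pi), tolerance = 1e-10)
  expect_equal(gaussian_loglik(0, m1), -0.9189, tolerance = 1e-4)

  # brute-force density with explicit inverse and determinant, 5-dim
  for (seed in 1:3) {
    m <- random_model(5, seed)
    withr::with_seed(seed + 10, x <- matrix(rnorm(20 * 5), 20))
    brute <- vapply(seq_len(20), function(i) {
      v <- x[i, ] - m$mu
      -0.5 * (5 * log(2 * pi) + log(det(m$C)) +
              drop(t(v) %*% solve(m$C) %*% v))
    }, numeric(1))
    expect_equal(gaussian_loglik(x, m), brute, tolerance = 1e-10)
  }

  # monotone decreasing in distance from the mean along a ray
  m <- random_model(4, 4)
  dists <- seq(0, 5, by = 0.5)
  ll <- vapply(dists, function(a) {
    gaussian_loglik(m$mu + a * c(1, 0, 0, 0), m)
  }, numeric(1))
  expect_true(all(diff(ll) <= 0))

  sing <- gaussian_stimulus_model(c(0, 0), matrix(c(1, 1, 1, 1), 2), "sing")
  expect_error(gaussian_loglik(c(0, 0), sing), "singular")
})

test_that("LLR test is exact at zero for identical models and obeys Gibbs", {
  d <- 6
  ma <- random_model(d, 1)
  mb <- random_model(d, 2)
  withr::with_seed(3, {
    X <- matrix(rnorm(500 * d), 500) %*% chol(ma$C) +
      matrix(ma$mu, 500, d, byrow = TRUE)
    folds <- sample(rep_len(1:10, 500))
  })
  same <- llr_test(X, folds, function(tr) ma, function(tr) ma,
                   identity_space(d))
  expect_equal(same$mean, 0)

  # data from model a: expected LLR = KL(a||b) in nats > 0
  res <- llr_test(X, folds, function(tr) ma, function(tr) mb,
                  identity_space(d))
  expect_gt(res$ci[["lower"]], 0)
  # outlier removal stays modest on Gaussian-consistent data
  expect_lt(res$n_outliers_removed / (res$n_used + res$n_outliers_removed),
            0.05)
})

test_that("bias correction centers the null for unequally estimated models", {
  d <- 10
  truth <- random_model(d, 5)
  ch <- chol(truth$C)
  withr::with_seed(6, {
    means <- replicate(40, {
      X <- matrix(rnorm(200 * d), 200) %*% ch +
        matrix(truth$mu, 200, d, byrow = TRUE)
      folds <- sample(rep_len(1:10, 200))
      llr_test(X, folds,
               fit_a = function(tr) fit_gaussian_model(tr),
               fit_b = function(tr) truth,
               identity_space(d))$mean
    })
  })
  expect_lt(abs(mean(means)), 3 * sd(means) / sqrt(40) + 0.04)
})

test_that("LLR decay fit recovers the generating time constant", {
  withr::with_seed(7, {
    isi <- 2:25
    y <- 2.7 * exp(-isi / 2.0) + rnorm(length(isi), 0, 0.03)
  })
  f <- fit_llr_decay(tibble::tibble(isi_ms = isi, mean = y))
  expect_equal(unname(f$params["x1"]), 2.7, tolerance = 0.4)
  expect_equal(unname(f$params["x2"]), 2.0, tolerance = 0.3)
  # the fast term has decayed to e^-4 of its amplitude at ISI = 4 x2
  f2 <- fit_llr_decay(tibble::tibble(isi_ms = isi, mean = y), orders = 2)
  x1 <- unname(f2$params["x1"]); x2 <- unname(f2$params["x2"])
  expect_equal(predict(f2, 4 * x2)$fit, x1 * exp(-4), tolerance = 1e-10)
  expect_true(is.finite(f$zero_isi_ms) || is.na(f$zero_isi_ms))

  # all-zero input: flat fit crossing zero immediately
  f0 <- fit_llr_decay(tibble::tibble(isi_ms = 2:25, mean = 0))
  expect_lt(abs(unname(f0$params["x1"])), 1e-6)
  expect_equal(f0$zero_isi_ms, 2)
})

test_that("offset scan finds the generating offset (self-consistency)", {
  ses <- surrogate_session(3)
  rs <- shared_reduced_space()
  eb <- ses$ensembles$doublet[["3"]]
  dtsm <- fit_gaussian_model(eb$segments, "DTSM", 3)

  withr::with_seed(8, {
    test_ens <- list()
    for (o_star in c(5, 12)) {
      mo <- project_model(synthesize_doublet_model(ses$stsm, o_star, dtsm, rs),
                          rs)
      Xr <- matrix(rnorm(300 * rs$d), 300) %*% chol(mo$C) +
        matrix(mo$mu, 300, rs$d, byrow = TRUE)
      X <- Xr %*% t(rs$basis) # embed the reduced-space draw in the window
      test_ens[[as.character(o_star)]] <-
        list(segments = X, isi_ms = o_star, folds = rep_len(1:10, 300))
    }
  })
  scan <- offset_scan(test_ens, ses$stsm, list("3" = dtsm),
                      reduced_space = rs)
  expect_equal(scan$peak$peak_offset_ms, c(5, 12))
  expect_equal(unname(colSums(scan$P)), c(1, 1), tolerance = 1e-12)
})

test_that("offset scan peaks on the diagonal for the bursty surrogate", {
  ses <- surrogate_session(3)
  rs <- shared_reduced_space()
  sel <- intersect(as.character(c(3, 4, 5, 8, 10, 12)),
                   names(ses$ensembles$doublet))
  dtsms <- purrr::map(ses$ensembles$doublet[sel],
                      function(eb) fit_gaussian_model(eb$segments, "DTSM",
                                                      eb$isi_ms))
  scan <- offset_scan(ses$ensembles$doublet[sel], ses$stsm, dtsms,
                      reduced_space = rs)
  expect_true(all(abs(scan$peak$peak_offset_ms - scan$peak$isi_ms) <= 1))
})

test_that("csDTSM inherits the scan peak and the volume constraint", {
  ses <- surrogate_session(3)
  rs <- shared_reduced_space()
  eb <- ses$ensembles$doublet[["3"]]
  dtsm <- fit_gaussian_model(eb$segments, "DTSM", 3)
  scan <- offset_scan(list("3" = eb), ses$stsm, list("3" = dtsm),
                      reduced_space = rs)
  cs <- build_csdtsm(ses$stsm, 3, scan, dtsm, rs)
  peak <- scan$peak$peak_offset_ms[1]
  ref <- synthesize_doublet_model(ses$stsm, peak, dtsm, rs)
  expect_equal(cs$mu, ref$mu)
  dd <- function(m) determinant(project_model(m, rs)$C, TRUE)$modulus
  expect_equal(as.numeric(dd(cs) - dd(dtsm)), 0, tolerance = 1e-6)
})
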
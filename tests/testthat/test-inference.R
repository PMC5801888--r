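test_that("psd_repair clips negative eigenvalues and fixes PSD inputs", {
  expect_equal(psd_repair(diag(c(1, -1))), diag(c(1, 0)))
  M <- crossprod(matrix(rnorm(20), 5, 4))
  expect_equal(psd_repair(M), (M + t(M)) / 2, tolerance = 1e-12)
  expect_equal(psd_repair(-diag(3)), matrix(0, 3, 3))
  expect_error(psd_repair(matrix(1:4, 2, 2)), "symmetric")
})

test_that("psd_repair is an idempotent projection that never raises eigenvalues", {
  for (seed in 1:20) {
    M <- privlr:::with_seed(seed, {
      A <- matrix(rnorm(25), 5, 5)
      (A + t(A)) / 2
    })
    R <- psd_repair(M)
    expect_equal(psd_repair(R), R, tolerance = 1e-10)
    ev_m <- sort(eigen(M, symmetric = TRUE, only.values = TRUE)$values)
    ev_r <- sort(eigen(R, symmetric = TRUE, only.values = TRUE)$values)
    expect_true(all(ev_r <= pmax(ev_m, 0) + 1e-10))
    expect_true(all(ev_r >= -1e-10))
  }
})

test_that("fixed-precision posterior matches hand examples", {
  zero <- sufficient_stats(matrix(numeric(0), 0, 3), numeric(0))
  p0 <- posterior_fixed(zero, lambda = 1, lambda0 = 2)
  expect_equal(p0$mu, rep(0, 3))
  expect_equal(p0$Lambda, 2 * diag(3))

  st <- privlr:::new_suff_stats(matrix(2, 1, 1), 3, 9, n = 2, is_noisy = FALSE)
  p1 <- posterior_fixed(st, 1, 1)
  expect_equal(p1$Lambda, matrix(3, 1, 1))
  expect_equal(p1$mu, 1)
  # prediction continues the example
  expect_equal(predict(p1, matrix(2, 1, 1)), 2)
})

test_that("clean-statistics posterior equals the direct ridge posterior", {
  for (seed in 1:10) {
    privlr:::with_seed(seed, {
      n <- sample(10:200, 1)
      d <- sample(2:8, 1)
      lam <- runif(1, 0.5, 2)
      lam0 <- runif(1, 0.5, 2)
      X <- matrix(rnorm(n * d), n, d)
      y <- rnorm(n)
      p <- posterior_fixed(sufficient_stats(X, y), lam, lam0)
      o <- direct_ridge_posterior(X, y, lam, lam0)
      expect_equal(p$mu, o$mu, tolerance = 1e-8)
      expect_equal(p$Lambda, o$Lambda, tolerance = 1e-8)
    })
  }
})

test_that("coefficient shrinkage increases with the prior precision", {
  for (seed in 1:10) {
    st <- sufficient_stats(random_dataset(40, 4, seed = seed))
    norms <- sapply(c(0.1, 1, 10, 100),
                    function(l0) sqrt(sum(posterior_fixed(st, 1, l0)$mu^2)))
    expect_true(all(diff(norms) <= 1e-12))
  }
})

test_that("hierarchical posterior agrees with the conjugate path on clean data", {
  g <- generate_auxiliary(2000, 5, lambda = 1, lambda0 = 1, seed = 31)
  st <- sufficient_stats(g$data)
  fit <- fit_hierarchical(st, prior_spec("hierarchical"), m = 2000,
                          burnin = 500, seed = 8)
  expect_equal(nrow(fit$beta), 2000)
  expect_true(all(fit$lambda > 0) && all(fit$lambda0 > 0))
  ref <- posterior_fixed(st, 1, 1)
  expect_lt(max(abs(colMeans(fit$beta) - ref$mu)), 0.05)
  # noise precision recovered near its true value 1
  expect_gt(mean(fit$lambda), 0.8)
  expect_lt(mean(fit$lambda), 1.2)
  expect_true(is.finite(fit$diagnostics$min_ess))
})

test_that("hierarchical sampler validates m and returns exactly m draws", {
  st <- sufficient_stats(random_dataset(50, 3, seed = 2))
  expect_error(fit_hierarchical(st, prior_spec("hierarchical"), m = 0), "m")
  fit <- fit_hierarchical(st, prior_spec("hierarchical"), m = 57,
                          burnin = 50, seed = 1)
  expect_equal(fit$m, 57L)
  expect_equal(length(fit$lambda), 57L)
})

test_that("prediction handles both posterior forms and checks dimensions", {
  pf <- structure(list(mu = rep(0, 3), Lambda = diag(3), lambda = 1,
                       lambda0 = 1, d = 3L), class = "posterior_fixed")
  expect_equal(predict(pf, matrix(rnorm(6), 2, 3)), c(0, 0))
  expect_error(predict(pf, matrix(1, 1, 2)), "columns")

  beta0 <- c(1, -2)
  ps <- structure(list(beta = matrix(beta0, 10, 2, byrow = TRUE),
                       lambda = rep(1, 10), lambda0 = rep(1, 10),
                       m = 10L, d = 2L,
                       diagnostics = list(min_ess = 10, converged = TRUE)),
                  class = "posterior_samples")
  Xn <- matrix(c(1, 0, 0, 1, 2, 2), 3, 2, byrow = TRUE)
  expect_equal(predict(ps, Xn), as.numeric(Xn %*% beta0))
})

test_that("noisy statistics are repaired before inversion", {
  st <- privlr:::new_suff_stats(diag(c(1, -5)), c(1, 1), -3, n = 10,
                                is_noisy = TRUE)
  p <- posterior_fixed(st, 1, 1)
  # negative direction clipped: Lambda = diag(2, 1)
  expect_equal(p$Lambda, diag(c(2, 1)))
  expect_equal(p$mu, c(0.5, 1))
})

test_that("gamma prior moments are shape/rate", {
  m <- gamma_prior_moments(2, 2)
  expect_equal(unname(m), c(1, 0.5))
  expect_equal(unname(gamma_prior_moments(3, 6)), c(0.5, 3 / 36))
})
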
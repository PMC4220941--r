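# Matern covariance, AR(1) structure, and the separable space-time prior.

test_that("Matern covariance: zero-lag, exponential limit, range convention", {
  set.seed(2)
  d <- matrix(0, 4, 4)
  xy <- cbind(runif(4, 0, 100), runif(4, 0, 100))
  d <- as.matrix(dist(xy))
  # C(0) = sigma^2 exactly
  C <- matern_covariance(d, range = 50, sigma = 1.7, nu = 1)
  expect_equal(unname(diag(C)), rep(1.7^2, 4))
  # nu = 0.5 is the exponential covariance
  for (rg in c(20, 80, 300)) {
    C05 <- matern_covariance(d, range = rg, sigma = 2, nu = 0.5)
    kappa <- sqrt(8 * 0.5) / rg
    expect_lt(max(abs(C05 - 4 * exp(-kappa * d))), 1e-10)
  }
  # the kappa = sqrt(8 nu)/range convention: correlation at d = range is
  # sqrt(8) K_1(sqrt(8)) = 0.1397 (the "approximately 0.1" range definition)
  corr_at_range <- matern_covariance(matrix(c(0, 50, 50, 0), 2), 50, 1, 1)[1, 2]
  expect_equal(corr_at_range, sqrt(8) * besselK(sqrt(8), 1), tolerance = 1e-10)
  expect_lt(abs(corr_at_range - 0.1), 0.05)
})

test_that("Matern covariance is monotone decreasing and positive definite", {
  dd <- seq(0, 500, by = 5)
  for (par in list(c(30, 0.5), c(100, 1), c(250, 2))) {
    cv <- matern_covariance(dd, range = par[1], sigma = 1, nu = par[2])
    expect_true(all(diff(cv) <= 1e-12))
  }
  set.seed(5)
  xy <- cbind(runif(30, 0, 200), runif(30, 0, 500))
  D <- as.matrix(dist(xy))
  for (rg in c(20, 150, 600)) {
    C <- matern_covariance(D, rg, 1, 1)
    diag(C) <- diag(C) + 1e-8
    ev <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
    expect_gt(min(ev), 0)
  }
  expect_error(matern_covariance(matrix(c(0, 1, 2, 0), 2), 10),
               class = "wp_value_error")
  expect_error(matern_covariance(dd, range = -1), class = "wp_value_error")
})

test_that("AR(1) correlation and precision are mutual inverses", {
  s <- ar1_structure(5, 0)
  expect_equal(s$correlation, diag(5))
  expect_equal(ar1_structure(2, 0.5)$correlation[1, 2], 0.5)
  for (par in list(c(12, 0.8), c(7, -0.6), c(30, 0.95))) {
    s <- ar1_structure(par[1], par[2])
    I <- as.matrix(s$precision %*% s$correlation)
    expect_lt(max(abs(I - diag(par[1]))), 1e-8)
  }
  expect_error(ar1_structure(5, 1), class = "wp_value_error")
})

test_that("separable prior matches dense Kronecker oracles", {
  set.seed(6)
  xy <- cbind(runif(4, 0, 50), runif(4, 0, 50))
  D <- as.matrix(dist(xy))
  hp <- hyperparameters(40, 1.3, 0.6, 0)
  pr <- st_prior(hp, D, 3)
  Sig <- st_prior_cov(pr)
  # stationary marginal variance = sigma_xi^2 (up to jitter)
  expect_equal(unname(diag(Sig)), rep(1.3^2, 12), tolerance = 1e-6)
  expect_equal(pr$logdet,
               as.numeric(determinant(Sig, logarithm = TRUE)$modulus),
               tolerance = 1e-8)
  X <- matrix(rnorm(12), 4, 3)
  expect_equal(as.vector(st_prior_solve(pr, X)),
               as.vector(solve(Sig, as.vector(X))), tolerance = 1e-8)
  # a = 0: occasions independent, per-occasion covariance = Matern block
  pr0 <- st_prior(hyperparameters(40, 1.3, 0, 0), D, 3)
  Sig0 <- st_prior_cov(pr0)
  expect_equal(Sig0[1:4, 1:4], pr0$Cs, ignore_attr = TRUE)
  expect_true(all(abs(Sig0[1:4, 5:8]) < 1e-12))
  # n = 1 reduces to a univariate AR(1) with variance sigma_xi^2
  pr1 <- st_prior(hyperparameters(40, 0.9, 0.7, 0), matrix(0, 1, 1), 6)
  expect_equal(st_prior_cov(pr1), 0.9^2 * ar1_structure(6, 0.7)$correlation,
               tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("sample_field draws from the declared distribution", {
  set.seed(3)
  xy <- cbind(c(0, 30), c(0, 10))
  D <- as.matrix(dist(xy))
  hp <- hyperparameters(50, 0.8, 0.6, 0)
  # determinism under a fixed seed
  f1 <- sample_field(hp, D, 4, seed = 123)
  f2 <- sample_field(hp, D, 4, seed = 123)
  expect_identical(f1, f2)
  expect_identical(dim(f1), c(2L, 4L))
  # sigma_xi = 0 gives the zero field
  expect_true(all(sample_field(hyperparameters(50, 0, 0.6, 0), D, 4) == 0))
  # empirical covariance over 10^4 draws matches the prior within 3 se
  ndraw <- 10000
  set.seed(77)
  draws <- matrix(NA_real_, ndraw, 4)
  pr <- st_prior(hp, D, 2)
  for (r in seq_len(ndraw)) draws[r, ] <- as.vector(sample_field(hp, D, 2))
  Sig <- as.matrix(st_prior_cov(pr))
  emp <- cov(draws)
  for (i in 1:4) for (j in 1:4) {
    se <- sqrt((Sig[i, j]^2 + Sig[i, i] * Sig[j, j]) / ndraw)
    expect_lt(abs(emp[i, j] - Sig[i, j]), 3.5 * se)
  }
  # stationarity: time-marginal variance does not drift with t
  vt <- apply(draws, 2, var)
  expect_lt(max(abs(vt - hp$sigma_xi^2)), 4 * sqrt(2 / ndraw) * hp$sigma_xi^2)
})
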
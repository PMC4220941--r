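# Independent oracles used by the inference tests: posterior moments by
# dense tensor Gauss-Hermite quadrature over (latent field, observation
# effects, coefficients). Entirely separate from the package's Laplace
# machinery (pracma supplies the quadrature rule; all algebra is dense).

# Exact posterior mean of every coefficient for a tiny Bernoulli panel.
# Latent dimensions: n*T field values (+ n*T observation effects when
# sigma_eps > 0) + p coefficients; keep n*T and p small enough that
# K^(dims) nodes are feasible.
oracle_beta_mean <- function(panel, design, hyper, beta_prior_sd, K = 12) {
  n <- nrow(panel$colonies); TT <- length(panel$occasions); nT <- n * TT
  Z <- matrix(design, nT, dim(design)[3])
  p <- ncol(Z)
  yv <- as.vector(panel$presence)
  obs <- which(!is.na(yv)); y <- yv[obs]
  D <- as.matrix(dist(cbind(panel$colonies$easting, panel$colonies$northing)))
  use_eps <- hyper$sigma_eps > 0
  d_xi <- nT; d_eps <- if (use_eps) nT else 0
  dims <- d_xi + d_eps + p
  # factor of the field covariance: kron(chol(Rt)', chol(Cs)') acting on iid
  Cs <- matern_covariance(D, hyper$spatial_range, hyper$sigma_xi, hyper$nu)
  diag(Cs) <- diag(Cs) + 1e-8 * hyper$sigma_xi^2
  Rt <- ar1_structure(TT, hyper$ar_coef)$correlation
  Lfield <- kronecker(t(chol(Rt)), t(chol(Cs)))

  gh <- pracma::gaussHermite(K)
  nodes <- sqrt(2) * gh$x
  lw <- log(gh$w / sqrt(pi))
  grids <- replicate(dims, nodes, simplify = FALSE)
  U <- as.matrix(expand.grid(grids))         # (K^dims) x dims standard normals
  lwsum <- rowSums(as.matrix(expand.grid(replicate(dims, lw, simplify = FALSE))))

  xi_cells <- U[, seq_len(d_xi), drop = FALSE] %*% t(Lfield)
  beta_mat <- U[, d_xi + d_eps + seq_len(p), drop = FALSE] * beta_prior_sd
  eta <- xi_cells[, obs, drop = FALSE] + beta_mat %*% t(Z[obs, , drop = FALSE])
  if (use_eps)
    eta <- eta + hyper$sigma_eps * U[, d_xi + seq_len(nT), drop = FALSE][, obs, drop = FALSE]
  ll <- eta %*% y - rowSums(log1p(exp(eta)))
  lpost <- as.vector(ll) + lwsum
  wpost <- exp(lpost - max(lpost))
  wpost <- wpost / sum(wpost)
  as.vector(crossprod(wpost, beta_mat))
}

# brute-force kernel intensity (double loop, same estimator definition)
oracle_kernel_intensity <- function(points, window, bandwidth, weights,
                                    gx, gy, edge = "uniform") {
  vals <- matrix(0, length(gx), length(gy))
  n <- nrow(points)
  w <- weights
  if (edge == "diggle") {
    for (i in seq_len(n)) {
      ex <- pnorm((window[2] - points[i, 1]) / bandwidth) -
        pnorm((window[1] - points[i, 1]) / bandwidth)
      ey <- pnorm((window[4] - points[i, 2]) / bandwidth) -
        pnorm((window[3] - points[i, 2]) / bandwidth)
      w[i] <- w[i] / (ex * ey)
    }
  }
  for (a in seq_along(gx)) for (b in seq_along(gy)) {
    s <- 0
    for (i in seq_len(n))
      s <- s + w[i] * dnorm(gx[a] - points[i, 1], sd = bandwidth) *
        dnorm(gy[b] - points[i, 2], sd = bandwidth)
    if (edge == "uniform") {
      ex <- pnorm((window[2] - gx[a]) / bandwidth) -
        pnorm((window[1] - gx[a]) / bandwidth)
      ey <- pnorm((window[4] - gy[b]) / bandwidth) -
        pnorm((window[3] - gy[b]) / bandwidth)
      s <- s / (ex * ey)
    }
    vals[a, b] <- s
  }
  vals
}
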
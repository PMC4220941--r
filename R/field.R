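# Latent spatio-temporal Gaussian structure.
#
# Space: a Matern Gaussian field evaluated exactly (dense covariance) at the
# colony sites -- at ~69 sites the dense computation is exact and cheap, so
# no finite-element/GMRF approximation of the field is needed. Time: AR(1)
# dynamics. The joint field is separable, cov = R_t (x) C_s, and all solves
# and log-determinants use the Kronecker factorisation.

#' Hyperparameters of the latent space-time field
#'
#' @param spatial_range Matern range in metres: the distance at which spatial
#'   correlation drops to about 0.1 (the convention `kappa = sqrt(8 nu) /
#'   range`).
#' @param sigma_xi marginal standard deviation of the latent field, on the
#'   logit scale.
#' @param ar_coef first-order autoregressive coefficient, in (-1, 1);
#'   month-to-month persistence of the latent field.
#' @param sigma_eps standard deviation of the iid Gaussian observation-level
#'   effect (the white-noise term of the model equation, realised as an
#'   unstructured logit-scale random effect because the response is binary).
#' @param nu Matern smoothness, default 1.
#' @return list of class `wp_hyper`.
#' @export
hyperparameters <- function(spatial_range, sigma_xi, ar_coef, sigma_eps,
                            nu = 1) {
  if (!is.finite(spatial_range) || spatial_range <= 0)
    stop_wp("spatial_range must be > 0", class = "wp_value_error")
  if (!is.finite(sigma_xi) || sigma_xi < 0)
    stop_wp("sigma_xi must be >= 0", class = "wp_value_error")
  if (!is.finite(ar_coef) || abs(ar_coef) >= 1)
    stop_wp("ar_coef must satisfy |a| < 1", class = "wp_value_error")
  if (!is.finite(sigma_eps) || sigma_eps < 0)
    stop_wp("sigma_eps must be >= 0", class = "wp_value_error")
  if (!is.finite(nu) || nu <= 0)
    stop_wp("nu must be > 0", class = "wp_value_error")
  structure(list(spatial_range = spatial_range, sigma_xi = sigma_xi,
                 ar_coef = ar_coef, sigma_eps = sigma_eps, nu = nu),
            class = "wp_hyper")
}

#' Matern covariance
#'
#' `C(d) = sigma^2 2^(1-nu)/Gamma(nu) (kappa d)^nu K_nu(kappa d)` with
#' `kappa = sqrt(8 nu)/range`, so that correlation is approximately 0.1 at
#' `d = range`. `C(0) = sigma^2` exactly; at `nu = 0.5` the family reduces to
#' the exponential covariance `sigma^2 exp(-kappa d)`.
#'
#' @param distances numeric vector or symmetric matrix of distances (m) with
#'   zero diagonal.
#' @param range,sigma,nu Matern parameters (range > 0, sigma > 0, nu > 0).
#' @return covariance of the same shape as `distances`.
#' @export
matern_covariance <- function(distances, range, sigma = 1, nu = 1) {
  if (range <= 0 || sigma <= 0 || nu <= 0)
    stop_wp("Matern parameters must be positive", class = "wp_value_error")
  if (is.matrix(distances)) {
    if (!isSymmetric(unname(distances), tol = 1e-8))
      stop_wp("distance matrix must be symmetric", class = "wp_value_error")
    if (any(abs(diag(distances)) > 1e-12))
      stop_wp("distance matrix must have zero diagonal", class = "wp_value_error")
  }
  if (any(distances < 0))
    stop_wp("distances must be non-negative", class = "wp_value_error")
  kappa <- sqrt(8 * nu) / range
  x <- kappa * distances
  out <- distances
  zero <- x == 0
  out[zero] <- sigma^2
  xs <- x[!zero]
  # log-scale evaluation; besselK(expon.scaled) avoids underflow at large x
  out[!zero] <- exp(2 * log(sigma) + (1 - nu) * log(2) - lgamma(nu) +
                      nu * log(xs) + log(besselK(xs, nu, expon.scaled = TRUE)) - xs)
  out
}

#' AR(1) correlation and precision
#'
#' Stationary first-order autoregression over `T` occasions:
#' correlation `R[t, t'] = a^|t - t'|` and its tridiagonal inverse.
#'
#' @param T number of occasions (>= 1).
#' @param a autoregressive coefficient, |a| < 1.
#' @return list with dense `correlation` (T x T) and sparse tridiagonal
#'   `precision`; their product is the identity.
#' @export
ar1_structure <- function(T, a) {
  if (abs(a) >= 1) stop_wp("|ar_coef| must be < 1", class = "wp_value_error")
  if (T < 1) stop_wp("T must be >= 1", class = "wp_value_error")
  R <- a^abs(outer(seq_len(T), seq_len(T), "-"))
  if (T == 1) {
    Q <- Matrix::Diagonal(1)
  } else {
    Q <- Matrix::bandSparse(T, k = 0:1,
      diagonals = list(c(1, rep(1 + a^2, T - 2), 1), rep(-a, T - 1)),
      symmetric = TRUE) / (1 - a^2)
  }
  list(correlation = R, precision = Q)
}

# log det of the AR(1) correlation matrix (closed form)
.ar1_logdet <- function(T, a) (T - 1) * log(1 - a^2)

#' Joint separable space-time prior
#'
#' The stacked latent field `xi` (cell order: colony fastest, occasion
#' slowest) has covariance `R_t (x) C_s`, where `R_t` is the AR(1)
#' correlation and `C_s` the Matern covariance with marginal variance
#' `sigma_xi^2` -- so the stationary marginal variance of every cell is
#' `sigma_xi^2`. Solves, log-determinants and sampling use the Kronecker
#' factorisation; the full `nT x nT` covariance is only materialised on
#' request for small problems.
#'
#' @param hyper a [hyperparameters()] object (with `sigma_xi > 0`).
#' @param distances n x n matrix of pairwise site distances (m).
#' @param T number of occasions.
#' @param jitter relative diagonal jitter added to the spatial covariance
#'   before factorisation (times `sigma_xi^2`).
#' @return object of class `wp_st_prior` with components `Cs`, `Rt`, the
#'   Cholesky factors, and bookkeeping fields.
#' @export
st_prior <- function(hyper, distances, T, jitter = 1e-8) {
  if (hyper$sigma_xi <= 0)
    stop_wp("st_prior requires sigma_xi > 0", class = "wp_value_error")
  n <- nrow(distances)
  Cs <- matern_covariance(distances, hyper$spatial_range, hyper$sigma_xi,
                          hyper$nu)
  diag(Cs) <- diag(Cs) + jitter * hyper$sigma_xi^2
  Rt <- ar1_structure(T, hyper$ar_coef)$correlation
  Ls <- chol(Cs)          # upper triangular
  Lt <- chol(Rt)
  structure(list(hyper = hyper, n = n, T = T, Cs = Cs, Rt = Rt,
                 chol_Cs = Ls, chol_Rt = Lt,
                 logdet = T * 2 * sum(log(diag(Ls))) +
                   n * .ar1_logdet(T, hyper$ar_coef)),
            class = "wp_st_prior")
}

#' Apply the prior precision to a field
#'
#' Computes `Sigma^{-1} vec(X)` in matrix form, `Cs^{-1} X Rt^{-1}`, without
#' forming the `nT x nT` matrix.
#'
#' @param prior a [st_prior()] object.
#' @param X n x T matrix (the latent field).
#' @return n x T matrix.
#' @export
st_prior_solve <- function(prior, X) {
  Y <- chol2inv(prior$chol_Cs) %*% X
  Y %*% chol2inv(prior$chol_Rt)
}

#' Dense covariance of the stacked field (small problems)
#' @param prior a [st_prior()] object with `n * T` modest.
#' @return dense `nT x nT` covariance, cell order colony-fastest.
#' @export
st_prior_cov <- function(prior) {
  kronecker(prior$Rt, prior$Cs)
}

#' Draw a latent field from the space-time prior
#'
#' Exact draw via the Kronecker Cholesky factors: `Xi = Ls' Z Ut` with
#' `Z ~ N(0, I)`, `Ls'Ls = Cs`, `Ut'Ut = Rt`.
#'
#' @param hyper a [hyperparameters()] object; `sigma_xi = 0` returns the zero
#'   field.
#' @param distances n x n site distance matrix.
#' @param T number of occasions.
#' @param seed optional integer seed for reproducibility.
#' @return n x T matrix (logit scale).
#' @export
sample_field <- function(hyper, distances, T, seed = NULL) {
  n <- nrow(distances)
  if (!is.null(seed)) set.seed(seed)
  if (hyper$sigma_xi == 0) return(matrix(0, n, T))
  prior <- st_prior(hyper, distances, T)
  Z <- matrix(stats::rnorm(n * T), n, T)
  t(prior$chol_Cs) %*% Z %*% prior$chol_Rt
}
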
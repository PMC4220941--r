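# Nested Laplace inference for the latent-Gaussian binomial model.
#
# Latent vector x = (xi_1..xi_nT, eps_1..eps_nT, beta_1..beta_p), with
# Gaussian prior precision Q = blockdiag(Q_time (x) Q_space / sigma_xi^2,
# I/sigma_eps^2, I/beta_prior_sd^2) and Bernoulli-logit likelihood through
# eta = A x, A = [S | S | Z_obs] (S selects observed cells). The inner step
# finds the posterior mode of x by damped Newton (the objective is strictly
# concave) and a Gaussian approximation with precision H = Q + A'WA; the
# outer step integrates the Laplace evidence over a deterministic grid of
# hyperparameters. The likelihood curvature enters H through a precomputed
# linear map from the per-cell Newton weights into the nonzero slots of H,
# so every iteration is a sparse mat-vec plus a CHOLMOD numeric update.

#' Inference control settings
#'
#' @param max_iter Newton iteration cap for the inner optimisation.
#' @param tol convergence tolerance on the max-abs gradient of the inner
#'   objective.
#' @param beta_prior_sd standard deviation of the zero-mean Gaussian prior on
#'   each (standardized-scale) coefficient.
#' @param jitter relative diagonal jitter for spatial covariance
#'   factorisations.
#' @param profile_terms coefficients whose posterior marginals are computed
#'   by the profile-Laplace method rather than taken from the conditional
#'   Gaussian approximation: a character vector of term names, `"all"`, or
#'   `character(0)` for the plain Gaussian strategy. Default `"intercept"`:
#'   the intercept is confounded with the overall level of the latent field,
#'   so its Gaussian (joint-mode) marginal is shifted for rare binary
#'   responses, while the slope marginals are effectively Gaussian at this
#'   information level. Profiling evaluates, for each abscissa of the
#'   coefficient, a Laplace approximation over all remaining latent
#'   variables.
#' @param profile_points abscissae per profiled coefficient.
#' @param profile_weight_min hyper-grid points with smaller posterior weight
#'   keep their Gaussian conditional marginal instead of being profiled.
#' @param marginal_points abscissae of the stored posterior marginal grids.
#' @param verbose print per-grid-point progress.
#' @return list of class `wp_control`.
#' @export
fit_control <- function(max_iter = 100L, tol = 1e-9, beta_prior_sd = 10,
                        jitter = 1e-8, profile_terms = "intercept",
                        profile_points = 11L, profile_weight_min = 0.03,
                        marginal_points = 512L, verbose = FALSE) {
  structure(list(max_iter = max_iter, tol = tol,
                 beta_prior_sd = beta_prior_sd, jitter = jitter,
                 profile_terms = profile_terms,
                 profile_points = profile_points,
                 profile_weight_min = profile_weight_min,
                 marginal_points = marginal_points, verbose = verbose),
            class = "wp_control")
}

#' Hyperparameter priors
#'
#' Weakly informative priors on the transformed hyperparameters, centred on
#' data-scale heuristics: log spatial range at the log median pairwise
#' distance between colonies; log latent and observation-effect standard
#' deviations at 0 (sd 1 on the logit scale); the AR coefficient on the
#' Fisher scale `log((1+a)/(1-a))` centred at a = 0.7 with a wide spread.
#'
#' @param panel a [survey_panel()] (for the distance heuristic).
#' @return list of prior means/sds used to weight the hyperparameter grid.
#' @export
default_priors <- function(panel) {
  D <- .pairwise_dist(.coords_of(panel$colonies))
  med <- stats::median(D[upper.tri(D)])
  list(lrange_mean = log(med), lrange_sd = 1,
       lsigma_xi_mean = 0, lsigma_xi_sd = 1,
       theta_a_mean = log(1.7 / 0.3), theta_a_sd = 2,
       lsigma_eps_mean = 0, lsigma_eps_sd = 1)
}

.log_hyper_prior <- function(hp, priors) {
  theta_a <- log((1 + hp$ar_coef) / (1 - hp$ar_coef))
  out <- stats::dnorm(log(hp$spatial_range), priors$lrange_mean,
                      priors$lrange_sd, log = TRUE) +
    stats::dnorm(theta_a, priors$theta_a_mean, priors$theta_a_sd, log = TRUE)
  # boundary values (variance pinned to zero) carry no prior contribution
  if (hp$sigma_xi > 0)
    out <- out + stats::dnorm(log(hp$sigma_xi), priors$lsigma_xi_mean,
                              priors$lsigma_xi_sd, log = TRUE)
  if (hp$sigma_eps > 0)
    out <- out + stats::dnorm(log(hp$sigma_eps), priors$lsigma_eps_mean,
                              priors$lsigma_eps_sd, log = TRUE)
  out
}

#' Hyperparameter integration grid
#'
#' Deterministic tensor grid over (spatial range, latent sd, AR coefficient,
#' observation-effect sd), evenly spaced on log scales (Fisher scale for the
#' AR coefficient). The spatial-range axis is centred on the median pairwise
#' distance between colonies. Rows are ordered so consecutive points differ
#' in one axis, which lets the inner optimiser warm-start.
#'
#' @param panel a [survey_panel()].
#' @param points_per_axis grid resolution per axis (default 3).
#' @param nu Matern smoothness held fixed across the grid.
#' @return data.frame of grid points with attribute `nu`.
#' @export
hyper_grid <- function(panel, points_per_axis = 3, nu = 1) {
  D <- .pairwise_dist(.coords_of(panel$colonies))
  med <- stats::median(D[upper.tri(D)])
  k <- points_per_axis
  range_v <- exp(seq(log(0.5 * med), log(2 * med), length.out = k))
  sxi_v <- exp(seq(log(0.3), log(3), length.out = k))
  a_v <- tanh(seq(0.4, 3.4, length.out = k) / 2)
  seps_v <- exp(seq(log(0.05), log(0.8), length.out = k))
  g <- expand.grid(sigma_eps = seps_v, sigma_xi = sxi_v, ar_coef = a_v,
                   spatial_range = range_v, KEEP.OUT.ATTRS = FALSE)
  g <- g[, c("spatial_range", "sigma_xi", "ar_coef", "sigma_eps")]
  attr(g, "nu") <- nu
  g
}

#' Linear predictor of the disease model
#'
#' `eta(i, t) = z(s_i, t) beta + xi(s_i, t) + eps(s_i, t)`; the presence
#' probability is `plogis(eta)`.
#'
#' @param design a [build_design()] array.
#' @param beta coefficient vector (length = number of covariates).
#' @param xi latent field matrix (colony x occasion) or `NULL` for zero.
#' @param eps observation-effect matrix or `NULL` for zero.
#' @return colony x occasion matrix of linear-predictor values.
#' @export
linear_predictor <- function(design, beta, xi = NULL, eps = NULL) {
  d <- dim(design)
  if (length(beta) != d[3])
    stop_wp("beta has length ", length(beta), ", design has ", d[3],
            " covariates", class = "wp_value_error")
  eta <- matrix(design_matrix(design) %*% beta, d[1], d[2])
  if (!is.null(xi)) {
    if (!all(dim(xi) == d[1:2]))
      stop_wp("xi dimensions do not match the design", class = "wp_value_error")
    eta <- eta + xi
  }
  if (!is.null(eps)) {
    if (!all(dim(eps) == d[1:2]))
      stop_wp("eps dimensions do not match the design", class = "wp_value_error")
    eta <- eta + eps
  }
  dimnames(eta) <- dimnames(design)[1:2]
  eta
}

# ---- observation families -------------------------------------------------
#
# The iid observation-level effect eps is not kept in the latent vector for
# the Bernoulli response: with one Bernoulli trial per cell a Laplace
# approximation over one effect per observation is the worst case for
# mode-based inference (it shrinks the effect towards zero and biases the
# evidence towards small variances). Instead eps is integrated out exactly,
# cell by cell, with Gauss-Hermite quadrature inside the likelihood:
#   ltilde(mu) = log Int N(e; 0, sigma_eps^2) Bern(y | logis(mu + e)) de,
# which stays strictly concave in mu (marginalisation preserves
# log-concavity), so the Newton inner step is unchanged.

# Golub-Welsch nodes/weights for the physicists' Gauss-Hermite rule
.gauss_hermite <- function(n) {
  if (n == 1) return(list(nodes = 0, weights = sqrt(pi)))
  J <- matrix(0, n, n)
  off <- sqrt(seq_len(n - 1) / 2)
  J[cbind(seq_len(n - 1), seq_len(n - 1) + 1)] <- off
  J[cbind(seq_len(n - 1) + 1, seq_len(n - 1))] <- off
  e <- eigen(J, symmetric = TRUE)
  list(nodes = e$values, weights = sqrt(pi) * e$vectors[1, ]^2)
}

.gh_default <- .gauss_hermite(15)

# Bernoulli-logit family with the observation effect marginalised by
# quadrature; sigma_eps = 0 reduces exactly to the plain logit likelihood.
# `all()` returns log-likelihood, score and Newton weight in one pass over
# the (cell x node) grid; `loglik()` is the cheap line-search version.
.family_bernoulli <- function(sigma_eps, gh = .gh_default) {
  en <- sqrt(2) * sigma_eps * gh$nodes        # effect values at the nodes
  cw <- gh$weights / sqrt(pi)                 # normalised weights
  Q <- length(en)
  nodal <- function(eta, y) {
    E <- outer(eta, en, "+")
    ll <- y * E - log1pexp(E)
    mx <- ll[, 1]
    if (Q > 1) for (q in 2:Q) mx <- pmax(mx, ll[, q])
    r <- exp(ll - mx) * rep(cw, each = length(eta))
    den <- rowSums(r)
    list(E = E, post = r / den, logI = mx + log(den))
  }
  list(
    loglik = function(eta, y) sum(nodal(eta, y)$logI),
    all = function(eta, y) {
      nd <- nodal(eta, y)
      pq <- stats::plogis(nd$E)
      s1 <- rowSums(nd$post * (y - pq))
      s2 <- rowSums(nd$post * (-pq * (1 - pq) + (y - pq)^2))
      list(loglik = sum(nd$logI), score = s1,
           weight = pmax(-(s2 - s1^2), 0))   # negative curvature of logI
    },
    score = function(eta, y) {
      nd <- nodal(eta, y)
      rowSums(nd$post * (y - stats::plogis(nd$E)))
    },
    weight = function(eta, y) {
      nd <- nodal(eta, y)
      pq <- stats::plogis(nd$E)
      s1 <- rowSums(nd$post * (y - pq))
      s2 <- rowSums(nd$post * (-pq * (1 - pq) + (y - pq)^2))
      pmax(-(s2 - s1^2), 0)
    },
    eps_mean = function(eta, y) {
      nd <- nodal(eta, y)
      rowSums(nd$post * rep(en, each = length(eta)))
    })
}

.family_gaussian <- function(obs_sd) list(
  loglik = function(eta, y) -0.5 * sum(((y - eta) / obs_sd)^2),
  all = function(eta, y) list(loglik = -0.5 * sum(((y - eta) / obs_sd)^2),
                              score = (y - eta) / obs_sd^2,
                              weight = rep(1 / obs_sd^2, length(eta))),
  score = function(eta, y) (y - eta) / obs_sd^2,
  weight = function(eta, y) rep(1 / obs_sd^2, length(eta)))

# ---- engine ---------------------------------------------------------------

# Precomputes everything that does not depend on the hyperparameters:
# the observation operator A, the likelihood-to-H slot map, the H pattern
# and its symbolic Cholesky factorisation. `drop_beta` removes one
# coefficient column from the latent vector (its contribution then enters
# through the `offset` argument of .eval_point -- the profile-Laplace path).
# `shared_cache` lets several engines reuse the spatial/temporal precision
# cache.
.wp_engine <- function(panel, design, control, include_eps = FALSE,
                       family = function(hp) .family_bernoulli(hp$sigma_eps),
                       response = NULL, drop_beta = NULL,
                       shared_cache = NULL) {
  n <- nrow(panel$colonies); TT <- length(panel$occasions); nT <- n * TT
  Z <- design_matrix(design)
  zdrop <- NULL
  if (!is.null(drop_beta)) {
    zdrop <- Z[, drop_beta]
    Z <- Z[, -drop_beta, drop = FALSE]
  }
  p <- ncol(Z)
  yv <- as.vector(if (is.null(response)) panel$presence else response)
  obs <- which(!is.na(yv))
  y <- yv[obs]
  nobs <- length(obs)
  neps <- if (include_eps) nT else 0L
  m <- nT + neps + p

  Sel <- Matrix::sparseMatrix(i = seq_len(nobs), j = obs, x = 1,
                              dims = c(nobs, nT))
  blocks <- list(Sel)
  if (include_eps) blocks <- c(blocks, list(Sel))
  blocks <- c(blocks, list(Matrix::Matrix(Z[obs, , drop = FALSE], sparse = TRUE)))
  A <- Reduce(methods::cbind2, blocks)

  # H pattern: reference prior (dense-in-space kron pattern) + A'A
  Qt_pat <- ar1_structure(TT, 0.5)$precision
  Qs_pat <- Matrix::Matrix(matrix(1, n, n) + diag(n), sparse = TRUE)
  Qxi_pat <- kronecker(Qt_pat, Qs_pat)
  Qpat <- Matrix::bdiag(c(list(Qxi_pat),
                          if (include_eps) list(Matrix::Diagonal(nT)),
                          list(Matrix::Diagonal(p))))
  Hpat <- Matrix::forceSymmetric(Qpat + crossprod(A), "U")
  Hpat <- methods::as(Hpat, "CsparseMatrix")
  stopifnot(methods::is(Hpat, "dsCMatrix"))
  nnzH <- length(Hpat@x)
  lookup <- Matrix::sparseMatrix(i = Hpat@i + 1L,
                                 j = rep(seq_len(ncol(Hpat)), diff(Hpat@p)),
                                 x = seq_len(nnzH), dims = dim(Hpat))

  # slot map for the likelihood part: entry (i, j) of A'WA (upper triangle)
  # receives sum_k w_k A[k, i] A[k, j]
  nz <- if (include_eps) 2L + p else 1L + p
  pi_ <- rep(seq_len(nz), times = nz); pj_ <- rep(seq_len(nz), each = nz)
  keep <- pi_ <= pj_
  pi_ <- pi_[keep]; pj_ <- pj_[keep]
  cidx <- cbind(obs, if (include_eps) nT + obs,
                matrix(rep(nT + neps + seq_len(p), each = nobs), nobs, p))
  vmat <- cbind(rep(1, nobs), if (include_eps) rep(1, nobs),
                Z[obs, , drop = FALSE])
  pos <- vv <- matrix(0, nobs, length(pi_))
  for (q in seq_along(pi_)) {
    pos[, q] <- lookup[cbind(cidx[, pi_[q]], cidx[, pj_[q]])]
    vv[, q] <- vmat[, pi_[q]] * vmat[, pj_[q]]
  }
  Pmap <- Matrix::sparseMatrix(i = as.vector(pos),
                               j = rep(seq_len(nobs), length(pi_)),
                               x = as.vector(vv), dims = c(nnzH, nobs))

  # slot positions of the prior blocks
  ut <- Qxi_pat@i + 1L <= rep(seq_len(ncol(Qxi_pat)), diff(Qxi_pat@p))
  qxi_ij <- cbind(Qxi_pat@i + 1L,
                  rep(seq_len(ncol(Qxi_pat)), diff(Qxi_pat@p)))[ut, , drop = FALSE]
  map_qxi <- lookup[qxi_ij]
  map_eps <- if (include_eps) lookup[cbind(nT + seq_len(nT), nT + seq_len(nT))]
  map_beta <- lookup[cbind(nT + neps + seq_len(p), nT + neps + seq_len(p))]

  D <- .pairwise_dist(.coords_of(panel$colonies))

  env <- new.env(parent = emptyenv())
  env$chol <- NULL
  cache <- shared_cache %||% new.env(parent = emptyenv())
  if (is.null(cache$kron)) cache$kron <- list()

  list(n = n, TT = TT, nT = nT, p = p, m = m, neps = neps,
       include_eps = include_eps, y = y, obs = obs, nobs = nobs,
       A = A, At = t(A), H = Hpat, Pmap = Pmap,
       map_qxi = map_qxi, map_eps = map_eps, map_beta = map_beta,
       D = D, family = family, control = control,
       zdrop = zdrop, env = env, cache = cache)
}

# spatial/temporal precision (unit latent variance) with its log det,
# cached per (range, ar_coef, nu)
.engine_qxi <- function(engine, hp) {
  key <- paste(signif(hp$spatial_range, 12), signif(hp$ar_coef, 12),
               signif(hp$nu, 12), sep = "|")
  cached <- engine$cache$kron[[key]]
  if (!is.null(cached)) return(cached)
  Cs <- matern_covariance(engine$D, hp$spatial_range, 1, hp$nu)
  diag(Cs) <- diag(Cs) + engine$control$jitter
  cls <- chol(Cs)
  Qs <- chol2inv(cls)
  Qt <- ar1_structure(engine$TT, hp$ar_coef)$precision
  Qxi_corr <- Matrix::forceSymmetric(
    methods::as(kronecker(Qt, Matrix::Matrix(Qs, sparse = TRUE)),
                "CsparseMatrix"), "U")
  stopifnot(methods::is(Qxi_corr, "dsCMatrix"))
  # align with the H pattern map (same deterministic construction each time)
  stopifnot(length(Qxi_corr@x) == length(engine$map_qxi))
  ld_corr <- -engine$n * .ar1_logdet(engine$TT, hp$ar_coef) -
    engine$TT * 2 * sum(log(diag(cls)))
  out <- list(Q = Qxi_corr, logdet = ld_corr)
  engine$cache$kron[[key]] <- out
  out
}

# Newton inner optimisation at one hyperparameter point. `offset` is added
# to the linear predictor (used when profiling a fixed coefficient).
.eval_point <- function(engine, hp, x0 = NULL, offset = 0,
                        want_beta_cov = TRUE) {
  ctrl <- engine$control
  nT <- engine$nT; neps <- engine$neps; p <- engine$p; m <- engine$m
  qxi <- .engine_qxi(engine, hp)
  tau_xi <- 1 / hp$sigma_xi^2
  tau_b <- 1 / ctrl$beta_prior_sd^2
  hkey <- paste(hp$spatial_range, hp$sigma_xi, hp$ar_coef, hp$sigma_eps,
                hp$nu)
  if (identical(engine$env$qkey, hkey)) {
    Qx0 <- engine$env$Qx0
    logdetQ <- engine$env$logdetQ
  } else {
    logdetQ <- qxi$logdet - nT * log(hp$sigma_xi^2) + p * log(tau_b)
    if (engine$include_eps)
      logdetQ <- logdetQ - neps * log(hp$sigma_eps^2)
    Qx0 <- numeric(length(engine$H@x))
    Qx0[engine$map_qxi] <- qxi$Q@x * tau_xi
    if (engine$include_eps)
      Qx0[engine$map_eps] <- Qx0[engine$map_eps] + 1 / hp$sigma_eps^2
    Qx0[engine$map_beta] <- Qx0[engine$map_beta] + tau_b
    engine$env$qkey <- hkey
    engine$env$Qx0 <- Qx0
    engine$env$logdetQ <- logdetQ
  }

  Qmul <- function(x) {
    out <- numeric(m)
    out[1:nT] <- as.vector(qxi$Q %*% x[1:nT]) * tau_xi
    if (engine$include_eps)
      out[nT + 1:nT] <- x[nT + 1:nT] / hp$sigma_eps^2
    if (p > 0) {
      bi <- (nT + neps) + seq_len(p)
      out[bi] <- x[bi] * tau_b
    }
    out
  }

  if (identical(engine$env$fam_key, hp$sigma_eps)) {
    fam <- engine$env$fam
  } else {
    fam <- engine$family(hp)
    engine$env$fam_key <- hp$sigma_eps
    engine$env$fam <- fam
  }
  y <- engine$y
  objective <- function(x, eta, Qx) fam$loglik(eta, y) - 0.5 * sum(x * Qx)

  x <- if (is.null(x0)) numeric(m) else x0
  eta <- as.vector(engine$A %*% x) + offset
  Qx <- Qmul(x)
  f <- objective(x, eta, Qx)
  H <- engine$H
  converged <- FALSE; it <- 0L; grad_max <- NA_real_
  while (it < ctrl$max_iter) {
    it <- it + 1L
    fa <- fam$all(eta, y)
    g <- as.vector(engine$At %*% fa$score) - Qx
    grad_max <- max(abs(g))
    if (grad_max < ctrl$tol) { converged <- TRUE; break }
    w <- pmax(fa$weight, 1e-12)
    H@x <- Qx0 + as.vector(engine$Pmap %*% w)
    if (is.null(engine$env$chol)) {
      engine$env$chol <- Matrix::Cholesky(H, LDL = FALSE, super = TRUE)
    } else {
      engine$env$chol <- update(engine$env$chol, H)
    }
    dx <- as.vector(solve(engine$env$chol, g))
    # predicted quadratic gain; once it falls below the rounding noise of
    # the objective the mode is resolved to machine precision
    pred <- sum(g * dx) / 2
    if (pred < 1e-14 * (1 + abs(f))) { converged <- TRUE; break }
    step <- 1; accepted <- FALSE
    for (h in 1:30) {
      x_new <- x + step * dx
      eta_new <- as.vector(engine$A %*% x_new) + offset
      Qx_new <- Qmul(x_new)
      f_new <- objective(x_new, eta_new, Qx_new)
      if (is.finite(f_new) && f_new >= f - 1e-10 * (1 + abs(f))) {
        accepted <- TRUE; break
      }
      step <- step / 2
    }
    if (!accepted) {
      # no numerically detectable ascent left
      converged <- pred < 1e-8 * (1 + abs(f))
      break
    }
    x <- x_new; eta <- eta_new; Qx <- Qx_new; f <- f_new
  }
  if (!converged && grad_max > 1e-4 * (1 + abs(f)))
    stop_wp("inner optimisation failed to converge (", it, " iterations, ",
            "max|grad| = ", signif(grad_max, 3), ")",
            class = "wp_convergence_error")

  # final curvature at the mode
  w <- pmax(fam$weight(eta, y), 1e-12)
  H@x <- Qx0 + as.vector(engine$Pmap %*% w)
  engine$env$chol <- if (is.null(engine$env$chol))
    Matrix::Cholesky(H, LDL = FALSE, super = TRUE) else
      update(engine$env$chol, H)
  logdetH <- 2 * as.numeric(determinant(engine$env$chol, sqrt = TRUE)$modulus)
  loglik <- fam$loglik(eta, y)
  log_evidence <- loglik - 0.5 * sum(x * Qx) + 0.5 * logdetQ - 0.5 * logdetH

  bidx <- (nT + neps) + seq_len(p)
  beta_mean <- x[bidx]
  beta_sd <- rep(NA_real_, p)
  if (want_beta_cov && p > 0) {
    B <- matrix(0, m, p); B[cbind(bidx, seq_len(p))] <- 1
    Sb <- as.matrix(solve(engine$env$chol, B))
    beta_sd <- sqrt(pmax(Sb[cbind(bidx, seq_len(p))], 0))
  }

  list(x = x, eta = eta, beta_mean = beta_mean, beta_sd = beta_sd,
       log_evidence = log_evidence, loglik = loglik, logdetH = logdetH,
       iterations = it, converged = converged, grad_max = grad_max, H = H)
}

#' Inner Gaussian (Laplace) approximation at fixed hyperparameters
#'
#' Optimises the Bernoulli-logit log-likelihood plus Gaussian log-prior over
#' the stacked latent vector (field and coefficients; the iid observation
#' effect is marginalised exactly inside the likelihood by Gauss-Hermite
#' quadrature) using damped Newton with step-halving; the objective is
#' strictly concave so the mode is unique. Returns the mode, the precision
#' at the mode and the Laplace approximation of the log marginal likelihood.
#'
#' @param panel a [survey_panel()].
#' @param design a [build_design()] array.
#' @param hyper a [hyperparameters()] object.
#' @param control a [fit_control()] list.
#' @param family `"bernoulli"` (presence/absence, the model's response) or
#'   `"gaussian"` (identity link with known noise sd; used to cross-check the
#'   optimiser against conjugate closed forms).
#' @param obs_sd observation noise sd for the Gaussian family.
#' @param response optional response matrix overriding `panel$presence`
#'   (real-valued responses for the Gaussian family).
#' @return list with elements `xi` (colony x occasion mode of the latent
#'   field), `eps` (posterior mean of the observation effect at the mode),
#'   `beta`, `beta_sd`, `precision` (sparse, at the mode), `log_evidence`
#'   and `diagnostics`.
#' @export
fit_laplace <- function(panel, design, hyper, control = fit_control(),
                        family = c("bernoulli", "gaussian"), obs_sd = 1,
                        response = NULL) {
  family <- match.arg(family)
  if (family == "bernoulli") {
    factory <- function(hp) .family_bernoulli(hp$sigma_eps)
    include_eps <- FALSE
  } else {
    factory <- function(hp) .family_gaussian(obs_sd)
    include_eps <- hyper$sigma_eps > 0
  }
  engine <- .wp_engine(panel, design, control, include_eps = include_eps,
                       family = factory, response = response)
  res <- .eval_point(engine, hyper)
  nT <- engine$nT
  xi <- matrix(res$x[1:nT], engine$n, engine$TT)
  eps <- matrix(0, engine$n, engine$TT)
  if (family == "bernoulli" && hyper$sigma_eps > 0) {
    fam <- .family_bernoulli(hyper$sigma_eps)
    eps[engine$obs] <- fam$eps_mean(res$eta, engine$y)
  } else if (engine$include_eps) {
    eps <- matrix(res$x[nT + 1:nT], engine$n, engine$TT)
  }
  list(xi = xi, eps = eps, beta = res$beta_mean, beta_sd = res$beta_sd,
       precision = res$H, log_evidence = res$log_evidence,
       diagnostics = res[c("iterations", "converged", "grad_max", "loglik",
                           "logdetH")])
}

#' Fit the space-time disease model
#'
#' Full nested-Laplace fit: for every hyperparameter grid point, the inner
#' Gaussian approximation over the latent vector is computed (warm-started
#' from the previous point) and its Laplace evidence recorded; grid weights
#' are the normalised product of evidence and hyperparameter prior; the
#' posterior marginal of each coefficient is the weight-mixture of its
#' conditional marginals. A single-point grid gives the empirical-Bayes
#' conditional fit.
#'
#' @param panel a [survey_panel()].
#' @param design a [build_design()] array (defaults to the standard design).
#' @param grid hyperparameter grid (data.frame from [hyper_grid()], or any
#'   data.frame with columns `spatial_range`, `sigma_xi`, `ar_coef`,
#'   `sigma_eps`); default `hyper_grid(panel)`.
#' @param priors hyperparameter prior settings from [default_priors()].
#' @param control a [fit_control()] list.
#' @return object of class `wp_fit`: the weighted grid (`$grid` with
#'   `log_evidence` and `weight` columns), per-point conditional moments,
#'   stored posterior marginals (`$beta_marginals`: abscissae and density per
#'   coefficient), the latent-field mode at the modal grid point
#'   (`$latent_mode`), and per-point diagnostics.
#' @export
fit_stmodel <- function(panel, design = build_design(panel), grid = NULL,
                        priors = NULL, control = fit_control()) {
  if (is.null(grid)) grid <- hyper_grid(panel)
  if (is.null(priors)) priors <- default_priors(panel)
  nu <- attr(grid, "nu") %||% 1
  K <- nrow(grid)
  engine <- .wp_engine(panel, design, control)
  p <- engine$p
  bm <- bs <- matrix(NA_real_, K, p)
  lev <- lpr <- rep(NA_real_, K)
  diag_df <- data.frame(iterations = integer(K), converged = logical(K),
                        grad_max = numeric(K))
  x_warm <- NULL
  best <- -Inf; x_best <- NULL; ok <- logical(K)
  res_list <- vector("list", K)
  for (k in seq_len(K)) {
    hp <- hyperparameters(grid$spatial_range[k], grid$sigma_xi[k],
                          grid$ar_coef[k], grid$sigma_eps[k], nu = nu)
    res <- tryCatch(.eval_point(engine, hp, x0 = x_warm),
                    wp_convergence_error = function(e) e)
    if (inherits(res, "error")) {
      diag_df$converged[k] <- FALSE
      next
    }
    ok[k] <- TRUE
    x_warm <- res$x
    res_list[[k]] <- res$x
    bm[k, ] <- res$beta_mean; bs[k, ] <- res$beta_sd
    lev[k] <- res$log_evidence
    lpr[k] <- .log_hyper_prior(hp, priors)
    diag_df$iterations[k] <- res$iterations
    diag_df$converged[k] <- res$converged
    diag_df$grad_max[k] <- res$grad_max
    if (lev[k] + lpr[k] > best) { best <- lev[k] + lpr[k]; x_best <- res$x }
    if (control$verbose)
      message(sprintf("  grid %d/%d: log evidence %.2f (%d iter)", k, K,
                      lev[k], res$iterations))
  }
  if (!any(ok))
    stop_wp("no hyperparameter grid point converged", class = "wp_fit_error")
  lw <- lev + lpr
  lw[!ok] <- -Inf
  w <- exp(lw - max(lw, na.rm = TRUE))
  w[!is.finite(w)] <- 0
  w <- w / sum(w)
  grid$log_evidence <- lev
  grid$weight <- w

  terms <- colnames(design_matrix(design))
  marg <- .mixture_marginals(w[ok], bm[ok, , drop = FALSE],
                             bs[ok, , drop = FALSE], terms,
                             n_grid = control$marginal_points)

  prof_terms <- control$profile_terms
  if (identical(prof_terms, "all")) prof_terms <- terms
  prof_idx <- match(intersect(prof_terms %||% character(0), terms), terms)
  for (j in prof_idx)
    marg[[j]] <- .profile_marginal(panel, design, engine, grid, nu, w, ok,
                                   bm, bs, res_list, j, control)

  structure(list(grid = grid, beta_mean = bm, beta_sd = bs,
                 weights = w, beta_marginals = marg,
                 latent_mode = matrix(x_best[1:engine$nT], engine$n,
                                      engine$TT),
                 x_mode = x_best, diagnostics = diag_df,
                 terms = terms,
                 labels = attr(design, "labels") %||% terms,
                 control = control, priors = priors,
                 n = engine$n, T = engine$TT, n_obs = engine$nobs),
            class = "wp_fit")
}

# Profile-Laplace posterior marginal of coefficient j: at every
# non-negligible hyper-grid point, evaluate the Laplace evidence on a grid
# of fixed coefficient values (Newton over all remaining latent variables,
# warm-started along the abscissa sweep), multiply by the coefficient's
# prior, and mix the per-point densities by the grid weights. Low-weight
# points keep their Gaussian conditional.
.profile_marginal <- function(panel, design, engine, grid, nu, w, ok,
                              bm, bs, xs, j, control) {
  ks_all <- which(ok & w > 0)
  thresh <- min(control$profile_weight_min, max(w[ks_all]))
  ks <- which(ok & w >= thresh)
  eng_j <- .wp_engine(panel, design, control,
                      include_eps = engine$include_eps,
                      family = engine$family, drop_beta = j,
                      shared_cache = engine$cache)
  zj <- eng_j$zdrop[eng_j$obs]
  bj_global <- engine$nT + engine$neps + j
  np <- control$profile_points
  prof <- vector("list", length(ks))
  for (ii in seq_along(ks)) {
    k <- ks[ii]
    hp <- hyperparameters(grid$spatial_range[k], grid$sigma_xi[k],
                          grid$ar_coef[k], grid$sigma_eps[k], nu = nu)
    bgrid <- seq(bm[k, j] - 5 * bs[k, j], bm[k, j] + 5 * bs[k, j],
                 length.out = np)
    centre <- (np + 1L) %/% 2L
    lp <- numeric(np)
    x0 <- xs[[k]][-bj_global]
    eval_b <- function(b, xw) {
      r <- .eval_point(eng_j, hp, x0 = xw, offset = zj * b,
                       want_beta_cov = FALSE)
      list(lp = r$log_evidence +
             stats::dnorm(b, 0, control$beta_prior_sd, log = TRUE), x = r$x)
    }
    r <- eval_b(bgrid[centre], x0); lp[centre] <- r$lp; x_centre <- r$x
    xw <- x_centre
    for (i in seq(centre + 1L, np)) {
      r <- eval_b(bgrid[i], xw); lp[i] <- r$lp; xw <- r$x
    }
    xw <- x_centre
    for (i in seq(centre - 1L, 1L)) {
      r <- eval_b(bgrid[i], xw); lp[i] <- r$lp; xw <- r$x
    }
    prof[[ii]] <- list(x = bgrid, lp = lp - max(lp))
  }
  # common grid: span of the profiled abscissae and the Gaussian tails
  lo <- min(vapply(prof, function(pp) pp$x[1], numeric(1)),
            bm[ks_all, j] - 6 * bs[ks_all, j])
  hi <- max(vapply(prof, function(pp) pp$x[length(pp$x)], numeric(1)),
            bm[ks_all, j] + 6 * bs[ks_all, j])
  xg <- seq(lo, hi, length.out = control$marginal_points)
  dens <- numeric(length(xg))
  for (ii in seq_along(ks)) {
    pp <- prof[[ii]]
    # interpolate the log-density (smooth, near-quadratic), then exponentiate
    lp_i <- stats::spline(pp$x, pp$lp, xout = xg)$y
    inside <- xg >= pp$x[1] & xg <= pp$x[length(pp$x)]
    d_i <- ifelse(inside, exp(lp_i), 0)
    d_i <- d_i / trapz(xg, d_i)
    dens <- dens + w[ks[ii]] * d_i
  }
  for (k in setdiff(ks_all, ks))
    dens <- dens + w[k] * stats::dnorm(xg, bm[k, j], bs[k, j])
  dens <- dens / trapz(xg, dens)
  list(x = xg, density = dens)
}

# Gaussian-mixture marginals on a fixed grid per coefficient
.mixture_marginals <- function(w, means, sds, terms, n_grid = 512,
                               half_width = 6) {
  p <- ncol(means)
  out <- vector("list", p); names(out) <- terms
  for (j in seq_len(p)) {
    mu <- sum(w * means[, j])
    v <- sum(w * (sds[, j]^2 + means[, j]^2)) - mu^2
    s <- sqrt(max(v, 1e-300))
    xg <- seq(mu - half_width * s, mu + half_width * s, length.out = n_grid)
    dens <- numeric(n_grid)
    for (k in seq_along(w))
      dens <- dens + w[k] * stats::dnorm(xg, means[k, j], sds[k, j])
    out[[j]] <- list(x = xg, density = dens)
  }
  out
}

# ---- summaries ------------------------------------------------------------

#' Summary statistics of a mixture-of-Gaussians marginal
#'
#' Mean, sd, quantiles (by numerical inversion of the trapezoidal CDF), mode
#' (argmax on the grid) and the credible-interval significance flag for a
#' posterior marginal represented as a weighted Gaussian mixture.
#'
#' @param weights mixture weights (sum to 1).
#' @param means,sds component means and standard deviations.
#' @param n_grid grid resolution (default 512 points over mean +/- 6 sd).
#' @return one-row data.frame: `mean`, `sd`, `q025`, `q500`, `q975`, `mode`,
#'   `significant`.
#' @export
mixture_summary <- function(weights, means, sds, n_grid = 512) {
  marg <- .mixture_marginals(weights, matrix(means, ncol = 1),
                             matrix(sds, ncol = 1), "x", n_grid = n_grid)[[1]]
  .marginal_stats(marg$x, marg$density)
}

.marginal_stats <- function(x, density) {
  z <- trapz(x, density)
  density <- density / z
  mu <- trapz(x, x * density)
  v <- trapz(x, (x - mu)^2 * density)
  dx <- diff(x)
  cdf <- c(0, cumsum(dx * (density[-1] + density[-length(x)]) / 2))
  cdf <- cdf / cdf[length(cdf)]
  qf <- function(pr) {
    i <- findInterval(pr, cdf, all.inside = TRUE)
    x[i] + (pr - cdf[i]) / max(cdf[i + 1] - cdf[i], 1e-300) * (x[i + 1] - x[i])
  }
  q <- vapply(c(0.025, 0.5, 0.975), qf, numeric(1))
  data.frame(mean = mu, sd = sqrt(max(v, 0)), q025 = q[1], q500 = q[2],
             q975 = q[3], mode = x[which.max(density)],
             significant = q[1] > 0 || q[3] < 0)
}

#' Posterior summary table of a model fit
#'
#' One row per coefficient, in the fixed covariate order (intercept first):
#' posterior mean, standard deviation, 2.5/50/97.5% quantiles, mode, and the
#' significance flag (95% credible interval excluding zero).
#'
#' @param object a `wp_fit` from [fit_stmodel()].
#' @param ... unused.
#' @return data.frame of class `wp_summary` with columns `term`, `label`,
#'   `mean`, `sd`, `q025`, `q500`, `q975`, `mode`, `significant`.
#' @export
summary.wp_fit <- function(object, ...) {
  rows <- lapply(seq_along(object$terms), function(j) {
    mg <- object$beta_marginals[[j]]
    cbind(data.frame(term = object$terms[j], label = object$labels[j],
                     stringsAsFactors = FALSE),
          .marginal_stats(mg$x, mg$density))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("wp_summary", "data.frame")
  out
}

#' @rdname summary.wp_fit
#' @param fit a `wp_fit`.
#' @export
posterior_summary <- function(fit) summary(fit)

#' @export
print.wp_fit <- function(x, ...) {
  cat(sprintf("wp_fit: %d x %d panel (%d observed cells), %d hyper grid point(s)\n",
              x$n, x$T, x$n_obs, nrow(x$grid)))
  top <- which.max(x$grid$weight)
  cat(sprintf("  modal hyperparameters: range %.0f m, sigma_xi %.2f, a %.2f, sigma_eps %.2f (weight %.2f)\n",
              x$grid$spatial_range[top], x$grid$sigma_xi[top],
              x$grid$ar_coef[top], x$grid$sigma_eps[top], x$grid$weight[top]))
  print(summary(x))
  invisible(x)
}

#' @export
print.wp_summary <- function(x, digits = 2, ...) {
  df <- as.data.frame(x)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], round, digits)
  print.data.frame(df, row.names = FALSE)
  invisible(x)
}
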
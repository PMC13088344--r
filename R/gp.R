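#' Gaussian-process surrogate state
#'
#' Training set and hyperparameters of the zero-mean Gaussian process with an
#' ARD (automatic relevance determination) Matern 5/2 kernel,
#' \deqn{k(x, x') = \sigma_f^2 \left(1 + \sqrt{5}r + \tfrac{5}{3}r^2\right)
#'   e^{-\sqrt{5} r}, \quad
#'   r^2 = \sum_d (x_d - x'_d)^2 / \ell_d^2,}
#' observed under i.i.d. Gaussian noise with variance `noise_var`.
#'
#' @param X numeric matrix, one evaluated input vector per row.
#' @param y numeric vector of observed objective values, `length(y) == nrow(X)`.
#' @param length_scales positive numeric vector, one per input dimension.
#' @param signal_var kernel signal variance `sigma_f^2`, > 0.
#' @param noise_var observation noise variance `sigma_n^2`, > 0.
#' @return An object of class `surrogate_state`.
#' @export
gp_state <- function(X, y, length_scales, signal_var, noise_var) {
  X <- as.matrix(X)
  stopifnot(nrow(X) == length(y),
            length(length_scales) == ncol(X),
            all(length_scales > 0), signal_var > 0, noise_var > 0)
  structure(list(X = X, y = as.numeric(y),
                 length_scales = as.numeric(length_scales),
                 signal_var = signal_var, noise_var = noise_var),
            class = "surrogate_state")
}

# ARD Matern 5/2 cross-covariance between row sets X1 (m x d) and X2 (p x d).
kernel_matern52 <- function(X1, X2, length_scales, signal_var) {
  X1s <- sweep(as.matrix(X1), 2L, length_scales, "/")
  X2s <- sweep(as.matrix(X2), 2L, length_scales, "/")
  r2 <- outer(rowSums(X1s^2), rep(1, nrow(X2s))) +
    outer(rep(1, nrow(X1s)), rowSums(X2s^2)) -
    2 * tcrossprod(X1s, X2s)
  r <- sqrt(pmax(r2, 0))
  signal_var * (1 + sqrt(5) * r + 5 * r^2 / 3) * exp(-sqrt(5) * r)
}

# Cholesky of K(X,X) + noise_var I, escalating a diagonal jitter when the
# system is numerically singular.
gp_chol <- function(state, jitter = 1e-8) {
  Kxx <- kernel_matern52(state$X, state$X, state$length_scales,
                         state$signal_var)
  n <- nrow(Kxx)
  for (j in c(0, jitter * c(1, 1e2, 1e4))) {
    L <- tryCatch(chol(Kxx + diag(state$noise_var + j, n)),
                  error = function(e) NULL)
    if (!is.null(L)) return(L)
  }
  stop("GP system is singular beyond jitter tolerance")
}

#' Gaussian-process posterior at new points
#'
#' Computes the posterior mean and variance of the latent objective at
#' `x_star` under the zero-mean GP with Matern 5/2 ARD kernel:
#' `mu = k*' (K + sigma_n^2 I)^{-1} y` and
#' `sigma^2 = k(x*, x*) - k*' (K + sigma_n^2 I)^{-1} k*`,
#' solved through a Cholesky factorization with diagonal jitter. Variances
#' are clamped at zero from below.
#'
#' @param state a [gp_state()].
#' @param x_star numeric vector (one point) or matrix (one point per row).
#' @return List with numeric vectors `mu` and `sigma2`.
#' @export
gp_posterior <- function(state, x_star) {
  stopifnot(inherits(state, "surrogate_state"))
  Xs <- if (is.matrix(x_star)) x_star else matrix(x_star, nrow = 1L)
  stopifnot(ncol(Xs) == ncol(state$X))
  L <- gp_chol(state)
  Ks <- kernel_matern52(state$X, Xs, state$length_scales, state$signal_var)
  alpha <- backsolve(L, backsolve(L, state$y, transpose = TRUE))
  mu <- as.numeric(crossprod(Ks, alpha))
  v <- backsolve(L, Ks, transpose = TRUE)
  sigma2 <- pmax(state$signal_var - colSums(v^2), 0)
  list(mu = mu, sigma2 = sigma2)
}

# Log marginal likelihood of the data under the GP.
gp_loglik <- function(state) {
  L <- gp_chol(state)
  alpha <- backsolve(L, backsolve(L, state$y, transpose = TRUE))
  -0.5 * sum(state$y * alpha) - sum(log(diag(L))) -
    0.5 * length(state$y) * log(2 * pi)
}

# Fit (length_scales, signal_var, noise_var) by maximizing the log marginal
# likelihood over log-parameters with multi-start L-BFGS-B. `init` (a
# surrogate_state or NULL) warm-starts the first run; additional seeded
# random starts guard against local optima. y is assumed roughly
# standardized by the caller.
gp_fit_hyper <- function(X, y, init = NULL, n_starts = 3L, seed = 1L,
                         noise_max = 1, ls_max = 10) {
  X <- as.matrix(X)
  d <- ncol(X)
  lower <- c(rep(log(0.02), d), log(1e-4), log(1e-8))
  upper <- c(rep(log(ls_max), d), log(1e2), log(noise_max))
  nll <- function(theta) {
    st <- gp_state(X, y, exp(theta[1:d]), exp(theta[d + 1L]),
                   exp(theta[d + 2L]))
    ll <- tryCatch(gp_loglik(st), error = function(e) -1e10)
    if (!is.finite(ll)) ll <- -1e10
    -ll
  }
  starts <- list()
  if (!is.null(init)) {
    starts[[1L]] <- log(c(init$length_scales, init$signal_var, init$noise_var))
  } else {
    starts[[1L]] <- c(rep(log(0.3), d), log(1), log(1e-3))
  }
  extra <- with_seed(seed, replicate(n_starts, {
    c(stats::runif(d, log(0.05), log(2)),
      stats::runif(1, log(0.1), log(10)),
      stats::runif(1, log(1e-6), log(1e-1)))
  }, simplify = FALSE))
  starts <- c(starts, extra)
  best <- NULL
  for (s in starts) {
    s <- pmin(pmax(s, lower), upper)
    fit <- tryCatch(
      stats::optim(s, nll, method = "L-BFGS-B", lower = lower, upper = upper,
                   control = list(maxit = 60)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value)) best <- fit
  }
  if (is.null(best)) stop("GP hyperparameter optimization failed")
  th <- best$par
  gp_state(X, y, exp(th[1:d]), exp(th[d + 1L]), exp(th[d + 2L]))
}

#' Expected Improvement acquisition value
#'
#' Expected reduction below the incumbent `f_min` under a Gaussian posterior
#' `N(mu, sigma^2)` (minimization):
#' `EI = (f_min - mu) * Phi(z) + sigma * phi(z)` with
#' `z = (f_min - mu) / sigma`, and the deterministic limit
#' `EI = max(f_min - mu, 0)` when `sigma = 0`.
#'
#' @param mu posterior mean(s).
#' @param sigma posterior standard deviation(s), `>= 0`.
#' @param f_min incumbent (smallest posterior-mean objective so far).
#' @return Numeric vector of non-negative EI values.
#' @export
expected_improvement <- function(mu, sigma, f_min) {
  stopifnot(all(sigma >= 0))
  out <- pmax(f_min - mu, 0)
  pos <- sigma > 0
  if (any(pos)) {
    z <- (f_min - mu[pos]) / sigma[pos]
    out[pos] <- (f_min - mu[pos]) * stats::pnorm(z) +
      sigma[pos] * stats::dnorm(z)
  }
  pmax(out, 0)
}
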
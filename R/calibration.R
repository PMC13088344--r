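#' Normalized Euclidean distance between two beats
#'
#' `D_ij = ||P_i - P_j||_2 / n` for two beats already time-normalized to the
#' same length `n`. Note the division is by the length `n` itself (not by
#' `sqrt(n)` as in an RMS distance).
#'
#' @param p_i,p_j numeric vectors of equal length `n`.
#' @return Scalar distance.
#' @export
normalized_distance <- function(p_i, p_j) {
  if (length(p_i) != length(p_j)) stop("beats must have the same length")
  sqrt(sum((p_i - p_j)^2)) / length(p_i)
}

#' Inter-beat similarity objective
#'
#' The calibration objective: a seeded random subsample `S` of `m` beats
#' (without replacement) is compared against all `N` beats, and the mean
#' normalized Euclidean distance
#' \deqn{f = \frac{1}{mN}\sum_{i \in S}\sum_{j=1}^{N} D_{ij}}
#' is returned. Smaller values mean the beats are more mutually similar,
#' i.e. less corrupted by residual motion artifact. `m` defaults to 20 and
#' falls back to `N` when fewer beats are available; with `m = N` the value
#' equals the full double-sum mean over all beat pairs.
#'
#' @param beats a [beat_set()].
#' @param m subsample size (default 20, capped at `N`).
#' @param seed integer seed for the subsample.
#' @return Scalar objective value.
#' @export
beat_objective <- function(beats, m = 20L, seed = 1L) {
  stopifnot(inherits(beats, "beat_set"))
  if (beats$empty || beats$N < 2L) {
    stop("insufficient calibration beats (need at least 2)")
  }
  N <- beats$N
  m <- min(m, N)
  S <- with_seed(seed, sample.int(N, m))
  B <- beats$beats
  total <- 0
  for (i in S) {
    diff_i <- B - matrix(B[i, ], N, beats$n, byrow = TRUE)
    total <- total + sum(sqrt(rowSums(diff_i^2)))
  }
  total / beats$n / (m * N)
}

#' Search space for the artifact-model parameters
#'
#' Box bounds for `x = (K, zeta, omega_n)`. The default gain ceiling `K_max`
#' should keep the degenerate over-subtraction regime out of reach; see
#' [default_search_space()].
#'
#' @param K_max upper bound on the gain `K`.
#' @param zeta_range damping-ratio bounds (default `[0.05, 1.5]`).
#' @param f_n_range natural-frequency bounds in Hz (default `[1, 30]`;
#'   converted internally to rad/s).
#' @return An object of class `search_space`: a `3 x 2` matrix of bounds with
#'   rows `K`, `zeta`, `omega_n`.
#' @export
search_space <- function(K_max, zeta_range = c(0.05, 1.5),
                         f_n_range = c(1, 30)) {
  stopifnot(K_max > 0, zeta_range[1L] < zeta_range[2L],
            f_n_range[1L] < f_n_range[2L])
  bounds <- rbind(K = c(0, K_max), zeta = zeta_range,
                  omega_n = 2 * pi * f_n_range)
  colnames(bounds) <- c("lower", "upper")
  structure(bounds, class = c("search_space", "matrix"))
}

#' Default search space derived from a calibration stream
#'
#' `K_max` is set to 3 times the ratio of the raw hot-film RMS (about its
#' mean) to the reference-acceleration RMS, which bounds the artifact gain by
#' a multiple of the largest gain that could be supported by the data.
#'
#' @param stream a `sensor_stream`.
#' @return A [search_space()].
#' @export
default_search_space <- function(stream) {
  a <- reference_acceleration(stream$acc)
  k_max <- 3 * stats::sd(stream$hf) / stats::sd(a)
  search_space(K_max = k_max)
}

#' Evaluate one candidate parameter vector on a calibration stream
#'
#' Pipeline: reference acceleration -> artifact reconstruction with the
#' candidate parameters -> band-pass of the artifact-subtracted hot-film
#' channel -> beat segmentation -> inter-beat similarity objective.
#' Deterministic given `(stream, x, cfg$obj_seed)`.
#'
#' @param stream a `sensor_stream` holding the calibration recording
#'   (2-minute natural running).
#' @param x numeric vector `(K, zeta, omega_n)`.
#' @param cfg list: `band` (default `c(0.5, 5)` Hz), `beat_n` (default 100),
#'   `m` (default 20), `obj_seed` (default 1).
#' @return Scalar objective value; errors if no beats are detectable.
#' @export
evaluate_candidate <- function(stream, x, cfg = list()) {
  cfg <- utils::modifyList(
    list(band = c(0.5, 5), beat_n = 100L, m = 20L, obj_seed = 1L), cfg)
  aref <- reference_acceleration(stream$acc)
  evaluate_candidate_impl(stream$hf, aref, stream$fs, x, cfg)
}

# Internal fast path reused by the BO loop (hf and aref precomputed).
evaluate_candidate_impl <- function(hf, aref, fs, x, cfg) {
  params <- artifact_params(K = x[1L], zeta = x[2L], omega_n = x[3L], fs = fs)
  ma <- simulate_artifact(aref, params)
  # Subtract before filtering: by linearity this equals
  # bandpass(hf) - bandpass(MA), keeping the subtraction coherent in band.
  pw <- bandpass_pulse(hf - ma, fs, cfg$band[1L], cfg$band[2L])
  beats <- segment_beats(pw, fs, n = cfg$beat_n)
  beat_objective(beats, m = cfg$m, seed = cfg$obj_seed)
}

#' Recognize artifact-model parameters by Bayesian optimization
#'
#' Minimizes the inter-beat similarity objective over the `(K, zeta,
#' omega_n)` search space with a Gaussian-process surrogate (ARD Matern 5/2
#' kernel, hyperparameters refit by marginal likelihood each iteration) and
#' the Expected Improvement acquisition. The loop starts from 8 seeded
#' space-filling evaluations, then repeatedly maximizes EI (seeded random
#' multi-start with local refinement), evaluates the chosen candidate and
#' appends it, stopping after `max_iters` acquisitions or when the maximal EI
#' drops below `ei_tol`. The returned parameters are the evaluated point with
#' the smallest GP posterior mean (not the smallest raw observation, which is
#' noisier).
#'
#' Candidates whose filtered stream has no detectable beats are assigned a
#' penalty of three times the raw-stream objective, so the surrogate steers
#' away from degenerate filters without aborting the run.
#'
#' @param stream calibration `sensor_stream` (at least ~2 minutes of natural
#'   running).
#' @param space a [search_space()]; default derived by
#'   [default_search_space()].
#' @param cfg list: `n_init` (default 8), `max_iters` (default 40), `ei_tol`
#'   (default 1e-9, in standardized objective units), `seed` (default 1),
#'   plus the [evaluate_candidate()] settings `band`, `beat_n`, `m`,
#'   `obj_seed`.
#' @return An object of class `calibration_result`: list with `params` (the
#'   recognized [artifact_params()]), `X` (evaluated parameter vectors), `y`
#'   (objective values), `mu` (final posterior means at `X`), `best_index`,
#'   `f_raw` (objective of the unfiltered stream) and `trace` (data frame
#'   with per-evaluation bookkeeping).
#' @export
calibrate_artifact <- function(stream, space = NULL, cfg = list()) {
  cfg <- utils::modifyList(
    list(n_init = 8L, max_iters = 40L, ei_tol = 1e-9, seed = 1L,
         band = c(0.5, 5), beat_n = 100L, m = 20L, obj_seed = 1L), cfg)
  if (is.null(space)) space <- default_search_space(stream)
  lb <- space[, 1L]
  ub <- space[, 2L]
  # omega_n is searched on a log scale (a frequency spanning a decade and a
  # half); K and zeta stay linear. The GP sees the unit cube of this map.
  unit_to_x <- function(u) {
    c(lb[1L] + u[1L] * (ub[1L] - lb[1L]),
      lb[2L] + u[2L] * (ub[2L] - lb[2L]),
      exp(log(lb[3L]) + u[3L] * (log(ub[3L]) - log(lb[3L]))))
  }
  # The surrogate sees (K/(2*zeta), zeta, log omega_n) rather than raw
  # (K, zeta, omega_n): near resonance the response scales with K/(2*zeta),
  # so equal-objective contours run along lines of constant resonance gain.
  # In this feature space those contours are axis-aligned and the ARD kernel
  # can follow them; in raw coordinates they are diagonal and it cannot.
  feat_of_u <- function(u) {
    x <- unit_to_x(u)
    # gains live on a log scale; the additive floor keeps K = 0 finite
    c(log(x[1L] / (2 * x[2L]) + 0.05 * ub[1L]), u[2L], u[3L])
  }
  fs <- stream$fs
  if (length(stream$hf) < 90 * fs) {
    warning("calibration stream is shorter than ~2 minutes; recovery may degrade")
  }
  aref <- reference_acceleration(stream$acc)
  hf <- stream$hf

  f_raw <- tryCatch(
    evaluate_candidate_impl(hf, aref, fs, c(0, 0.7, 2 * pi * 5), cfg),
    error = function(e) NA_real_)
  if (!is.finite(f_raw)) {
    stop("calibration error: no detectable beats in the raw calibration stream")
  }
  penalty <- 3 * f_raw

  eval_unit <- function(u) {
    x <- unit_to_x(u)
    x[1L] <- max(x[1L], 0)
    val <- tryCatch(evaluate_candidate_impl(hf, aref, fs, x, cfg),
                    error = function(e) NA_real_)
    if (!is.finite(val)) val <- penalty
    list(x = x, y = val)
  }

  # 8 seeded space-filling initial points (Latin hypercube in the unit cube)
  U <- with_seed(seed_child(cfg$seed, 1L), lhs::randomLHS(cfg$n_init, 3L))
  X <- matrix(NA_real_, 0L, 3L, dimnames = list(NULL, c("K", "zeta", "omega_n")))
  Uall <- matrix(NA_real_, 0L, 3L)
  Fall <- matrix(NA_real_, 0L, 3L)
  y <- numeric(0)
  for (i in seq_len(cfg$n_init)) {
    r <- eval_unit(U[i, ])
    X <- rbind(X, r$x); Uall <- rbind(Uall, U[i, ])
    Fall <- rbind(Fall, feat_of_u(U[i, ])); y <- c(y, r$y)
  }
  if (all(y >= penalty)) stop("calibration error: all initial evaluations failed")

  # The surrogate models the standardized log-objective: the objective is
  # positive with a dynamic range of ~2 decades, and the log warp keeps the
  # plateau of poor candidates from inflating the GP signal variance (which
  # would starve exploitation). The warp is monotone, so the minimizer is
  # unchanged.
  warp <- function(v) log(pmax(v, 1e-12))
  n_cand <- 64L
  state <- NULL
  ei_trace <- rep(NA_real_, cfg$n_init)
  for (it in seq_len(cfg$max_iters)) {
    yl <- warp(y)
    mu_y <- mean(yl); sd_y <- stats::sd(yl)
    if (!is.finite(sd_y) || sd_y < 1e-12) sd_y <- 1
    ys <- (yl - mu_y) / sd_y
    state <- gp_fit_hyper(Fall, ys, init = state,
                          seed = seed_child(cfg$seed, 100L + it),
                          ls_max = 0.7)
    post_X <- gp_posterior(state, Fall)
    f_min <- min(post_X$mu)

    # EI inner maximization: seeded random multi-start + local refinement;
    # a quarter of the starts perturb the incumbent so exploitation always
    # has a foothold
    ord_mu <- order(post_X$mu)
    inc <- Uall[ord_mu[1L], ]
    x_inc <- unit_to_x(inc)
    g_inc <- x_inc[1L] / (2 * x_inc[2L])
    cand <- with_seed(seed_child(cfg$seed, 200L + it), {
      rand <- matrix(stats::runif(32L * 3L), 32L, 3L)
      local <- rbind(
        matrix(rep(inc, each = 8L) + stats::rnorm(8L * 3L, sd = 0.02), 8L, 3L),
        matrix(rep(inc, each = 8L) + stats::rnorm(8L * 3L, sd = 0.07), 8L, 3L),
        matrix(rep(inc, each = 8L) + stats::rnorm(8L * 3L, sd = 0.2), 8L, 3L))
      # sweep the constant-resonance-gain line through the incumbent: vary
      # zeta over its range with K = 2 * g_inc * zeta, omega_n near incumbent
      z_sw <- stats::runif(8L, 0, 1)
      k_sw <- 2 * g_inc * (lb[2L] + z_sw * (ub[2L] - lb[2L])) /
        (ub[1L] - lb[1L])
      sweep_c <- cbind(k_sw, z_sw, inc[3L] + stats::rnorm(8L, sd = 0.02))
      pmin(pmax(rbind(rand, local, sweep_c), 0), 1)
    })
    p <- gp_posterior(state, t(apply(cand, 1L, feat_of_u)))
    ei <- expected_improvement(p$mu, sqrt(p$sigma2), f_min)
    neg_ei <- function(u) {
      pp <- gp_posterior(state, matrix(feat_of_u(u), 1L))
      -expected_improvement(pp$mu, sqrt(pp$sigma2), f_min)
    }
    top <- order(ei, decreasing = TRUE)[1:5]
    best_u <- cand[top[1L], ]
    best_ei <- ei[top[1L]]
    for (s in top) {
      fit <- tryCatch(
        stats::optim(cand[s, ], neg_ei, method = "L-BFGS-B",
                     lower = rep(0, 3), upper = rep(1, 3),
                     control = list(maxit = 80)),
        error = function(e) NULL)
      if (!is.null(fit) && -fit$value > best_ei) {
        best_ei <- -fit$value
        best_u <- fit$par
      }
    }
    ei_trace <- c(ei_trace, best_ei)
    if (best_ei < cfg$ei_tol) break
    r <- eval_unit(best_u)
    X <- rbind(X, r$x); Uall <- rbind(Uall, best_u)
    Fall <- rbind(Fall, feat_of_u(best_u)); y <- c(y, r$y)
  }

  yl <- warp(y)
  mu_y <- mean(yl); sd_y <- stats::sd(yl)
  if (!is.finite(sd_y) || sd_y < 1e-12) sd_y <- 1
  ys <- (yl - mu_y) / sd_y
  state <- gp_fit_hyper(Fall, ys, init = state,
                        seed = seed_child(cfg$seed, 999L))
  mu_final <- exp(gp_posterior(state, Fall)$mu * sd_y + mu_y)
  best <- which.min(mu_final)
  params <- artifact_params(K = X[best, 1L], zeta = X[best, 2L],
                            omega_n = X[best, 3L], fs = fs)
  structure(list(
    params = params,
    X = X, y = y, mu = mu_final, best_index = best, f_raw = f_raw,
    trace = data.frame(eval = seq_along(y), K = X[, 1L], zeta = X[, 2L],
                       omega_n = X[, 3L], y = y,
                       best_so_far = cummin(y),
                       ei = ei_trace[seq_along(y)])
  ), class = "calibration_result")
}

#' @export
print.calibration_result <- function(x, ...) {
  cat(sprintf("calibration_result: %d evaluations, raw objective %.5g -> best %.5g\n",
              length(x$y), x$f_raw, min(x$y)))
  print(x$params)
  invisible(x)
}

#' Write a calibration report to JSON
#'
#' Records every evaluated parameter vector, the objective trace and the
#' chosen parameters.
#'
#' @param result a `calibration_result`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_calibration_report <- function(result, path) {
  stopifnot(inherits(result, "calibration_result"))
  jsonlite::write_json(list(
    params = list(K = result$params$K, zeta = result$params$zeta,
                  omega_n = result$params$omega_n, fs = result$params$fs),
    f_raw = result$f_raw,
    trace = result$trace
  ), path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}
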
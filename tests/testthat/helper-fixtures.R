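# Shared fixtures: ground-truth artifact parameters used across tests (the
# simulator's frozen study conditions) and small stream builders.

true_params <- function(fs = 100) artifact_params(0.25, 0.7, 2 * pi * 3, fs)

# Short steady-running stream (single segment, constant intensity).
steady_stream <- function(duration = 60, intensity = 0.9, seed = 6,
                          params = true_params(), noise = list()) {
  proto <- exercise_protocol(data.frame(label = "run", duration = duration,
                                        intensity = intensity))
  synth_session(proto, params, noise_cfg = noise, seed = seed)
}

# Random normalized beat set for objective / distance tests.
random_beats <- function(N, n = 100, seed = 1) {
  with_seed(seed, {
    beats <- matrix(stats::rnorm(N * n), N, n)
    beat_set(beats, onsets = cumsum(c(1L, sample(60:110, N))), n = n)
  })
}

# Dense-solve GP posterior oracle (direct matrix inversion of the posterior
# equations), independent of the Cholesky path used by gp_posterior().
gp_posterior_oracle <- function(state, x_star) {
  Xs <- if (is.matrix(x_star)) x_star else matrix(x_star, nrow = 1L)
  Kxx <- thermopulse:::kernel_matern52(state$X, state$X,
                                       state$length_scales, state$signal_var)
  Ks <- thermopulse:::kernel_matern52(state$X, Xs,
                                      state$length_scales, state$signal_var)
  A <- solve(Kxx + diag(state$noise_var, nrow(Kxx)))
  mu <- as.numeric(crossprod(Ks, A %*% state$y))
  sigma2 <- state$signal_var - diag(crossprod(Ks, A %*% Ks))
  list(mu = mu, sigma2 = pmax(sigma2, 0))
}

random_gp_state <- function(t, d = 3, seed = 1) {
  with_seed(seed, {
    gp_state(X = matrix(stats::runif(t * d), t, d),
             y = stats::rnorm(t),
             length_scales = stats::runif(d, 0.1, 2),
             signal_var = stats::runif(1, 0.2, 5),
             noise_var = stats::runif(1, 1e-6, 0.1))
  })
}
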
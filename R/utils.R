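#' Root-mean-square of a numeric vector
#'
#' @param x numeric vector.
#' @return `sqrt(mean(x^2))`.
#' @export
rms <- function(x) sqrt(mean(x^2))

#' Evaluate an expression with a temporary RNG seed
#'
#' Sets the seed, evaluates `code`, and restores the caller's RNG state so
#' that package functions taking an explicit `seed` argument behave as pure
#' functions of their inputs.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1L)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  code
}

# Deterministic child seed derivation; keeps results < 2^31 so they remain
# valid R integer seeds.
seed_child <- function(seed, k) {
  as.integer((as.numeric(seed) * 48271 + 7919 * as.numeric(k)) %% 2147483647)
}

# Band-limited unit-variance noise: white Gaussian noise low-passed at
# `cutoff` Hz and rescaled to sd 1. Used for slow envelopes and wander.
slow_noise <- function(n, fs, cutoff, seed) {
  w <- with_seed(seed, stats::rnorm(n + 4L * fs))
  bf <- signal::butter(2, min(cutoff / (fs / 2), 0.99), type = "low")
  x <- as.numeric(signal::filter(bf, w))
  x <- x[-seq_len(4L * fs)] # drop filter warm-up
  s <- stats::sd(x)
  if (s < .Machine$double.eps) return(numeric(n))
  x / s
}

# First-order relaxation of a set-point trajectory: dx/dt = (target - x)/tau.
relax_towards <- function(target, tau, fs, init = target[1L]) {
  alpha <- 1 / (tau * fs)
  x <- numeric(length(target))
  cur <- init
  for (i in seq_along(target)) {
    cur <- cur + alpha * (target[i] - cur)
    x[i] <- cur
  }
  x
}

`%||%` <- function(a, b) if (is.null(a)) b else a
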
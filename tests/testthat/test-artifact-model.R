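test_that("parameter validation enforces the model invariants", {
  expect_s3_class(artifact_params(0.3, 0.5, 2 * pi * 4), "artifact_params")
  expect_error(artifact_params(-0.1, 0.5, 10), "K")
  expect_error(artifact_params(0.3, 0, 10))
  expect_error(artifact_params(0.3, -0.2, 10))
  expect_error(artifact_params(0.3, 0.5, 2 * pi * 60), "Nyquist")
})

test_that("bilinear discretization is stable and preserves DC gain", {
  grid <- expand.grid(K = c(0.1, 1, 3), zeta = c(0.2, 0.7, 1.3),
                      f_n = c(1, 5, 20))
  for (i in seq_len(nrow(grid))) {
    filt <- discretize(artifact_params(grid$K[i], grid$zeta[i],
                                       2 * pi * grid$f_n[i]))
    expect_true(all(Mod(polyroot(rev(filt$a))) < 1))
    expect_equal(sum(filt$b) / sum(filt$a), grid$K[i], tolerance = 1e-9)
  }
})

test_that("discrete frequency response matches the continuous model well below Nyquist", {
  fs <- 100
  K <- 1.4; zeta <- 0.5
  h_cont <- function(w, wn) K * wn^2 / ((1i * w)^2 + 2 * zeta * wn * (1i * w) + wn^2)
  h_disc <- function(filt, w) {
    z <- exp(1i * w / fs)
    sum(filt$b * z^(-(seq_along(filt$b) - 1))) /
      sum(filt$a * z^(-(seq_along(filt$a) - 1)))
  }
  for (f_n in c(1, 3, 8)) {
    wn <- 2 * pi * f_n
    filt <- discretize(artifact_params(K, zeta, wn, fs))
    for (f in c(0.5 * f_n, f_n, 1.5 * f_n)) {
      w <- 2 * pi * f
      # exact bilinear identity: discrete response equals the continuous
      # response at the tan-warped frequency
      w_warp <- 2 * fs * tan(w / (2 * fs))
      expect_equal(Mod(h_disc(filt, w)), Mod(h_cont(w_warp, wn)),
                   tolerance = 1e-9)
    }
    # warping is negligible deep below Nyquist: the unwarped continuous
    # value at resonance agrees within 2% for f_n well under fs / 10
    if (f_n <= 3) {
      expect_equal(Mod(h_disc(filt, wn)), Mod(h_cont(wn, wn)),
                   tolerance = 0.02)
    }
  }
})

test_that("artifact simulation is causal, linear, and has the right statics", {
  params <- artifact_params(1.5, 0.5, 2 * pi * 4)
  n <- 2000
  expect_equal(simulate_artifact(numeric(n), params), numeric(n))
  # constant input reaches K * a
  y <- simulate_artifact(rep(2, 5000), params)
  expect_equal(tail(y, 1), 1.5 * 2, tolerance = 1e-6)
  # linearity to machine precision
  x1 <- with_seed(1, rnorm(n))
  x2 <- with_seed(2, rnorm(n))
  lhs_resp <- simulate_artifact(3 * x1 - 0.5 * x2, params)
  rhs_resp <- 3 * simulate_artifact(x1, params) - 0.5 * simulate_artifact(x2, params)
  expect_equal(lhs_resp, rhs_resp, tolerance = 1e-12)
})

test_that("discretized response matches an RK4 integration of the underlying ODE", {
  fs <- 100
  K <- 0.8; zeta <- 0.6; wn <- 2 * pi * 3
  params <- artifact_params(K, zeta, wn, fs)
  dur <- 5
  t_fine <- seq(0, dur, by = 1 / (100 * fs)) # 100x oversampling
  # band-limited input: sinusoids within the pulse band
  a_of_t <- function(t) sin(2 * pi * 1.3 * t) + 0.5 * sin(2 * pi * 2.8 * t + 1)
  h <- 1 / (100 * fs)
  state <- c(0, 0) # x, xdot
  deriv <- function(s, a) c(s[2], K * wn^2 * a - 2 * zeta * wn * s[2] - wn^2 * s[1])
  x_fine <- numeric(length(t_fine))
  for (i in seq_along(t_fine)[-1]) {
    tm <- t_fine[i - 1]
    k1 <- deriv(state, a_of_t(tm))
    k2 <- deriv(state + h / 2 * k1, a_of_t(tm + h / 2))
    k3 <- deriv(state + h / 2 * k2, a_of_t(tm + h / 2))
    k4 <- deriv(state + h * k3, a_of_t(tm + h))
    state <- state + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    x_fine[i] <- state[1]
  }
  t_coarse <- seq(0, dur, by = 1 / fs)
  ma <- simulate_artifact(a_of_t(t_coarse), params)
  ref <- x_fine[match(round(t_coarse, 10), round(t_fine, 10))]
  expect_lt(rms(ma - ref) / rms(ref), 0.005)
})

test_that("artifact parameters round-trip through JSON", {
  p <- artifact_params(0.731, 0.456, 2 * pi * 3.21)
  path <- tempfile(fileext = ".json")
  write_artifact_params(p, path)
  q <- read_artifact_params(path)
  expect_equal(unclass(q), unclass(p))
})
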
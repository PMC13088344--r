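test_that("normalized Euclidean distance divides by the beat length", {
  expect_equal(normalized_distance(1:5, 1:5), 0)
  expect_equal(normalized_distance(c(0, 0, 0, 0), c(1, 1, 1, 1)), 0.5)
  a <- with_seed(1, rnorm(100)); b <- with_seed(2, rnorm(100))
  expect_equal(normalized_distance(a, b), normalized_distance(b, a))
  expect_equal(normalized_distance(a, b), sqrt(sum((a - b)^2)) / 100)
  expect_error(normalized_distance(1:4, 1:5), "length")
})

test_that("similarity objective matches enumeration and brute force", {
  # identical beats: zero
  bs_same <- beat_set(matrix(1, 4, 10), onsets = c(1L, 11L, 21L, 31L, 41L), n = 10)
  expect_equal(beat_objective(bs_same, seed = 1), 0)
  # N = 2, both selected: (0 + D + D + 0) / 4 = D / 2
  bs2 <- random_beats(2, n = 50, seed = 7)
  d_uv <- normalized_distance(bs2$beats[1, ], bs2$beats[2, ])
  expect_equal(beat_objective(bs2, m = 2, seed = 1), d_uv / 2)
  # m = N equals the full double-sum mean (independent double-loop oracle)
  for (N in c(3, 17, 50)) {
    bs <- random_beats(N, n = 40, seed = N)
    oracle <- 0
    for (i in seq_len(N)) for (j in seq_len(N)) {
      oracle <- oracle + normalized_distance(bs$beats[i, ], bs$beats[j, ])
    }
    expect_equal(beat_objective(bs, m = N, seed = 1), oracle / N^2,
                 tolerance = 1e-12)
  }
  expect_error(beat_objective(random_beats(1, seed = 1)), "insufficient")
})

test_that("objective is invariant under beat reordering and common time shift", {
  bs <- random_beats(12, n = 30, seed = 4)
  f0 <- beat_objective(bs, m = 12, seed = 1)
  perm <- with_seed(9, sample(12))
  bs_p <- beat_set(bs$beats[perm, ], onsets = bs$onsets, n = 30)
  expect_equal(beat_objective(bs_p, m = 12, seed = 1), f0, tolerance = 1e-12)
  bs_s <- beat_set(bs$beats, onsets = bs$onsets + 500L, n = 30)
  expect_equal(beat_objective(bs_s, m = 12, seed = 1), f0)
})

test_that("GP posterior interpolates, reverts to the prior, and handles variance bounds", {
  # near-noiseless GP reproduces a training observation
  st <- random_gp_state(6, seed = 2)
  st$noise_var <- 1e-12
  p <- gp_posterior(st, st$X[3, ])
  expect_equal(p$mu, st$y[3], tolerance = 1e-4)
  expect_lt(p$sigma2, 1e-6)
  # far from all data: zero prior mean, prior variance
  far <- matrix(rep(100, ncol(st$X)), 1)
  pf <- gp_posterior(st, far)
  expect_equal(pf$mu, 0, tolerance = 1e-8)
  expect_equal(pf$sigma2, st$signal_var, tolerance = 1e-8)
  # variances never negative
  st2 <- random_gp_state(10, seed = 5)
  ps <- gp_posterior(st2, st2$X)
  expect_true(all(ps$sigma2 >= 0))
})

test_that("expected improvement matches its closed-form limits", {
  expect_equal(expected_improvement(0.5, 0, f_min = 1), 0.5)
  expect_equal(expected_improvement(1.5, 0, f_min = 1), 0)
  expect_equal(expected_improvement(1, 1, f_min = 1), 1 / sqrt(2 * pi),
               tolerance = 1e-12)
  mu <- with_seed(3, rnorm(50)); sg <- with_seed(4, runif(50))
  expect_true(all(expected_improvement(mu, sg, 0) >= 0))
})

test_that("candidate evaluation is deterministic and identity at K = 0", {
  st <- steady_stream(duration = 40, seed = 11,
                      params = artifact_params(1e-9, 0.7, 2 * pi * 3))
  f1 <- evaluate_candidate(st, c(0, 0.7, 2 * pi * 5))
  f2 <- evaluate_candidate(st, c(0, 0.3, 2 * pi * 12))
  expect_identical(f1, f2) # K = 0 ignores the rest of the vector
  # raw objective equals the K = 0 objective on an artifact-free stream
  pw <- bandpass_pulse(st$hf, st$fs)
  f_raw <- beat_objective(segment_beats(pw, st$fs), seed = 1)
  expect_equal(f1, f_raw)
  expect_identical(evaluate_candidate(st, c(0.2, 0.5, 20)),
                   evaluate_candidate(st, c(0.2, 0.5, 20)))
})

test_that("objective is locally minimal at the generating parameters on clean data", {
  proto <- exercise_protocol(data.frame(label = "run", duration = 60,
                                        intensity = 0.9))
  st <- synth_session(proto, true_params(),
                      noise_cfg = list(hf_sd = 0, cf_sd = 0,
                                       baseline_wander_sd = 0), seed = 12)
  x0 <- c(0.25, 0.7, 2 * pi * 3)
  f0 <- evaluate_candidate(st, x0)
  for (d in 1:3) for (s in c(0.8, 1.2)) {
    x <- x0; x[d] <- x[d] * s
    expect_gt(evaluate_candidate(st, x), f0)
  }
})

test_that("calibration is seed-deterministic with monotone incumbent trace", {
  st <- steady_stream(duration = 45, seed = 13)
  cfg <- list(seed = 7, n_init = 4L, max_iters = 4L)
  r1 <- suppressWarnings(calibrate_artifact(st, cfg = cfg)) # short-stream warning
  r2 <- suppressWarnings(calibrate_artifact(st, cfg = cfg))
  expect_identical(unclass(r1$params), unclass(r2$params))
  expect_identical(r1$y, r2$y)
  expect_true(all(diff(r1$trace$best_so_far) <= 0))
})

test_that("calibration on an artifact-free running stream drives K to zero", {
  st0 <- synth_session(calibration_protocol(),
                       artifact_params(0, 0.7, 2 * pi * 3), seed = 5)
  res <- calibrate_artifact(st0, cfg = list(seed = 5, max_iters = 10L))
  k_max <- default_search_space(st0)["K", "upper"]
  expect_lt(res$params$K, 0.05 * k_max)
})
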
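test_that("pulse train tracks the requested heart rate", {
  # constant 60 BPM for 10 s: exactly 10 beat onsets
  pt <- synth_pulse_train(rep(60, 1000), fs = 100, seed = 1)
  expect_equal(length(pt$onsets), 10L)
  # constant 72 BPM: dominant spectral line at 1.2 Hz
  pt72 <- synth_pulse_train(rep(72, 6000), fs = 100, seed = 1, envelope_sd = 0)
  spec <- Mod(stats::fft(pt72$x - mean(pt72$x)))[1:3000]
  expect_equal((which.max(spec) - 1) * 100 / 6000, 1.2, tolerance = 1e-6)
  # reproducibility and rejection of invalid input
  expect_identical(synth_pulse_train(rep(70, 500), seed = 3)$x,
                   synth_pulse_train(rep(70, 500), seed = 3)$x)
  expect_error(synth_pulse_train(c(rep(70, 10), NA)), "finite")
  expect_error(synth_pulse_train(rep(250, 100)), "40, 220")
})

test_that("gait acceleration has gravity at rest and cadence lines when running", {
  rest <- exercise_protocol(data.frame(label = "rest", duration = 30, intensity = 0))
  acc_r <- synth_gait_accel(rest, seed = 1)
  expect_equal(mean(sqrt(rowSums(acc_r^2))), 9.80665, tolerance = 0.02)
  run <- exercise_protocol(data.frame(label = "run", duration = 60, intensity = 0.9))
  acc <- synth_gait_accel(run, seed = 1)
  aref <- reference_acceleration(acc)
  sel <- 2001:6000 # past the intensity ramp
  spec <- Mod(stats::fft(aref[sel] - mean(aref[sel])))[1:2000]
  f_peak <- (which.max(spec) - 1) * 100 / length(sel)
  cadence <- 1.6 + 1.4 * 0.9
  expect_equal(f_peak, cadence, tolerance = 0.15 * cadence)
  # different seeds: different waveforms, similar total power
  acc2 <- synth_gait_accel(run, seed = 2)
  expect_false(isTRUE(all.equal(acc, acc2)))
  expect_equal(sd(reference_acceleration(acc2)[sel]), sd(aref[sel]),
               tolerance = 0.2)
})

test_that("session construction conserves its components exactly", {
  proto <- exercise_protocol(data.frame(label = c("rest", "run"),
                                        duration = c(20, 40),
                                        intensity = c(0, 0.8)))
  st <- synth_session(proto, true_params(),
                      noise_cfg = list(hf_sd = 0, cf_sd = 0,
                                       baseline_wander_sd = 0), seed = 2)
  recon <- st$truth$clean_pulse + st$truth$baseline + st$truth$artifact
  expect_equal(st$hf, recon, tolerance = 1e-14)
  # zero artifact gain: hf - baseline equals the clean pulse exactly
  st0 <- synth_session(proto, artifact_params(0, 0.7, 2 * pi * 3),
                       noise_cfg = list(hf_sd = 0, cf_sd = 0,
                                        baseline_wander_sd = 0), seed = 2)
  expect_equal(st0$hf - st0$truth$baseline, st0$truth$clean_pulse,
               tolerance = 1e-12)
})

test_that("simulator artifact channel is the artifact model applied to the reference acceleration", {
  st <- steady_stream(duration = 30, seed = 9)
  expect_equal(st$truth$artifact,
               simulate_artifact(reference_acceleration(st$acc), true_params()),
               tolerance = 1e-14)
})

test_that("stream length is segment-duration arithmetic and generators are seed-pure", {
  st <- synth_session(default_protocol(300), true_params(), seed = 1)
  expect_equal(length(st$hf), 180000L) # six 5-minute segments at 100 Hz
  st_a <- steady_stream(duration = 20, seed = 4)
  st_b <- steady_stream(duration = 20, seed = 4)
  expect_identical(st_a$hf, st_b$hf)
  expect_identical(st_a$acc, st_b$acc)
  expect_error(synth_session(default_protocol(10), true_params(),
                             noise_cfg = list(hf_sd = -1)), ">= 0")
})
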
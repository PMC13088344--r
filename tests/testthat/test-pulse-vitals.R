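test_that("artifact removal recovers the band-passed clean pulse at the true parameters", {
  proto <- exercise_protocol(data.frame(label = "run", duration = 60,
                                        intensity = 0.9))
  st <- synth_session(proto, true_params(),
                      noise_cfg = list(hf_sd = 0, cf_sd = 0,
                                       baseline_wander_sd = 0), seed = 6)
  pw <- remove_artifact(st$hf, st$acc, true_params())
  clean_bp <- bandpass_pulse(st$truth$clean_pulse, st$fs)
  sel <- 501:length(pw) # skip filter warm-up
  expect_lt(rms(pw[sel] - clean_bp[sel]) / rms(clean_bp[sel]), 0.01)
})

test_that("artifact removal is the identity band-pass when K = 0 or the device is still", {
  st <- steady_stream(duration = 20, seed = 7)
  pw0 <- remove_artifact(st$hf, st$acc, artifact_params(0, 0.7, 2 * pi * 3))
  expect_equal(pw0, bandpass_pulse(st$hf, st$fs), tolerance = 1e-12)
  # stationary device: reference acceleration is ~0, MA decays to nothing
  n <- 3000
  acc_still <- cbind(numeric(n), numeric(n), rep(9.80665, n))
  hf <- with_seed(1, rnorm(n))
  pw_still <- remove_artifact(hf, acc_still, true_params())
  expect_equal(pw_still, bandpass_pulse(hf, 100), tolerance = 1e-10)
  expect_error(remove_artifact(hf[-1], acc_still, true_params()), "length")
})

test_that("artifact removal is linear in the hot-film channel", {
  st <- steady_stream(duration = 15, seed = 8)
  h1 <- with_seed(1, rnorm(length(st$hf)))
  h2 <- with_seed(2, rnorm(length(st$hf)))
  p <- true_params()
  lhs_pw <- remove_artifact(2 * h1 + 3 * h2, st$acc, p)
  rhs_pw <- 2 * remove_artifact(h1, st$acc, p) +
    3 * remove_artifact(h2, st$acc, p) -
    # MA is subtracted in each call; keep a single subtraction overall
    4 * bandpass_pulse(-simulate_artifact(reference_acceleration(st$acc), p), 100)
  expect_equal(lhs_pw, rhs_pw, tolerance = 1e-6)
})

test_that("FFT heart rate hits synthetic frequencies and flags flat spectra", {
  t <- (0:999) / 100
  hr <- heart_rate_fft(sin(2 * pi * 1.2 * t), 100)
  expect_equal(as.numeric(hr), 72, tolerance = 0.5)
  expect_identical(attr(hr, "flag"), "ok")
  expect_equal(as.numeric(heart_rate_fft(sin(2 * pi * 1.0 * t), 100)), 60,
               tolerance = 0.1)
  flat <- heart_rate_fft(rep(1, 1000), 100)
  expect_true(is.na(flat))
  expect_identical(attr(flat, "flag"), "invalid")
  expect_error(heart_rate_fft(sin(2 * pi * t[1:500]), 100), "10 s")
})

test_that("cold-film conversion is the affine inverse of the simulated sensor", {
  st <- steady_stream(duration = 20, seed = 9, noise = list(cf_sd = 0))
  temp <- cold_film_temperature(st$cf, default_temp_calibration(), st$fs)
  sel <- 200:length(temp)
  expect_lt(max(abs(temp[sel] - st$truth$core_temp[sel])), 0.01)
  # two-point calibration reproduces its anchor points
  cal <- two_point_calibration(0.9, 34, 1.1, 36)
  expect_equal(cal$gain * 0.9 + cal$offset, 34)
  expect_equal(cal$gain * 1.1 + cal$offset, 36)
  # monotone voltage in, monotone temperature out (positive gain)
  v <- seq(0.8, 1.2, length.out = 300)
  out <- cold_film_temperature(v, cal, fs = 100)
  expect_true(all(diff(out) >= -1e-12))
})

test_that("sliding vitals emit 1 Hz records with warm-up flags and tracked HR", {
  st <- steady_stream(duration = 40, intensity = 0.5, seed = 10)
  v <- sliding_vitals(st, true_params())
  expect_equal(v$t, 1:40)
  expect_true(all(v$flags[1:9] == "warmup"))
  expect_true(all(is.na(v$hr_bpm[1:9])))
  sel <- 25:40 # past HR relaxation transient of the short stream
  hr_true <- st$truth$heart_rate[v$t[sel] * st$fs]
  expect_lt(mean(abs(v$hr_bpm[sel] - hr_true)), 2)
  expect_true(all(v$temp_c[sel] > 25 & v$temp_c[sel] < 45))
})

test_that("HR error shrinks as hot-film noise shrinks", {
  errs <- vapply(c(0.3, 0.02), function(sd_hf) {
    st <- steady_stream(duration = 40, intensity = 0.4, seed = 21,
                        noise = list(hf_sd = sd_hf))
    v <- sliding_vitals(st, true_params())
    sel <- 25:40
    mean(abs(v$hr_bpm[sel] - st$truth$heart_rate[v$t[sel] * st$fs]), na.rm = TRUE)
  }, 1)
  expect_lte(errs[2], errs[1] + 0.25)
})
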
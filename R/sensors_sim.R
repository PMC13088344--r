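#' Exercise protocol
#'
#' An ordered list of activity segments, each with a label, a duration in
#' seconds and a dimensionless intensity in `[0, 1]` (0 = rest). Intensity
#' drives the heart-rate, metabolic-rate, skin-temperature and gait-cadence
#' set points of the simulator.
#'
#' @param segments data frame with columns `label` (character), `duration`
#'   (seconds, > 0) and `intensity` (>= 0; 0 for rest).
#' @param sampling_rate sampling rate in Hz (default 100).
#' @return An object of class `exercise_protocol`.
#' @export
exercise_protocol <- function(segments, sampling_rate = 100) {
  stopifnot(is.data.frame(segments),
            all(c("label", "duration", "intensity") %in% names(segments)),
            all(segments$duration > 0),
            all(is.finite(segments$intensity)), all(segments$intensity >= 0),
            sampling_rate > 0)
  segments$label <- as.character(segments$label)
  structure(list(segments = segments, sampling_rate = sampling_rate),
            class = "exercise_protocol")
}

#' Six-segment rest/walk/jog/run/rest routine
#'
#' Mirrors a typical treadmill routine: initial rest, slow walking (4 km/h),
#' brisk walking (6 km/h), light jogging (7 km/h), intense running (9 km/h),
#' final rest. Intensity is speed / 10 km/h.
#'
#' @param segment_duration duration of each segment in seconds (default 300,
#'   i.e. 5-minute stages).
#' @param sampling_rate sampling rate in Hz.
#' @return An `exercise_protocol`.
#' @export
default_protocol <- function(segment_duration = 300, sampling_rate = 100) {
  exercise_protocol(data.frame(
    label = c("rest", "walk_4kmh", "walk_6kmh", "jog_7kmh", "run_9kmh", "rest"),
    duration = rep(segment_duration, 6L),
    intensity = c(0, 0.4, 0.6, 0.7, 0.9, 0)
  ), sampling_rate = sampling_rate)
}

#' Two-minute natural-running calibration protocol
#'
#' The artifact-model parameters are recognized on a short calibration
#' recording of natural running. Natural (un-paced) running does not hold a
#' metronomic cadence, so the protocol varies the running intensity across
#' sub-segments; the resulting cadence sweep excites the skin response over a
#' band of frequencies rather than a single line, which is what makes all
#' three artifact-model parameters identifiable.
#'
#' @param duration total running duration in seconds (default 120).
#' @param intensities running intensity of each equal-length sub-segment.
#' @param sampling_rate sampling rate in Hz.
#' @return An `exercise_protocol`.
#' @export
calibration_protocol <- function(duration = 120,
                                 intensities = c(0.75, 0.95, 0.65, 1.0, 0.85, 0.9),
                                 sampling_rate = 100) {
  k <- length(intensities)
  exercise_protocol(data.frame(label = paste0("run_calibration_", seq_len(k)),
                               duration = rep(duration / k, k),
                               intensity = intensities),
                    sampling_rate = sampling_rate)
}

# Per-sample raw (un-relaxed) intensity and label of a protocol.
protocol_profile <- function(protocol) {
  fs <- protocol$sampling_rate
  seg <- protocol$segments
  n_seg <- round(seg$duration * fs)
  list(intensity = rep(seg$intensity, n_seg),
       label = rep(seg$label, n_seg),
       fs = fs,
       n = sum(n_seg))
}

# Physiological set-point maps, shared by the simulator. Values are
# design choices representative of a healthy adult; all configurable through
# physio_cfg in synth_session().
default_physio_cfg <- function() {
  list(
    hr_rest = 70, hr_span = 90, hr_tau = 30,           # BPM, BPM, s
    met_rest = 1.2, met_span = 9.6, met_tau = 45,      # W/kg, W/kg, s
    temp_rest = 34, temp_span = 2.0, temp_tau = 120,   # degC, degC, s
    cadence_base = 1.6, cadence_slope = 1.4,           # Hz at intensity 0 / +per unit
    accel_vert = 3.0, accel_lat = 0.8,                 # m/s^2 per unit intensity
    accel_noise_sd = 0.15, accel_ramp_tau = 5,         # m/s^2, s
    stride_var = 0.2, cadence_jitter = 0.06,           # stride-to-stride variability
    strike_amp = 1.2, strike_freq = 6, strike_tau = 0.07, # heel-strike transients
    step_asym = 0.15                                   # left/right step asymmetry
  )
}

#' Default pulse-beat template
#'
#' A beat on the unit interval modelled as a sum of Gaussian bumps: a
#' dominant systolic peak and a smaller reflective peak. Amplitude, center
#' (phase in `[0, 1]`) and width triples per peak.
#'
#' @return A list with numeric vectors `amp`, `center`, `width`.
#' @export
default_pulse_template <- function() {
  list(amp = c(1.0, 0.45), center = c(0.25, 0.55), width = c(0.06, 0.09))
}

#' Synthesize a pulse-waveform train
#'
#' Integrates the instantaneous heart rate into a beat phase and renders each
#' beat from a template of Gaussian bumps warped to the instantaneous period,
#' so beat morphology is period-invariant after time normalization. The
#' amplitude is modulated by a slow (< 0.05 Hz) unit-mean envelope.
#'
#' @param hr_profile numeric vector of instantaneous heart rate in BPM,
#'   within `[40, 220]`, one value per output sample.
#' @param template beat template, see [default_pulse_template()].
#' @param fs sampling rate in Hz.
#' @param seed integer seed for the envelope.
#' @param envelope_sd relative sd of the slow amplitude envelope.
#' @return An object of class `pulse_train`: list with the waveform `x`,
#'   ground-truth beat-onset sample indices `onsets` (phase-zero crossings)
#'   and `fs`.
#' @export
synth_pulse_train <- function(hr_profile, template = default_pulse_template(),
                              fs = 100, seed = 1, envelope_sd = 0.08) {
  if (!all(is.finite(hr_profile))) stop("hr_profile must be finite")
  if (any(hr_profile < 40 | hr_profile > 220)) {
    stop("hr_profile must lie within [40, 220] BPM")
  }
  n <- length(hr_profile)
  phase <- cumsum(hr_profile / 60) / fs
  u <- phase %% 1
  x <- numeric(n)
  for (k in seq_along(template$amp)) {
    for (shift in c(-1, 0, 1)) { # wrap bumps across beat boundaries
      x <- x + template$amp[k] *
        exp(-((u - template$center[k] + shift)^2) / (2 * template$width[k]^2))
    }
  }
  env <- 1 + envelope_sd * slow_noise(n, fs, cutoff = 0.05,
                                      seed = seed_child(seed, 11L))
  onsets <- which(diff(floor(phase)) >= 1) + 1L
  structure(list(x = x * env, onsets = onsets, fs = fs),
            class = "pulse_train")
}

#' Synthesize gait-like 3-axis head acceleration
#'
#' Per segment, produces quasi-periodic acceleration at a cadence that
#' increases with intensity: a vertical component (gravity axis) at the step
#' cadence with a second harmonic, lateral sway at half cadence, plus
#' band-limited (< 15 Hz) Gaussian noise. Rest segments produce gravity plus
#' the noise floor only. Segment transitions are smoothed by a short
#' first-order ramp of the mechanical intensity.
#'
#' @param protocol an [exercise_protocol()].
#' @param seed integer seed.
#' @param cfg physiological/mechanical configuration, see
#'   `default_physio_cfg()`.
#' @return An `n x 3` matrix with columns `ax`, `ay`, `az` in m/s^2; gravity
#'   is on `az`.
#' @export
synth_gait_accel <- function(protocol, seed = 1, cfg = default_physio_cfg()) {
  stopifnot(inherits(protocol, "exercise_protocol"))
  prof <- protocol_profile(protocol)
  fs <- prof$fs
  n <- prof$n
  g <- 9.80665
  ir <- relax_towards(prof$intensity, cfg$accel_ramp_tau, fs,
                      init = prof$intensity[1L])
  # stride-to-stride variability: slow amplitude modulation and cadence
  # jitter, as in natural gait (no two strides are identical)
  amp_mod <- 1 + cfg$stride_var * slow_noise(n, fs, cutoff = 1.0,
                                             seed = seed_child(seed, 22L))
  cadence <- (cfg$cadence_base + cfg$cadence_slope * ir) *
    (1 + cfg$cadence_jitter * slow_noise(n, fs, cutoff = 0.5,
                                         seed = seed_child(seed, 23L)))
  ph <- 2 * pi * cumsum(cadence) / fs
  phi <- with_seed(seed_child(seed, 21L), stats::runif(3L, 0, 2 * pi))
  a_v <- cfg$accel_vert * ir * amp_mod
  a_l <- cfg$accel_lat * ir * amp_mod
  # vertical bob at step cadence + second harmonic + left/right asymmetry
  # (a stride-frequency component at half cadence)
  az <- g + a_v * (sin(ph + phi[1L]) + 0.4 * sin(2 * ph + phi[2L]) +
                     cfg$step_asym * sin(ph / 2 + phi[2L]))
  ax <- a_l * sin(ph / 2 + phi[3L])
  ay <- 0.6 * a_l * sin(ph + phi[3L])
  # heel-strike transients: one short broadband decaying oscillation per
  # step, amplitude jittered stride to stride
  strikes <- which(diff(floor(ph / (2 * pi))) >= 1L) + 1L
  if (length(strikes) && cfg$strike_amp > 0) {
    kt <- seq(0, 6 * cfg$strike_tau, by = 1 / fs)
    kernel <- exp(-kt / cfg$strike_tau) * sin(2 * pi * cfg$strike_freq * kt)
    jit <- with_seed(seed_child(seed, 24L),
                     stats::runif(length(strikes), 0.6, 1.4))
    spikes <- numeric(n + length(kernel))
    for (s_i in seq_along(strikes)) {
      idx <- strikes[s_i]:(strikes[s_i] + length(kernel) - 1L)
      spikes[idx] <- spikes[idx] +
        cfg$strike_amp * ir[strikes[s_i]] * jit[s_i] * kernel
    }
    az <- az + spikes[seq_len(n)]
  }
  nsd <- cfg$accel_noise_sd * (0.2 + ir)
  bf <- signal::butter(4, 15 / (fs / 2), type = "low")
  noise <- sapply(1:3, function(k) {
    w <- with_seed(seed_child(seed, 30L + k), stats::rnorm(n))
    as.numeric(signal::filter(bf, w))
  })
  noise <- noise / stats::sd(noise) # unit-sd band-limited noise
  acc <- cbind(ax = ax + nsd * noise[, 1L],
               ay = ay + nsd * noise[, 2L],
               az = az + nsd * noise[, 3L])
  acc
}

#' Synthesize a full multimodal sensor session
#'
#' Generates a synchronized 100 Hz recording of the hot-film channel (clean
#' pulse + perfusion baseline + motion artifact + white noise), the cold-film
#' channel (affine map of skin temperature + noise) and 3-axis acceleration,
#' together with complete ground truth. The artifact channel is produced by
#' [simulate_artifact()] applied to the gravity-subtracted acceleration
#' magnitude, so the simulator and the artifact model share a single source
#' of truth.
#'
#' Heart rate, metabolic rate and skin temperature relax toward
#' intensity-dependent set points with first-order dynamics (time constants
#' 30 s, 45 s and 120 s by default). The perfusion baseline of the hot film
#' is a slow (< 0.1 Hz) component proportional to the metabolic rate, which
#' encodes the correlation between skin heat dissipation and energy cost:
#' `baseline = 0.25 + 0.12 * metabolic_rate + wander`.
#'
#' @param protocol an [exercise_protocol()].
#' @param true_params [artifact_params()] driving the artifact channel.
#' @param noise_cfg list with `hf_sd` (hot-film white-noise sd, default
#'   0.05), `cf_sd` (cold-film noise sd in volts, default 0.005) and
#'   `baseline_wander_sd` (sd of the < 0.08 Hz hot-film baseline wander,
#'   default 0.05). All must be `>= 0`.
#' @param seed integer seed.
#' @param template pulse-beat template.
#' @param physio_cfg physiological configuration, see `default_physio_cfg()`.
#' @return An object of class `sensor_stream`: list with `t` (seconds), `hf`,
#'   `cf`, `acc` (n x 3 matrix), `fs`, and `truth` (list with `heart_rate`,
#'   `metabolic_rate`, `core_temp`, `clean_pulse`, `artifact`, `baseline`,
#'   `onsets`, `intensity`, `label`).
#' @export
synth_session <- function(protocol, true_params,
                          noise_cfg = list(), seed = 1,
                          template = default_pulse_template(),
                          physio_cfg = default_physio_cfg()) {
  stopifnot(inherits(protocol, "exercise_protocol"),
            inherits(true_params, "artifact_params"))
  nc <- utils::modifyList(
    list(hf_sd = 0.05, cf_sd = 0.005, baseline_wander_sd = 0.05), noise_cfg)
  if (any(unlist(nc) < 0)) stop("noise standard deviations must be >= 0")
  prof <- protocol_profile(protocol)
  fs <- prof$fs
  if (abs(fs - true_params$fs) > 1e-12) {
    stop("protocol sampling rate and artifact-model fs disagree")
  }
  n <- prof$n
  pc <- physio_cfg

  hr <- relax_towards(pc$hr_rest + pc$hr_span * prof$intensity, pc$hr_tau, fs,
                      init = pc$hr_rest + pc$hr_span * prof$intensity[1L])
  met <- relax_towards(pc$met_rest + pc$met_span * prof$intensity, pc$met_tau,
                       fs, init = pc$met_rest + pc$met_span * prof$intensity[1L])
  temp <- relax_towards(pc$temp_rest + pc$temp_span * prof$intensity,
                        pc$temp_tau, fs,
                        init = pc$temp_rest + pc$temp_span * prof$intensity[1L])

  pulse <- synth_pulse_train(hr, template = template, fs = fs,
                             seed = seed_child(seed, 1L))
  acc <- synth_gait_accel(protocol, seed = seed_child(seed, 2L), cfg = pc)
  aref <- reference_acceleration(acc)
  artifact <- simulate_artifact(aref, true_params)

  wander <- if (nc$baseline_wander_sd > 0) {
    nc$baseline_wander_sd * slow_noise(n, fs, cutoff = 0.08,
                                       seed = seed_child(seed, 3L))
  } else numeric(n)
  baseline <- 0.25 + 0.12 * met + wander

  hf_noise <- if (nc$hf_sd > 0) {
    with_seed(seed_child(seed, 4L), stats::rnorm(n, sd = nc$hf_sd))
  } else numeric(n)
  cf_noise <- if (nc$cf_sd > 0) {
    with_seed(seed_child(seed, 5L), stats::rnorm(n, sd = nc$cf_sd))
  } else numeric(n)

  hf <- pulse$x + baseline + artifact + hf_noise
  cf <- (temp - 25) / 10 + cf_noise # 0.1 V per degC, 25 degC -> 0 V

  structure(list(
    t = (seq_len(n) - 1L) / fs,
    hf = hf,
    cf = cf,
    acc = acc,
    fs = fs,
    truth = list(heart_rate = hr, metabolic_rate = met, core_temp = temp,
                 clean_pulse = pulse$x, artifact = artifact,
                 baseline = baseline, onsets = pulse$onsets,
                 intensity = prof$intensity, label = prof$label,
                 params = true_params)
  ), class = "sensor_stream")
}

#' Cold-film temperature calibration matching the simulator
#'
#' The simulator maps skin temperature T (degC) to cold-film volts as
#' `cf = (T - 25) / 10`; the inverse calibration is gain 10 degC/V,
#' offset 25 degC.
#'
#' @return A [temp_calibration()] object.
#' @export
default_temp_calibration <- function() temp_calibration(gain = 10, offset = 25)

#' @export
print.sensor_stream <- function(x, ...) {
  cat(sprintf("sensor_stream: %d samples at %g Hz (%.1f s)%s\n",
              length(x$hf), x$fs, length(x$hf) / x$fs,
              if (!is.null(x$truth)) ", with ground truth" else ""))
  invisible(x)
}

# Extract a [i1, i2] sample range as a new sensor_stream (truth subset too).
stream_slice <- function(stream, i1, i2) {
  idx <- i1:i2
  truth <- stream$truth
  if (!is.null(truth)) {
    per_sample <- c("heart_rate", "metabolic_rate", "core_temp",
                    "clean_pulse", "artifact", "baseline", "intensity", "label")
    for (f in intersect(per_sample, names(truth))) truth[[f]] <- truth[[f]][idx]
    if (!is.null(truth$onsets)) {
      truth$onsets <- truth$onsets[truth$onsets >= i1 & truth$onsets <= i2] - i1 + 1L
    }
  }
  structure(list(t = stream$t[idx], hf = stream$hf[idx], cf = stream$cf[idx],
                 acc = stream$acc[idx, , drop = FALSE], fs = stream$fs,
                 truth = truth),
            class = "sensor_stream")
}
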
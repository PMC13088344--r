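#' Linear cold-film temperature calibration
#'
#' The cold film is an unheated thermistor whose output voltage is
#' proportional to skin temperature; the calibration is the affine map
#' `temp = gain * volts + offset`.
#'
#' @param gain degrees C per volt, non-zero.
#' @param offset degrees C.
#' @return An object of class `temp_calibration`.
#' @export
temp_calibration <- function(gain, offset) {
  stopifnot(is.finite(gain), gain != 0, is.finite(offset))
  structure(list(gain = gain, offset = offset), class = "temp_calibration")
}

#' Two-point temperature calibration
#'
#' Fits the line through two (voltage, temperature) reference points.
#'
#' @param v1,t1 first reference point (volts, degC).
#' @param v2,t2 second reference point (volts, degC).
#' @return A [temp_calibration()].
#' @export
two_point_calibration <- function(v1, t1, v2, t2) {
  stopifnot(v1 != v2)
  gain <- (t2 - t1) / (v2 - v1)
  temp_calibration(gain = gain, offset = t1 - gain * v1)
}

#' Remove motion artifact from the hot-film channel
#'
#' Reconstructs the motion artifact from the gravity-subtracted acceleration
#' magnitude through the recognized second-order model and subtracts it from
#' the hot-film channel, then restricts the result to the pulse band. The
#' subtraction is performed before band-passing, which by linearity equals
#' `bandpass(hf) - bandpass(MA)` and keeps the artifact cancellation coherent
#' inside the pulse band.
#'
#' @param hf hot-film series.
#' @param acc `n x 3` acceleration matrix aligned with `hf`.
#' @param params recognized [artifact_params()].
#' @param band pulse band in Hz (default `c(0.5, 5)`).
#' @return Clean pulse waveform `PW`, same length as `hf`.
#' @export
remove_artifact <- function(hf, acc, params, band = c(0.5, 5)) {
  stopifnot(inherits(params, "artifact_params"))
  if (length(hf) != nrow(acc)) stop("hf and acc must have the same length")
  ma <- simulate_artifact(reference_acceleration(acc), params)
  bandpass_pulse(hf - ma, params$fs, band[1L], band[2L])
}

#' FFT heart rate from a pulse window
#'
#' Hann-windowed magnitude spectrum of a pulse window (>= 10 s), restricted
#' to the pulse band; the heart rate is 60 times the peak frequency, refined
#' by quadratic (parabolic) interpolation of the log-magnitudes around the
#' peak bin. A flat in-band spectrum (peak below `flat_ratio` times the
#' median in-band magnitude) yields `NA` with an `"invalid"` flag.
#'
#' @param pw_window numeric pulse window.
#' @param fs sampling rate in Hz.
#' @param band frequency band in Hz to search (default `c(0.5, 5)`).
#' @param flat_ratio peak-to-median magnitude ratio under which the spectrum
#'   is declared flat (default 5).
#' @return Numeric heart rate in BPM, with attribute `flag` equal to `"ok"`
#'   or `"invalid"` (`NA` value when invalid).
#' @export
heart_rate_fft <- function(pw_window, fs = 100, band = c(0.5, 5),
                           flat_ratio = 5) {
  n <- length(pw_window)
  if (n < 10 * fs) stop("heart-rate window must be at least 10 s")
  if (stats::sd(pw_window) < 1e-12) { # constant input: no pulse at all
    return(structure(NA_real_, flag = "invalid"))
  }
  w <- as.numeric(signal::hanning(n))
  spec <- Mod(stats::fft(pw_window * w))[seq_len(floor(n / 2) + 1L)]
  freq <- (seq_len(floor(n / 2) + 1L) - 1L) * fs / n
  inband <- which(freq >= band[1L] & freq <= band[2L])
  mags <- spec[inband]
  medmag <- stats::median(mags)
  if (!is.finite(medmag) || medmag <= 0 || max(mags) < flat_ratio * medmag) {
    return(structure(NA_real_, flag = "invalid"))
  }
  k <- inband[which.max(mags)]
  f_peak <- freq[k]
  if (k > 1L && k < length(spec)) {
    la <- log(spec[k - 1L] + 1e-300)
    lb <- log(spec[k] + 1e-300)
    lc <- log(spec[k + 1L] + 1e-300)
    denom <- la - 2 * lb + lc
    if (is.finite(denom) && abs(denom) > 1e-12) {
      delta <- 0.5 * (la - lc) / denom
      delta <- max(min(delta, 0.5), -0.5)
      f_peak <- f_peak + delta * fs / n
    }
  }
  structure(60 * f_peak, flag = "ok")
}

#' Convert the cold-film voltage to temperature
#'
#' Applies the linear calibration and smooths with a causal 1 s moving
#' average.
#'
#' @param cf cold-film voltage series.
#' @param cal a [temp_calibration()].
#' @param fs sampling rate in Hz.
#' @param smooth_s moving-average length in seconds (default 1).
#' @return Temperature series in degC, same length as `cf`.
#' @export
cold_film_temperature <- function(cf, cal, fs = 100, smooth_s = 1) {
  stopifnot(inherits(cal, "temp_calibration"))
  temp <- cal$gain * cf + cal$offset
  k <- max(1L, round(smooth_s * fs))
  cs <- cumsum(temp)
  sm <- numeric(length(temp))
  idx <- seq_along(temp)
  lead <- pmax(idx - k, 0L)
  sm <- (cs - c(0, cs)[lead + 1L]) / (idx - lead)
  sm
}

#' Per-second vitals from a sensor stream
#'
#' Applies [remove_artifact()] once, then emits one record per second: heart
#' rate from a 10 s trailing Hann/FFT window, smoothed forehead temperature,
#' and a robust pulse amplitude (half the 5-95% range of the window). The
#' first `window_s - 1` seconds are emitted with `NA` vitals and a
#' `"warmup"` flag. Heart rates outside `[24, 300]` BPM and temperatures
#' outside `[25, 45]` degC are flagged.
#'
#' @param stream a `sensor_stream`.
#' @param params recognized [artifact_params()].
#' @param cal a [temp_calibration()].
#' @param cfg list: `window_s` (default 10), `band` (default `c(0.5, 5)`).
#' @return Data frame with columns `t`, `hr_bpm`, `temp_c`, `pulse_amp`,
#'   `flags` — one row per second, cadence exactly 1 Hz.
#' @export
sliding_vitals <- function(stream, params, cal = default_temp_calibration(),
                           cfg = list()) {
  cfg <- utils::modifyList(list(window_s = 10L, band = c(0.5, 5)), cfg)
  fs <- stream$fs
  pw <- remove_artifact(stream$hf, stream$acc, params, band = cfg$band)
  temp <- cold_film_temperature(stream$cf, cal, fs)
  n_sec <- floor(length(pw) / fs)
  win <- round(cfg$window_s * fs)
  out <- data.frame(t = seq_len(n_sec), hr_bpm = NA_real_,
                    temp_c = NA_real_, pulse_amp = NA_real_,
                    flags = "warmup", stringsAsFactors = FALSE)
  for (s in seq_len(n_sec)) {
    end <- round(s * fs)
    if (end < win) next
    wdat <- pw[(end - win + 1L):end]
    hr <- heart_rate_fft(wdat, fs, band = cfg$band)
    flags <- character(0)
    if (identical(attr(hr, "flag"), "invalid")) flags <- c(flags, "invalid_hr")
    hr_val <- as.numeric(hr)
    if (is.finite(hr_val) && (hr_val < 24 || hr_val > 300)) {
      flags <- c(flags, "hr_range")
    }
    tv <- temp[end]
    if (tv < 25 || tv > 45) flags <- c(flags, "temp_range")
    q <- stats::quantile(wdat, c(0.05, 0.95), names = FALSE)
    out$hr_bpm[s] <- hr_val
    out$temp_c[s] <- tv
    out$pulse_amp[s] <- (q[2L] - q[1L]) / 2
    out$flags[s] <- if (length(flags)) paste(flags, collapse = ",") else "ok"
  }
  out
}
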
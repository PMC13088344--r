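#' Scalar reference acceleration
#'
#' Collapses the 3-axis accelerometer signal into the scalar reference used
#' by the artifact model: the Euclidean norm of the acceleration vector minus
#' standard gravity. Subtracting gravity from the magnitude (rather than from
#' one axis) makes the reference independent of wearing orientation. The
#' result is signed and unclipped; a stationary device gives 0 and free fall
#' gives `-9.80665`.
#'
#' @param acc `n x 3` numeric matrix of acceleration in m/s^2.
#' @return Numeric vector of length `n`.
#' @export
reference_acceleration <- function(acc) {
  stopifnot(is.matrix(acc), ncol(acc) == 3L, all(is.finite(acc)))
  sqrt(rowSums(acc^2)) - 9.80665
}

#' Band-pass filter for the pulse band
#'
#' 4th-order Butterworth band-pass (default 0.5-5 Hz, the band containing the
#' pulse fundamental and its useful harmonics), applied causally by default.
#' The design attenuates by more than 20 dB one octave outside either band
#' edge and is flat (< 1 dB ripple) in band.
#'
#' @param x numeric series.
#' @param fs sampling rate in Hz.
#' @param lo,hi band edges in Hz, `0 < lo < hi < fs/2`.
#' @param zero_phase if `TRUE` filter forward-backward (offline use).
#' @return Filtered numeric vector, same length as `x`.
#' @export
bandpass_pulse <- function(x, fs = 100, lo = 0.5, hi = 5, zero_phase = FALSE) {
  if (!(lo > 0 && lo < hi && hi < fs / 2)) {
    stop("invalid band: need 0 < lo < hi < fs/2")
  }
  bf <- signal::butter(4, c(lo, hi) / (fs / 2), type = "pass")
  if (zero_phase) {
    as.numeric(signal::filtfilt(bf, x))
  } else {
    as.numeric(signal::filter(bf, x))
  }
}

#' Segmented, time-normalized pulse beats
#'
#' Container for beats cut from a band-passed pulse waveform and linearly
#' resampled to a common length `n`, so any two beats are comparable by
#' Euclidean distance.
#'
#' @param beats numeric matrix, one beat per row, `n` columns.
#' @param onsets integer sample indices of the beat onsets in the source
#'   stream (length `N + 1`: each beat spans `onsets[k]` to `onsets[k+1]`).
#' @param n normalized beat length.
#' @param empty logical flag: `TRUE` when no beats were detectable.
#' @return An object of class `beat_set` with fields `beats`, `onsets`, `n`,
#'   `N` and `empty`.
#' @export
beat_set <- function(beats, onsets, n, empty = FALSE) {
  stopifnot(is.matrix(beats))
  if (!empty) {
    stopifnot(ncol(beats) == n, all(diff(onsets) > 0))
  }
  structure(list(beats = beats, onsets = onsets, n = n,
                 N = if (empty) 0L else nrow(beats), empty = empty),
            class = "beat_set")
}

#' @export
print.beat_set <- function(x, ...) {
  if (x$empty) cat("beat_set: empty (no detectable beats)\n")
  else cat(sprintf("beat_set: %d beats, normalized length %d\n", x$N, x$n))
  invisible(x)
}

# Local maxima above an adaptive threshold, pruned to a minimum spacing
# (greedy, tallest first). Threshold is relative to the upper quantile of
# candidate peak heights, which adapts to the overall waveform scale.
find_pulse_peaks <- function(x, fs, min_dist_s = 0.27, rel_height = 0.4) {
  d <- diff(x)
  cand <- which(d[-length(d)] > 0 & d[-1L] <= 0) + 1L
  if (length(cand) < 2L) return(integer(0))
  h <- x[cand]
  thr <- rel_height * stats::quantile(h, 0.95, names = FALSE)
  cand <- cand[h >= thr]
  if (length(cand) < 2L) return(integer(0))
  ord <- cand[order(x[cand], decreasing = TRUE)]
  min_dist <- round(min_dist_s * fs)
  keep <- logical(0)
  kept <- integer(0)
  for (p in ord) {
    if (all(abs(kept - p) >= min_dist)) kept <- c(kept, p)
  }
  sort(kept)
}

#' Segment a pulse waveform into normalized beats
#'
#' Detects systolic peaks (local maxima with adaptive height threshold and a
#' minimum inter-peak spacing of 0.27 s, i.e. a 220 BPM ceiling), places each
#' beat onset at the waveform minimum immediately preceding the systolic
#' upstroke, and linearly resamples every onset-to-onset beat to exactly `n`
#' samples.
#'
#' @param pw band-passed pulse waveform.
#' @param fs sampling rate in Hz.
#' @param n normalized beat length (default 100 samples).
#' @return A [beat_set()]. If fewer than two beats are detectable (e.g. a
#'   constant input) the set is flagged `empty`.
#' @export
segment_beats <- function(pw, fs = 100, n = 100) {
  stopifnot(is.numeric(pw), all(is.finite(pw)))
  if (stats::sd(pw) < .Machine$double.eps^0.5) {
    return(beat_set(matrix(numeric(0), 0L, n), integer(0), n, empty = TRUE))
  }
  peaks <- find_pulse_peaks(pw, fs)
  if (length(peaks) < 3L) {
    return(beat_set(matrix(numeric(0), 0L, n), integer(0), n, empty = TRUE))
  }
  # onset = minimum between the late part of the previous inter-peak gap and
  # the current peak (the minimum immediately preceding the systolic upstroke)
  onsets <- integer(length(peaks) - 1L)
  for (k in 2:length(peaks)) {
    gap <- peaks[k] - peaks[k - 1L]
    from <- peaks[k - 1L] + max(1L, round(0.3 * gap))
    seg <- pw[from:peaks[k]]
    onsets[k - 1L] <- from + which.min(seg) - 1L
  }
  if (length(onsets) < 2L) {
    return(beat_set(matrix(numeric(0), 0L, n), integer(0), n, empty = TRUE))
  }
  N <- length(onsets) - 1L
  beats <- matrix(0, N, n)
  for (k in seq_len(N)) {
    idx <- onsets[k]:onsets[k + 1L]
    beats[k, ] <- stats::approx(seq(0, 1, length.out = length(idx)),
                                pw[idx],
                                xout = seq(0, 1, length.out = n))$y
  }
  beat_set(beats, onsets, n)
}

#' Write a beat set to CSV or JSON
#'
#' CSV: one beat per row, no header. JSON: object with `onsets`, `n` and the
#' beat matrix.
#'
#' @param bs a [beat_set()].
#' @param path output path.
#' @param format `"csv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_beats <- function(bs, path, format = c("csv", "json")) {
  format <- match.arg(format)
  stopifnot(inherits(bs, "beat_set"))
  if (format == "csv") {
    utils::write.table(bs$beats, path, sep = ",", row.names = FALSE,
                       col.names = FALSE)
  } else {
    jsonlite::write_json(list(onsets = bs$onsets, n = bs$n,
                              beats = bs$beats),
                         path, digits = NA)
  }
  invisible(path)
}
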
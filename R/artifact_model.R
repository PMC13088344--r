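#' Second-order motion-artifact model parameters
#'
#' The pulse channel of a forehead-worn thermal-film sensor is contaminated
#' by motion artifact generated by skin deformation under head acceleration.
#' The skin/sensor interface is modelled as a spring-damper system, so the
#' mapping from the scalar reference acceleration A(s) to the artifact MA(s)
#' is the second-order low-pass transfer function
#' \deqn{H(s) = \frac{K\,\omega_n^2}{s^2 + 2\zeta\omega_n s + \omega_n^2}}
#' with dimensionless gain `K`, damping ratio `zeta` and undamped natural
#' frequency `omega_n` (rad/s). `K`, `zeta` and `omega_n` depend on the
#' individual and the wearing conditions and are recognized per wearer by
#' [calibrate_artifact()].
#'
#' The reference acceleration is in m/s^2; any unit rescaling is absorbed by
#' `K`.
#'
#' @param K gain, dimensionless, `>= 0`.
#' @param zeta damping ratio, `> 0`.
#' @param omega_n undamped natural frequency in rad/s, `> 0` and below the
#'   Nyquist rate (`omega_n / (2*pi) < fs / 2`).
#' @param fs sampling rate in Hz.
#' @return An object of class `artifact_params`.
#' @seealso [discretize()], [simulate_artifact()], [calibrate_artifact()]
#' @export
artifact_params <- function(K, zeta, omega_n, fs = 100) {
  stopifnot(
    is.numeric(K), length(K) == 1L, is.finite(K), K >= 0,
    is.numeric(zeta), length(zeta) == 1L, is.finite(zeta), zeta > 0,
    is.numeric(omega_n), length(omega_n) == 1L, is.finite(omega_n), omega_n > 0,
    is.numeric(fs), length(fs) == 1L, fs > 0
  )
  if (omega_n / (2 * pi) >= fs / 2) {
    stop("omega_n must place the resonance below the Nyquist frequency")
  }
  structure(list(K = K, zeta = zeta, omega_n = omega_n, fs = fs),
            class = "artifact_params")
}

#' @export
print.artifact_params <- function(x, ...) {
  cat(sprintf(
    "artifact_params: K = %.4g, zeta = %.4g, omega_n = %.4g rad/s (%.3g Hz), fs = %g Hz\n",
    x$K, x$zeta, x$omega_n, x$omega_n / (2 * pi), x$fs))
  invisible(x)
}

#' Discretize the second-order artifact transfer function
#'
#' Applies the bilinear (Tustin) transform to the continuous prototype
#' `K * omega_n^2 / (s^2 + 2*zeta*omega_n*s + omega_n^2)` at the stream's
#' sampling rate. No frequency pre-warping is applied: at 100 Hz the artifact
#' energy sits far below Nyquist and the Tustin map preserves both stability
#' and the DC gain `K` exactly.
#'
#' @param params an [artifact_params()] object.
#' @return An object of class `discrete_filter` with feed-forward
#'   coefficients `b`, feedback coefficients `a` and the originating
#'   `params`. All poles lie strictly inside the unit circle and the DC gain
#'   equals `K` to within 1e-9 relative.
#' @export
discretize <- function(params) {
  stopifnot(inherits(params, "artifact_params"))
  wn <- params$omega_n
  zt <- params$zeta
  wd <- wn * sqrt(abs(1 - zt^2) + 0i)
  if (zt < 1) {
    poles <- c(complex(real = -zt * wn, imaginary = wn * sqrt(1 - zt^2)),
               complex(real = -zt * wn, imaginary = -wn * sqrt(1 - zt^2)))
  } else {
    # critically damped / overdamped: real poles
    poles <- c(-zt * wn + wn * sqrt(zt^2 - 1), -zt * wn - wn * sqrt(zt^2 - 1))
    poles <- as.complex(poles)
  }
  zpg <- signal::bilinear(Sz = numeric(0), Sp = poles,
                          Sg = params$K * wn^2, T = 1 / params$fs)
  arma <- signal::as.Arma(zpg)
  b <- Re(arma$b)
  a <- Re(arma$a)
  dc <- sum(b) / sum(a)
  if (params$K > 0 && abs(dc - params$K) > 1e-9 * params$K) {
    stop("bilinear discretization failed to preserve the DC gain")
  }
  structure(list(b = b, a = a, params = params), class = "discrete_filter")
}

#' @export
print.discrete_filter <- function(x, ...) {
  cat("discrete_filter (bilinear transform of second-order artifact model)\n")
  cat("  b:", signif(x$b, 6), "\n  a:", signif(x$a, 6), "\n")
  invisible(x)
}

#' Reconstruct motion artifact from the reference acceleration
#'
#' Runs the discretized second-order model causally over the scalar reference
#' acceleration (see [reference_acceleration()]), starting from zero filter
#' state. An optional zero-phase mode (forward-backward filtering) exists for
#' offline analysis; calibration and the real-time path always use the causal
#' filter.
#'
#' @param accel_ref numeric vector, reference acceleration in m/s^2 sampled
#'   uniformly at `params$fs`.
#' @param params an [artifact_params()] object.
#' @param zero_phase logical; if `TRUE`, filter forward and backward
#'   (non-causal, offline use only).
#' @return Numeric vector: the modelled motion artifact, same length as
#'   `accel_ref`, in the units of the pulse channel.
#' @export
simulate_artifact <- function(accel_ref, params, zero_phase = FALSE) {
  stopifnot(is.numeric(accel_ref), all(is.finite(accel_ref)))
  filt <- discretize(params)
  if (zero_phase) {
    as.numeric(signal::filtfilt(filt$b, filt$a, accel_ref))
  } else {
    as.numeric(signal::filter(filt$b, filt$a, accel_ref))
  }
}

#' Serialize artifact-model parameters to JSON
#'
#' @param params an [artifact_params()] object.
#' @param path file path; if `NULL`, the JSON string is returned.
#' @return `path` invisibly, or the JSON string when `path` is `NULL`.
#' @export
write_artifact_params <- function(params, path = NULL) {
  stopifnot(inherits(params, "artifact_params"))
  x <- list(K = params$K, zeta = params$zeta,
            omega_n = params$omega_n, fs = params$fs)
  if (is.null(path)) {
    return(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA))
  }
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read artifact-model parameters from JSON
#'
#' @param path file path to a flat JSON object `{K, zeta, omega_n, fs}`.
#' @return An [artifact_params()] object.
#' @export
read_artifact_params <- function(path) {
  x <- jsonlite::fromJSON(path)
  artifact_params(K = x$K, zeta = x$zeta, omega_n = x$omega_n, fs = x$fs)
}
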
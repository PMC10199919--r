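#' FMCW chirp configuration
#'
#' Parameters of the near-ultrasonic frequency-modulated continuous-wave
#' (FMCW) transmission: each speaker repeatedly sweeps from \code{f0} to
#' \code{f1} over a period \code{T}, and speaker \eqn{i} transmits a copy
#' delayed by \eqn{(i-1)\,\code{shift_fraction}\,T} so that the receiver can
#' separate the speakers in the beat-frequency domain after dechirping.
#'
#' @param f0 sweep start frequency, Hz (default 18 kHz).
#' @param f1 sweep end frequency, Hz (default 22 kHz).
#' @param T_chirp chirp duration, s (default 43 ms).
#' @param n_speakers number of speakers on the array (default 4).
#' @param shift_fraction per-speaker time shift as a fraction of \code{T_chirp}
#'   (default 1/5).
#' @param fs sample rate, Hz (default 50 000; must exceed \code{2*f1}).
#' @return an object of class \code{"chirp_config"}; a list with the arguments
#'   plus \code{B = f1 - f0} (sweep bandwidth, Hz) and \code{n_frame}, the
#'   number of samples per chirp period.
#' @examples
#' cfg <- chirp_config()
#' cfg$B          # 4000 Hz
#' cfg$n_frame    # 2150 samples per 43 ms frame at 50 kHz
#' @export
chirp_config <- function(f0 = 18000, f1 = 22000, T_chirp = 0.043,
                         n_speakers = 4L, shift_fraction = 1 / 5,
                         fs = 50000) {
  stop_if_not(f1 > f0, "f1 must exceed f0")
  stop_if_not(fs > 2 * f1, "sample rate violates Nyquist for f1")
  stop_if_not(shift_fraction > 0 && shift_fraction * n_speakers <= 1 + 1e-12,
              "shift_fraction must place all speaker shifts within one period")
  structure(list(f0 = f0, f1 = f1, T_chirp = T_chirp,
                 n_speakers = as.integer(n_speakers),
                 shift_fraction = shift_fraction, fs = fs,
                 B = f1 - f0, n_frame = round(T_chirp * fs)),
            class = "chirp_config")
}

#' @export
print.chirp_config <- function(x, ...) {
  cat(sprintf("FMCW chirp: %.0f-%.0f Hz over %.1f ms (B = %.0f Hz), fs = %.0f Hz\n",
              x$f0, x$f1, 1000 * x$T_chirp, x$B, x$fs))
  cat(sprintf("%d speakers, per-speaker shift %.2f ms (%d samples/frame)\n",
              x$n_speakers, 1000 * x$shift_fraction * x$T_chirp, x$n_frame))
  invisible(x)
}

speaker_shift <- function(i, cfg) (i - 1) * cfg$shift_fraction * cfg$T_chirp

# Closed-form evaluation of the (periodic) analytic chirp of speaker i at
# arbitrary continuous times.  The transmit phase is
#   2 pi ( f0 u + B/(2T) u^2 ),  u = (t - shift_i) mod T,
# so delayed/clock-warped copies can be rendered exactly by evaluating at
# shifted times -- no fractional-sample interpolation involved.
chirp_wave_at <- function(t, i, cfg) {
  u <- (t - speaker_shift(i, cfg)) %% cfg$T_chirp
  exp(2i * pi * (cfg$f0 * u + cfg$B / (2 * cfg$T_chirp) * u^2))
}

#' Generate one period of a speaker's FMCW chirp
#'
#' Returns the complex analytic baseband chirp of speaker \code{i}, sampled at
#' \code{cfg$fs} over one period, wrapped periodically so that the time shift
#' of later speakers rotates the waveform circularly. Take \code{Re()} for a
#' real render (e.g. WAV export).
#'
#' @param i speaker index, 1-based (1 .. \code{cfg$n_speakers}).
#' @param cfg a [chirp_config()].
#' @return complex vector of length \code{cfg$n_frame}.
#' @examples
#' x <- generate_chirp(1, chirp_config())
#' x[1]   # phase zero at t = 0 for the unshifted speaker
#' @export
generate_chirp <- function(i, cfg) {
  stop_if_not(i >= 1 && i <= cfg$n_speakers, "invalid speaker index")
  t <- seq_len(cfg$n_frame) - 1
  chirp_wave_at(t / cfg$fs, i, cfg)
}

#' Forward FMCW phase model
#'
#' Phase of the dechirped (receiver-times-conjugate-reference) signal at time
#' \code{t} within the chirp, for a direct path arriving with time of flight
#' \code{t_d}:
#' \deqn{\phi(t) = -2\pi\left(\frac{B}{T} t\, t_d + f_0 t_d -
#'   \frac{B}{2T} t_d^2\right).}
#' This is the model that [phase_to_tof()] inverts.
#'
#' @param t time within the chirp period, s.
#' @param t_d time of arrival, s; must lie in \code{[0, T]}.
#' @param cfg a [chirp_config()].
#' @return unwrapped phase in radians.
#' @export
forward_phase <- function(t, t_d, cfg) {
  stop_if_not(all(t_d >= 0 & t_d <= cfg$T_chirp), "t_d outside [0, T]")
  -2 * pi * (cfg$B / cfg$T_chirp * t * t_d + cfg$f0 * t_d -
               cfg$B / (2 * cfg$T_chirp) * t_d^2)
}

# Unrestricted version used internally by the tracker (delays beyond one
# period arise when clock drift is deliberately left uncorrected).
forward_phase_unchecked <- function(t, t_d, cfg) {
  -2 * pi * (cfg$B / cfg$T_chirp * t * t_d + cfg$f0 * t_d -
               cfg$B / (2 * cfg$T_chirp) * t_d^2)
}

#' Speaker array geometry
#'
#' Four speakers on the corners of a square of side \code{L} in the z = 0
#' plane, with the z axis pointing from the array toward the patient. The
#' layout is chosen so that the difference-based position equations return
#' (+x, +y): speaker 1 at (-L/2, -L/2), speaker 2 at (+L/2, -L/2), speaker 3
#' at (-L/2, +L/2), speaker 4 at (+L/2, +L/2). Three of the four speakers
#' transmit (default 1-3): speakers 1/2 form the x baseline and 1/3 the y
#' baseline.
#'
#' @param L adjacent-speaker separation, m (default 0.1).
#' @param active indices of the three transmitting speakers (default 1:3).
#' @return object of class \code{"speaker_array"}: list with \code{L},
#'   4 x 3 \code{positions} matrix (m), and \code{active}.
#' @export
speaker_array <- function(L = 0.1, active = 1:3) {
  stop_if_not(L > 0, "L must be positive")
  stop_if_not(length(active) == 3 && all(active %in% 1:4),
              "exactly 3 active speakers from 1..4")
  half <- L / 2
  pos <- rbind(c(-half, -half, 0),
               c(+half, -half, 0),
               c(-half, +half, 0),
               c(+half, +half, 0))
  rownames(pos) <- paste0("s", 1:4)
  colnames(pos) <- c("x", "y", "z")
  structure(list(L = L, positions = pos, active = as.integer(active)),
            class = "speaker_array")
}

#' @export
print.speaker_array <- function(x, ...) {
  cat(sprintf("Speaker array: square side L = %.3f m, active speakers %s\n",
              x$L, paste(x$active, collapse = ",")))
  print(round(x$positions, 4))
  invisible(x)
}

#' Serialize chirp and array configuration to JSON
#' @param cfg a [chirp_config()].
#' @param array a [speaker_array()], optional.
#' @param path file to write; if missing the JSON string is returned.
#' @return the JSON string, invisibly when written to a file.
#' @export
chirp_to_json <- function(cfg, array = NULL, path = NULL) {
  x <- list(chirp = unclass(cfg))
  if (!is.null(array)) {
    x$array <- list(L = array$L, active = array$active)
  }
  js <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}

#' Read chirp/array configuration from JSON
#' @param path file or JSON string produced by [chirp_to_json()].
#' @return list with \code{cfg} and (if present) \code{array}.
#' @export
chirp_from_json <- function(path) {
  x <- jsonlite::fromJSON(path)
  cfg <- chirp_config(f0 = x$chirp$f0, f1 = x$chirp$f1,
                      T_chirp = x$chirp$T_chirp,
                      n_speakers = x$chirp$n_speakers,
                      shift_fraction = x$chirp$shift_fraction,
                      fs = x$chirp$fs)
  out <- list(cfg = cfg)
  if (!is.null(x$array)) out$array <- speaker_array(x$array$L, x$array$active)
  out
}
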
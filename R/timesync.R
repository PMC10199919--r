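# Two-stage clock-drift correction: beacon-based alignment plus a
# sliding-window regression on the height history that removes residual drift.

#' Resample a signal by a clock drift factor
#'
#' Implements drift-factor resampling through a forward transform followed by
#' synthesis on a frequency-shifted basis:
#' \deqn{X_f = \sum_t x_t e^{-i2\pi f t/N}, \qquad
#'       \hat x_t = \frac1N \sum_f X_f e^{i2\pi \alpha f t/N},}
#' with signed frequencies so real inputs stay real. \code{alpha = 1} is the
#' identity (to transform round-trip precision); \code{alpha > 1} scales every
#' frequency up by \code{alpha}, which is how a receiver sampling slightly too
#' slowly is corrected.
#'
#' Synthesis is evaluated densely (O(N^2), blocked to bound memory); intended
#' for chirp-frame-scale inputs, not multi-minute streams (the tracker removes
#' drift equivalently by evaluating its dechirp reference on the beacon-mapped
#' timeline).
#'
#' @param x numeric or complex vector.
#' @param alpha drift factor, dimensionless, within (0.9, 1.1).
#' @return resampled vector, same length and mode as \code{x}.
#' @export
resample_with_drift <- function(x, alpha) {
  stop_if_not(all(is.finite(Mod(x))), "signal must be finite")
  stop_if_not(is.finite(alpha) && alpha > 0.9 && alpha < 1.1,
              "alpha must lie in (0.9, 1.1)")
  n <- length(x)
  X <- stats::fft(x) / n
  f <- c(0:floor(n / 2), -(ceiling(n / 2) - 1):-1)[seq_len(n)]
  if (n %% 2 == 0) {
    # split the Nyquist bin so conjugate symmetry (real input) is preserved
    k <- n / 2 + 1
    X <- c(X[seq_len(k - 1)], X[k] / 2, X[k] / 2, X[seq(k + 1, n)][seq_len(n - k)])
    f <- c(f[seq_len(k - 1)], n / 2, -n / 2, f[seq(k + 1, n)][seq_len(n - k)])
  }
  out <- complex(length.out = n)
  tt <- 0:(n - 1)
  block <- max(1L, floor(2^22 / length(f)))
  for (s in seq(1, n, by = block)) {
    e <- min(s + block - 1, n)
    basis <- exp(outer(tt[s:e], f, function(a, b) 2i * pi * alpha * a * b / n))
    out[s:e] <- as.vector(basis %*% X)
  }
  if (is.complex(x)) out else Re(out)
}

#' Align the receiver timeline to the transmitter via sync beacons
#'
#' Unwraps the wrapped 16 MHz timer tick streams on both sides, converts them
#' to seconds, and fits transmitter time as a linear function of receiver time
#' by ordinary least squares. The slope is the drift factor between the two
#' clocks; the residual is bounded by timer quantization (62.5 ns per tick)
#' plus beacon jitter, averaged down by the number of beacons.
#'
#' @param beacons data.frame(t_true, tx_ticks, rx_ticks) from
#'   [simulate_beacons()] (or a real beacon log).
#' @param clocks a [clock_model()] (for timer constants).
#' @return object of class \code{"clock_map"}: list(alpha, offset, resid_sd,
#'   n). Evaluate with [map_rx_to_tx()].
#' @export
beacon_align <- function(beacons, clocks = clock_model()) {
  stop_if_not(nrow(beacons) >= 2, "need at least 2 beacons")
  tau_tx <- unwrap_ticks(beacons$tx_ticks, clocks$timer_max) / clocks$timer_freq
  tau_rx <- unwrap_ticks(beacons$rx_ticks, clocks$timer_max) / clocks$timer_freq
  stop_if_not(!is.unsorted(tau_rx), "non-monotonic beacon times")
  fit <- stats::lm.fit(cbind(1, tau_rx), tau_tx)
  structure(list(alpha = unname(fit$coefficients[2]),
                 offset = unname(fit$coefficients[1]),
                 resid_sd = stats::sd(fit$residuals),
                 n = nrow(beacons)),
            class = "clock_map")
}

unwrap_ticks <- function(ticks, timer_max) {
  wraps <- cumsum(c(0, diff(ticks) < -timer_max / 2))
  ticks + wraps * timer_max
}

#' Identity clock map (no synchronization)
#' @export
identity_clock_map <- function() {
  structure(list(alpha = 1, offset = 0, resid_sd = 0, n = 0L),
            class = "clock_map")
}

#' Map receiver time to transmitter time
#' @param map a \code{"clock_map"} from [beacon_align()].
#' @param tau_rx receiver nominal times, s.
#' @return transmitter times, s.
#' @export
map_rx_to_tx <- function(map, tau_rx) map$alpha * tau_rx + map$offset

#' @export
print.clock_map <- function(x, ...) {
  cat(sprintf("Clock map: alpha = 1%+.3g (%.2f ppm), offset %.3g s, residual sd %.3g s (n=%d)\n",
              x$alpha - 1, (x$alpha - 1) * 1e6, x$offset, x$resid_sd, x$n))
  invisible(x)
}

#' Estimate residual drift from a height (or distance) history
#'
#' The post-processing stage: split the trailing history window into fixed
#' chunks, fit a least-squares line per chunk, rank chunks by their residual
#' sum of squares, keep the better (lower-residual) half — motion bursts and
#' occlusions inflate a chunk's residual and push it out — and return the mean
#' slope of the kept chunks as the drift estimate. With an odd chunk count the
#' lower \code{floor(n/2)} chunks are kept.
#'
#' @param t timestamps, s.
#' @param h series (height in cm or distance in m — slope units follow).
#' @param window trailing history span to use, s (default 300).
#' @param chunk chunk length, s (default 30).
#' @param min_chunk_n discard chunks with fewer samples than this (default 10).
#' @param motion optional logical vector of IMU motion flags: drift is only
#'   learned from motion-free stretches, and chunks never straddle a motion
#'   interval (a bed transition would otherwise masquerade as drift). Static
#'   stretches shorter than ~3/4 of a chunk are discarded.
#' @return object of class \code{"drift_estimate"}: list(slope, ok, n_chunks,
#'   chunks). \code{ok = FALSE} (slope 0) when fewer than 2 usable chunks.
#' @export
estimate_residual_drift <- function(t, h, window = 300, chunk = 30,
                                    min_chunk_n = 10, motion = NULL) {
  stop_if_not(window / chunk >= 2, "window must span at least 2 chunks")
  keep <- t >= max(t) - window
  if (!is.null(motion)) {
    stop_if_not(length(motion) == length(t), "motion flags length mismatch")
    run <- cumsum(c(0, diff(motion) != 0))
    keep <- keep & !motion
  } else {
    run <- rep(0L, length(t))
  }
  run <- run[keep]; t <- t[keep]; h <- h[keep]
  if (!length(t)) {
    return(structure(list(slope = 0, ok = FALSE, n_chunks = 0L,
                          chunks = NULL), class = "drift_estimate"))
  }
  id <- paste(run, floor((t - min(t)) / chunk))
  res <- lapply(split(seq_along(t), id), function(ii) {
    if (length(ii) < min_chunk_n) return(NULL)
    if (diff(range(t[ii])) < 0.75 * chunk) return(NULL)
    ft <- stats::lm.fit(cbind(1, t[ii]), h[ii])
    c(slope = unname(ft$coefficients[2]), rss = sum(ft$residuals^2))
  })
  res <- do.call(rbind, Filter(Negate(is.null), res))
  if (is.null(res) || nrow(res) < 2) {
    return(structure(list(slope = 0, ok = FALSE, n_chunks = NROW(res),
                          chunks = res), class = "drift_estimate"))
  }
  ord <- order(res[, "rss"])
  kept <- ord[seq_len(max(1L, floor(nrow(res) / 2)))]
  structure(list(slope = mean(res[kept, "slope"]), ok = TRUE,
                 n_chunks = nrow(res), chunks = res),
            class = "drift_estimate")
}

#' @export
print.drift_estimate <- function(x, ...) {
  if (x$ok) {
    cat(sprintf("Residual drift: %.4g per s over %d chunks (lower half kept)\n",
                x$slope, x$n_chunks))
  } else cat("Residual drift: no estimate (history too short)\n")
  invisible(x)
}

#' Apply a residual-drift correction forward from a reference time
#' @param t timestamps, s.
#' @param x series to correct (same units as the history the estimate came
#'   from).
#' @param est a [estimate_residual_drift()] result (or a bare slope).
#' @param t_ref reference time (default first timestamp).
#' @return corrected series \code{x - slope * (t - t_ref)}.
#' @export
apply_drift_correction <- function(t, x, est, t_ref = t[1]) {
  slope <- if (inherits(est, "drift_estimate")) est$slope else est
  x - slope * (t - t_ref)
}

#' Drift-equivalent resampling factor
#'
#' Converts a distance-domain drift slope (cm/s) to the sampling drift factor
#' that [resample_with_drift()] would use to cancel it: apparent distance
#' drifts at \code{c * (alpha - 1)} m/s, so \code{alpha = 1 + slope/(100 c)}.
#' @param slope_cm_s drift slope, cm/s.
#' @param c speed of sound, m/s.
#' @export
drift_slope_to_alpha <- function(slope_cm_s, c = 343) {
  1 + slope_cm_s / (100 * c)
}
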
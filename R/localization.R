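# Distances -> 3-D position: calibration offsets, difference-based
# triangulation, IMU gating.

#' Calibrate per-speaker distance offsets
#'
#' The raw tracked distances carry a constant per-speaker offset (filter
#' residuals, electronics latency, phase-ambiguity lock). Calibration places
#' the wearable at a known reference position near the array, tracks for a
#' short static interval, and records \eqn{D_i} = mean raw reading minus the
#' true geometric distance, so that \eqn{d_i = \tilde d_i - D_i} is absolute.
#'
#' @param rec a [render_received()] recording of the static calibration
#'   interval (device at \code{reference_position}).
#' @param reference_position known device location, m (default 5 cm stand-off
#'   on the array axis).
#' @param cfg,array,clock_map,... passed to [track_distances()].
#' @param min_frames minimum number of valid frames required (default 10).
#' @return object of class \code{"calibration_offsets"}: list(D (named per
#'   speaker, m), reference_position, n_frames).
#' @export
calibrate <- function(rec, reference_position = c(0, 0, 0.05), cfg = NULL,
                      array = NULL, clock_map = NULL, min_frames = 10, ...) {
  if (is.null(cfg)) cfg <- rec$scene$cfg
  if (is.null(array)) array <- rec$scene$array
  if (!is.null(rec$imu) && any(rec$imu$motion)) {
    stop("motion detected during calibration; calibration rejected",
         call. = FALSE)
  }
  rt <- track_distances(rec, cfg = cfg, array = array, clock_map = clock_map,
                        ...)
  ok <- rt$valid
  stop_if_not(sum(ok) >= min_frames,
              "too few valid frames for calibration")
  true_d <- drop(speaker_distances(array, matrix(reference_position, 1)))
  dcols <- paste0("d", array$active)
  D <- vapply(seq_along(dcols),
              function(j) mean(rt[[dcols[j]]][ok]) - true_d[j], 0)
  names(D) <- dcols
  structure(list(D = D, reference_position = reference_position,
                 n_frames = sum(ok)),
            class = "calibration_offsets")
}

#' @export
print.calibration_offsets <- function(x, ...) {
  cat(sprintf("Calibration offsets from %d frames at (%.2f, %.2f, %.2f) m:\n",
              x$n_frames, x$reference_position[1], x$reference_position[2],
              x$reference_position[3]))
  print(round(x$D, 5))
  invisible(x)
}

#' Write / read calibration offsets as JSON
#' @param cal a \code{"calibration_offsets"}.
#' @param path JSON file.
#' @export
calibration_to_json <- function(cal, path = NULL) {
  x <- unclass(cal)
  x$D <- as.list(x$D)    # keep speaker names through JSON
  js <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}

#' @rdname calibration_to_json
#' @export
calibration_from_json <- function(path) {
  x <- jsonlite::fromJSON(path)
  structure(list(D = unlist(x$D), reference_position = x$reference_position,
                 n_frames = x$n_frames), class = "calibration_offsets")
}

#' Triangulate position from three absolute distances
#'
#' Difference-based far-field triangulation for the square array: with
#' \eqn{\bar d = (d_1+d_2+d_3)/3},
#' \deqn{X = \bar d\,(d_1-d_2)/L,\quad Y = \bar d\,(d_1-d_3)/L,\quad
#'       Z = \sqrt{\bar d^2 - X^2 - Y^2}.}
#' Speakers 1/2 form the x baseline and 1/3 the y baseline (see
#' [speaker_array()]). Frames with a negative radicand (geometrically
#' inconsistent distances) return NA and are flagged.
#'
#' The plane-wave approximation biases Z upward by roughly
#' \eqn{L^2/(4\,\mathrm{range})}; height *changes* cancel this bias to well
#' under a millimetre over clinical bed excursions.
#'
#' @param d1,d2,d3 absolute distances, m (vectors).
#' @param L adjacent-speaker separation, m.
#' @return data.frame(X, Y, Z, valid).
#' @export
triangulate <- function(d1, d2, d3, L) {
  dbar <- (d1 + d2 + d3) / 3
  X <- dbar * (d1 - d2) / L
  Y <- dbar * (d1 - d3) / L
  rad <- dbar^2 - X^2 - Y^2
  ok <- is.finite(rad) & rad >= 0 & dbar > 0
  Z <- ifelse(ok, sqrt(pmax(rad, 0)), NA_real_)
  data.frame(X = X, Y = Y, Z = Z, valid = ok)
}

#' Gate a height stream with IMU motion flags
#'
#' Disambiguates acoustic changes caused by occlusions from true height
#' changes: while the IMU reports no motion the output height is held
#' constant, whatever the acoustics say. When motion is flagged, tracking
#' resumes and continues until the height stabilizes — standard deviation
#' over the trailing \code{stability_window} below \code{stability_sd} with
#' no motion and no invalid frames in the window — at which point the mean
#' over the window is latched and the gate returns to idle.
#'
#' @param t frame timestamps, s.
#' @param z measured heights, m (NA or held values where invalid).
#' @param motion logical IMU motion flags per frame.
#' @param valid logical acoustic validity (occlusion) flags per frame.
#' @param stability_window s (default 2).
#' @param stability_sd m (default 0.003, i.e. 0.3 cm).
#' @return data.frame(t, z_gated, gate_state ("active"/"idle"), held).
#' @export
imu_gate <- function(t, z, motion, valid = rep(TRUE, length(t)),
                     stability_window = 2, stability_sd = 0.003) {
  n <- length(t)
  stop_if_not(length(z) == n && length(motion) == n && length(valid) == n,
              "streams must be time-aligned (equal length)")
  out <- numeric(n)
  state <- character(n)
  active <- TRUE
  hold <- NA_real_
  last <- NA_real_
  for (k in seq_len(n)) {
    if (!active && isTRUE(motion[k])) active <- TRUE
    if (active) {
      cur <- if (isTRUE(valid[k]) && is.finite(z[k])) z[k] else last
      out[k] <- cur
      last <- cur
      state[k] <- "active"
      win <- which(t > t[k] - stability_window & t <= t[k])
      if (length(win) >= 3 && t[k] - t[win[1]] >= 0.9 * stability_window &&
          !any(motion[win]) && all(valid[win]) && all(is.finite(z[win])) &&
          stats::sd(z[win]) < stability_sd) {
        hold <- mean(z[win])
        out[k] <- hold
        last <- hold
        active <- FALSE
        state[k] <- "idle"
      }
    } else {
      out[k] <- hold
      last <- hold
      state[k] <- "idle"
    }
  }
  data.frame(t = t, z_gated = out, gate_state = state,
             held = !(state == "active"))
}
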
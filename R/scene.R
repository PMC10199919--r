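#' Clock model for transmitter and receiver
#'
#' Both devices run free oscillators with a frequency tolerance of a few ppm;
#' the relative error accumulates as time offset (40 ppm relative error is
#' 2.4 ms of drift per minute). The transmitter broadcasts radio time-sync
#' beacons carrying the value of a free-running 16 MHz hardware timer that
#' wraps at \code{timer_max} ticks (~20 Hz wrap rate).
#'
#' @param ppm_tx transmitter clock error, ppm.
#' @param ppm_rx receiver clock error, ppm.
#' @param beacon_rate beacon rate, Hz (default 200).
#' @param timer_freq hardware timer frequency, Hz (default 16e6).
#' @param timer_max timer wrap value, ticks (default 800 000).
#' @param beacon_jitter_sd standard deviation of beacon arrival-time jitter, s
#'   (default 20 microseconds, radio scheduling granularity).
#' @return object of class \code{"clock_model"}.
#' @export
clock_model <- function(ppm_tx = 0, ppm_rx = 0, beacon_rate = 200,
                        timer_freq = 16e6, timer_max = 800000,
                        beacon_jitter_sd = 20e-6) {
  stop_if_not(abs(ppm_tx) <= 100 && abs(ppm_rx) <= 100,
              "clock error outside plausible ppm range")
  structure(list(ppm_tx = ppm_tx, ppm_rx = ppm_rx,
                 beacon_rate = beacon_rate, timer_freq = timer_freq,
                 timer_max = timer_max, beacon_jitter_sd = beacon_jitter_sd),
            class = "clock_model")
}

rate_tx <- function(clocks) 1 + clocks$ppm_tx * 1e-6
rate_rx <- function(clocks) 1 + clocks$ppm_rx * 1e-6

#' Device trajectory
#'
#' Piecewise-linear position knots plus an optional sinusoidal z modulation
#' emulating respiration-scale chest motion. The z axis points from the
#' speaker array toward the patient, so raising the bed decreases z.
#'
#' @param t_knots knot times, s.
#' @param pos_knots matrix (length(t_knots) x 3) of positions, m.
#' @param respiration_pp peak-to-peak amplitude of the respiration z
#'   modulation, m (default 0; a stated height variation of 0.5 cm means
#'   \code{respiration_pp = 0.005}, i.e. +/- 0.25 cm about the plateau).
#' @param respiration_rate respiration rate, Hz (default 0.25).
#' @return object of class \code{"device_trajectory"}.
#' @export
trajectory <- function(t_knots, pos_knots, respiration_pp = 0,
                       respiration_rate = 0.25) {
  pos_knots <- matrix(pos_knots, ncol = 3)
  stop_if_not(length(t_knots) == nrow(pos_knots), "knot length mismatch")
  stop_if_not(!is.unsorted(t_knots), "knot times must be nondecreasing")
  structure(list(t = t_knots, pos = pos_knots,
                 respiration_pp = respiration_pp,
                 respiration_rate = respiration_rate),
            class = "device_trajectory")
}

#' Static trajectory at a fixed position
#' @param position 3-vector (x, y, z), m.
#' @param ... passed to [trajectory()].
#' @export
static_trajectory <- function(position, ...) {
  trajectory(c(0, 1), rbind(position, position), ...)
}

#' Evaluate a trajectory
#' @param traj a [trajectory()].
#' @param t times, s.
#' @param respiration include the respiration modulation (default TRUE).
#' @return matrix length(t) x 3 of positions, m.
#' @export
traj_position <- function(traj, t, respiration = TRUE) {
  p <- cbind(interp_knots(traj$t, traj$pos[, 1], t),
             interp_knots(traj$t, traj$pos[, 2], t),
             interp_knots(traj$t, traj$pos[, 3], t))
  if (respiration && traj$respiration_pp > 0) {
    p[, 3] <- p[, 3] + traj$respiration_pp / 2 *
      sin(2 * pi * traj$respiration_rate * t)
  }
  colnames(p) <- c("x", "y", "z")
  p
}

#' Scripted bed-height session trajectory
#'
#' Emulates the clinical protocol: the bed dwells at a sequence of heights
#' (cm above the starting height) with smooth raised-cosine transitions.
#' Raising the bed moves the wearable toward the array (z decreases).
#'
#' @param levels_cm bed heights relative to the first level, cm; must lie
#'   within \[0, 50\] cm of the start.
#' @param dwell dwell time per level, s.
#' @param transition transition time between levels, s.
#' @param start_pos device position at the first level, m (default
#'   c(0.03, -0.02, 1.2)).
#' @param respiration_pp,respiration_rate see [trajectory()].
#' @return a [trajectory()] whose knots trace the plateaus; attribute
#'   \code{"plateaus"} holds a data.frame (level_cm, t_start, t_end) of the
#'   dwell intervals.
#' @export
scripted_bed_session <- function(levels_cm, dwell = 8, transition = 2,
                                 start_pos = c(0.03, -0.02, 1.2),
                                 respiration_pp = 0.005,
                                 respiration_rate = 0.25) {
  stop_if_not(dwell > 0, "negative or zero dwell")
  stop_if_not(all(levels_cm >= -1e-9 & levels_cm <= 50),
              "levels must lie within [0, 50] cm of the start height")
  n <- length(levels_cm)
  t_cur <- 0
  tt <- c(); zz <- c()
  plat <- data.frame(level_cm = levels_cm, t_start = NA_real_, t_end = NA_real_)
  for (k in seq_len(n)) {
    z_k <- start_pos[3] - levels_cm[k] / 100
    plat$t_start[k] <- t_cur
    tt <- c(tt, t_cur, t_cur + dwell)
    zz <- c(zz, z_k, z_k)
    plat$t_end[k] <- t_cur + dwell
    t_cur <- t_cur + dwell
    if (k < n) {
      # raised-cosine ramp sampled densely so the acceleration profile is
      # smooth for the accelerometer model
      z_next <- start_pos[3] - levels_cm[k + 1] / 100
      tau <- seq(0, transition, by = 0.05)
      s <- (1 - cos(pi * tau / transition)) / 2
      tt <- c(tt, t_cur + tau[-c(1, length(tau))])
      zz <- c(zz, z_k + (z_next - z_k) * s[-c(1, length(s))])
      t_cur <- t_cur + transition
    }
  }
  tr <- trajectory(tt, cbind(start_pos[1], start_pos[2], zz),
                   respiration_pp = respiration_pp,
                   respiration_rate = respiration_rate)
  attr(tr, "plateaus") <- plat
  tr
}

#' Acoustic scene description
#'
#' Bundles everything the renderer needs: array geometry, chirp parameters,
#' device trajectory, propagation paths, noise level, and clock models.
#' Body multipath is specified per reflection as an excess path length over
#' the direct path (the reflection rides along with the device) and a relative
#' amplitude; distant multipath as a fixed absolute path length and amplitude.
#' The direct path must dominate the summed body multipath unless an
#' occlusion interval is scripted.
#'
#' @param array a [speaker_array()].
#' @param cfg a [chirp_config()].
#' @param traj a [trajectory()].
#' @param body_paths data.frame with columns \code{excess} (m) and
#'   \code{rel_amp}, applied to every active speaker; or NULL.
#' @param distant_paths data.frame with columns \code{dist} (m) and
#'   \code{rel_amp}; or NULL.
#' @param noise_snr_db per-speaker direct-path SNR of the additive white
#'   Gaussian noise, dB; \code{Inf} disables noise.
#' @param clocks a [clock_model()].
#' @param c speed of sound, m/s (default 343).
#' @param clothing_db extra attenuation applied to the direct path, dB
#'   (positive attenuates).
#' @param occlusion NULL or list(t0, t1, factor): multiply the direct path
#'   amplitude by \code{factor} during \[t0, t1\].
#' @param tones optional data.frame(freq, amp) of environmental tonal
#'   interferers (alarms) added outside the chirp band.
#' @param direct_amp amplitude of each direct path before clothing loss.
#' @return object of class \code{"acoustic_scene"}.
#' @export
acoustic_scene <- function(array, cfg, traj, body_paths = NULL,
                           distant_paths = NULL, noise_snr_db = Inf,
                           clocks = clock_model(), c = 343,
                           clothing_db = 0, occlusion = NULL, tones = NULL,
                           direct_amp = 1) {
  stop_if_not(is.finite(noise_snr_db) || is.infinite(noise_snr_db),
              "SNR specification non-finite")
  if (!is.null(body_paths)) {
    stop_if_not(all(body_paths$excess > 0), "body-path excess must be > 0")
    stop_if_not(sum(body_paths$rel_amp) < 1,
                "summed body multipath must stay below the direct path")
  }
  structure(list(array = array, cfg = cfg, traj = traj,
                 body_paths = body_paths, distant_paths = distant_paths,
                 noise_snr_db = noise_snr_db, clocks = clocks, c = c,
                 clothing_db = clothing_db, occlusion = occlusion,
                 tones = tones, direct_amp = direct_amp),
            class = "acoustic_scene")
}

#' @export
print.acoustic_scene <- function(x, ...) {
  cat("Acoustic scene\n")
  print(x$array)
  print(x$cfg)
  cat(sprintf("noise SNR %s dB; clocks %+g/%+g ppm; clothing %.1f dB\n",
              format(x$noise_snr_db), x$clocks$ppm_tx, x$clocks$ppm_rx,
              x$clothing_db))
  cat(sprintf("%d body path(s), %d distant path(s)\n",
              NROW(x$body_paths), NROW(x$distant_paths)))
  invisible(x)
}

#' Scene configuration to/from JSON
#'
#' Serializes the scene description (not the rendered audio) with a flat,
#' documented schema so scenes can be scripted from the command line.
#' @param scene an [acoustic_scene()].
#' @param path output file; if NULL the JSON string is returned.
#' @export
scene_to_json <- function(scene, path = NULL) {
  x <- list(
    array = list(L = scene$array$L, active = scene$array$active),
    chirp = unclass(scene$cfg)[c("f0", "f1", "T_chirp", "n_speakers",
                                 "shift_fraction", "fs")],
    trajectory = list(t = scene$traj$t, pos = scene$traj$pos,
                      respiration_pp = scene$traj$respiration_pp,
                      respiration_rate = scene$traj$respiration_rate),
    body_paths = scene$body_paths, distant_paths = scene$distant_paths,
    noise_snr_db = if (is.finite(scene$noise_snr_db)) scene$noise_snr_db else "Inf",
    clocks = unclass(scene$clocks), c = scene$c,
    clothing_db = scene$clothing_db, occlusion = scene$occlusion,
    tones = scene$tones, direct_amp = scene$direct_amp)
  js <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, null = "null")
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}

#' @rdname scene_to_json
#' @export
scene_from_json <- function(path) {
  x <- jsonlite::fromJSON(path)
  acoustic_scene(
    array = speaker_array(x$array$L, x$array$active),
    cfg = do.call(chirp_config, x$chirp),
    traj = trajectory(x$trajectory$t, matrix(unlist(x$trajectory$pos), ncol = 3),
                      respiration_pp = x$trajectory$respiration_pp,
                      respiration_rate = x$trajectory$respiration_rate),
    body_paths = x$body_paths, distant_paths = x$distant_paths,
    noise_snr_db = if (identical(x$noise_snr_db, "Inf")) Inf else x$noise_snr_db,
    clocks = do.call(clock_model, x$clocks),
    c = x$c, clothing_db = x$clothing_db, occlusion = x$occlusion,
    tones = x$tones, direct_amp = x$direct_amp)
}
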
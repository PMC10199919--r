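# Scene renderer: what the wearable microphone records.

#' Simulate radio time-sync beacons
#'
#' The transmitter emits beacons at \code{beacon_rate} on its own clock; each
#' carries its free-running 16 MHz timer value (wrapped at \code{timer_max}).
#' The receiver stamps each arrival with its own wrapped timer. Arrival-time
#' jitter models radio scheduling granularity; propagation time is neglected
#' (radio, not acoustic).
#'
#' @param clocks a [clock_model()].
#' @param duration session length, s (true time).
#' @param seed RNG seed for the jitter.
#' @return data.frame(t_true, tx_ticks, rx_ticks).
#' @export
simulate_beacons <- function(clocks, duration, seed = 1) {
  stop_if_not(duration > 0, "duration must be positive")
  # start one interval in so jitter cannot push an arrival before time zero
  tau_tx <- seq(1 / clocks$beacon_rate, duration * rate_tx(clocks),
                by = 1 / clocks$beacon_rate)
  t_true <- tau_tx / rate_tx(clocks)
  jit <- with_seed(seed, stats::rnorm(length(t_true), 0,
                                      clocks$beacon_jitter_sd))
  t_arr <- t_true + jit
  tau_rx <- t_arr * rate_rx(clocks)
  data.frame(
    t_true = t_true,
    tx_ticks = floor(tau_tx * clocks$timer_freq) %% clocks$timer_max,
    rx_ticks = floor(tau_rx * clocks$timer_freq) %% clocks$timer_max)
}

# direct-path distances from every speaker to positions p (n x 3)
speaker_distances <- function(array, p) {
  sp <- array$positions[array$active, , drop = FALSE]
  d <- sapply(seq_len(nrow(sp)), function(j) {
    sqrt((p[, 1] - sp[j, 1])^2 + (p[, 2] - sp[j, 2])^2 +
           (p[, 3] - sp[j, 3])^2)
  })
  matrix(d, ncol = nrow(sp))
}

#' Render the received waveform for a scene
#'
#' Evaluates, sample by sample on the receiver's (drifted) clock, the sum over
#' speakers and propagation paths of attenuated, delayed copies of the
#' periodic transmit chirps, plus white Gaussian noise scaled to the requested
#' per-speaker direct-path SNR. Delays are applied in continuous time through
#' the closed-form chirp phase, so sub-sample delay fidelity is exact.
#'
#' @param scene an [acoustic_scene()].
#' @param duration recording length, s (receiver nominal time); at least one
#'   chirp period.
#' @param seed RNG seed; identical seeds give bit-identical output.
#' @return object of class \code{"scene_recording"}: list with \code{x}
#'   (waveform), \code{fs}, \code{truth} (per-frame ground truth positions),
#'   \code{imu} (accelerometer stream with motion flags), \code{beacons},
#'   \code{noise_sd}, and the \code{scene}.
#' @export
render_received <- function(scene, duration, seed = 1) {
  cfg <- scene$cfg
  stop_if_not(duration >= cfg$T_chirp, "duration shorter than one chirp")
  clocks <- scene$clocks
  n <- floor(duration * cfg$fs)
  active <- scene$array$active
  amp_direct <- scene$direct_amp * db_to_lin(-scene$clothing_db)

  # noise level from the per-speaker direct-path power
  sigma <- if (is.finite(scene$noise_snr_db)) {
    sqrt((amp_direct^2 / 2) / 10^(scene$noise_snr_db / 10))
  } else 0

  x <- numeric(n)
  chunk <- 2^20L
  starts <- seq(0L, n - 1L, by = chunk)
  for (s0 in starts) {
    idx <- s0:min(s0 + chunk - 1L, n - 1L)
    t_true <- (idx / cfg$fs) / rate_rx(clocks)
    p <- traj_position(scene$traj, t_true)
    dmat <- speaker_distances(scene$array, p)
    a_dir <- rep(amp_direct, length(idx))
    if (!is.null(scene$occlusion)) {
      occ <- t_true >= scene$occlusion$t0 & t_true <= scene$occlusion$t1
      a_dir[occ] <- a_dir[occ] * scene$occlusion$factor
    }
    acc <- numeric(length(idx))
    for (j in seq_along(active)) {
      i <- active[j]
      d_dir <- dmat[, j]
      tau_emit <- (t_true - d_dir / scene$c) * rate_tx(clocks)
      acc <- acc + a_dir * Re(chirp_wave_at(tau_emit, i, cfg))
      if (!is.null(scene$body_paths)) {
        for (b in seq_len(nrow(scene$body_paths))) {
          tau_b <- (t_true - (d_dir + scene$body_paths$excess[b]) / scene$c) *
            rate_tx(clocks)
          acc <- acc + amp_direct * scene$body_paths$rel_amp[b] *
            Re(chirp_wave_at(tau_b, i, cfg))
        }
      }
      if (!is.null(scene$distant_paths)) {
        for (b in seq_len(nrow(scene$distant_paths))) {
          tau_b <- (t_true - scene$distant_paths$dist[b] / scene$c) *
            rate_tx(clocks)
          acc <- acc + amp_direct * scene$distant_paths$rel_amp[b] *
            Re(chirp_wave_at(tau_b, i, cfg))
        }
      }
    }
    if (!is.null(scene$tones)) {
      for (b in seq_len(nrow(scene$tones))) {
        acc <- acc + scene$tones$amp[b] *
          sin(2 * pi * scene$tones$freq[b] * t_true)
      }
    }
    x[idx + 1L] <- acc
  }
  if (sigma > 0) {
    x <- x + with_seed(seed, stats::rnorm(n, 0, sigma))
  }

  # ground truth at chirp-frame centres (frames counted on the tx clock)
  t_true_end <- (n / cfg$fs) / rate_rx(clocks)
  n_frames <- floor(t_true_end * rate_tx(clocks) / cfg$T_chirp)
  t_frames <- ((seq_len(n_frames) - 0.5) * cfg$T_chirp) / rate_tx(clocks)
  pos <- traj_position(scene$traj, t_frames)
  truth <- data.frame(frame = seq_len(n_frames), t = t_frames,
                      x = pos[, 1], y = pos[, 2], z = pos[, 3])

  imu <- imu_stream(scene$traj, t_frames)
  beacons <- simulate_beacons(clocks, t_true_end, seed = seed + 7919L)

  structure(list(x = x, fs = cfg$fs, truth = truth, imu = imu,
                 beacons = beacons, noise_sd = sigma, scene = scene),
            class = "scene_recording")
}

# Accelerometer surrogate: z acceleration by central differences of the
# trajectory (respiration excluded: its acceleration is micro-g scale), motion
# flag = |az| above the wake threshold, latched across zero crossings within
# a transition (gap closing <= 0.5 s).
imu_stream <- function(traj, t, wake_threshold = 0.05) {
  if (length(t) < 3) {
    return(data.frame(t = t, az = 0, motion = FALSE))
  }
  z <- traj_position(traj, t, respiration = FALSE)[, 3]
  dt <- diff(t[1:2])
  az <- c(0, diff(z, differences = 2), 0) / dt^2
  flag <- abs(az) > wake_threshold
  gap <- max(1L, round(0.5 / dt))
  idx <- which(flag)
  if (length(idx) > 1) {
    for (k in seq_len(length(idx) - 1)) {
      if (idx[k + 1] - idx[k] <= gap) flag[idx[k]:idx[k + 1]] <- TRUE
    }
  }
  data.frame(t = t, az = az, motion = flag)
}

#' @export
print.scene_recording <- function(x, ...) {
  cat(sprintf("Scene recording: %.1f s at %.0f Hz (%d frames, noise sd %.3g)\n",
              length(x$x) / x$fs, x$fs, nrow(x$truth), x$noise_sd))
  invisible(x)
}

#' Write a rendered scene to a directory
#'
#' Produces the on-disk interchange layout: \code{received.wav} (float32),
#' \code{truth.csv}, \code{imu.csv}, \code{beacons.csv}, \code{scene.json}.
#'
#' @param rec a [render_received()] result.
#' @param dir output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
write_scene_recording <- function(rec, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_wav(rec$x, file.path(dir, "received.wav"), fs = rec$fs,
            type = "float32")
  utils::write.csv(rec$truth, file.path(dir, "truth.csv"), row.names = FALSE)
  utils::write.csv(rec$imu, file.path(dir, "imu.csv"), row.names = FALSE)
  utils::write.csv(rec$beacons, file.path(dir, "beacons.csv"),
                   row.names = FALSE)
  scene_to_json(rec$scene, file.path(dir, "scene.json"))
  invisible(dir)
}

#' Read a scene directory written by [write_scene_recording()]
#' @param dir directory path.
#' @return a \code{"scene_recording"} (without \code{noise_sd}).
#' @export
read_scene_recording <- function(dir) {
  wav <- read_wav(file.path(dir, "received.wav"))
  structure(list(
    x = wav$x, fs = wav$fs,
    truth = utils::read.csv(file.path(dir, "truth.csv")),
    imu = utils::read.csv(file.path(dir, "imu.csv")),
    beacons = utils::read.csv(file.path(dir, "beacons.csv")),
    noise_sd = NA_real_,
    scene = scene_from_json(file.path(dir, "scene.json"))),
    class = "scene_recording")
}
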
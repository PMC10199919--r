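#' Run the full height-tracking pipeline
#'
#' The complete chain from a recording to a gated height track: beacon clock
#' alignment, per-speaker distance tracking, calibration-offset subtraction,
#' residual-drift regression correction (applied to each per-speaker
#' distance), triangulation, and IMU gating. The result carries the height
#' change from session start, \code{h_cm}, defined upward-positive (the
#' z axis points from the array down toward the patient, so a rising bed
#' decreases Z).
#'
#' @param rec a [render_received()] recording (or [read_scene_recording()]).
#' @param calibration a [calibrate()] result; NULL assumes zero offsets.
#' @param cfg,array defaults from the recording's scene.
#' @param clock_map "auto" (align from the recording's beacon log), NULL
#'   (identity / unsynchronized), or a \code{"clock_map"}.
#' @param drift_correct apply [estimate_residual_drift()] per speaker
#'   (default TRUE).
#' @param drift_window,drift_chunk window and chunk lengths, s, for the
#'   regression stage.
#' @param ... further arguments to [track_distances()].
#' @return object of class \code{"height_track"}: data.frame(frame, t, X, Y,
#'   Z, z_gated, h_cm, gate_state, valid, reliable) with attributes
#'   \code{range_track}, \code{clock_map}, \code{calibration},
#'   \code{drift_estimates}, \code{z_ref}.
#' @export
run_tracker <- function(rec, calibration = NULL, cfg = NULL, array = NULL,
                        clock_map = "auto", drift_correct = TRUE,
                        drift_window = 300, drift_chunk = 30, ...) {
  if (is.null(cfg)) cfg <- rec$scene$cfg
  if (is.null(array)) array <- rec$scene$array
  if (identical(clock_map, "auto")) {
    clock_map <- if (!is.null(rec$beacons) && nrow(rec$beacons) >= 2) {
      beacon_align(rec$beacons, rec$scene$clocks)
    } else identity_clock_map()
  }
  rt <- track_distances(rec, cfg = cfg, array = array, clock_map = clock_map,
                        ...)
  dcols <- paste0("d", array$active)
  d <- as.matrix(as.data.frame(rt)[dcols])
  if (!is.null(calibration)) {
    d <- sweep(d, 2, calibration$D[dcols])
  }

  motion_frames <- if (!is.null(rec$imu)) {
    stats::approx(rec$imu$t, as.numeric(rec$imu$motion), xout = rt$t,
                  method = "constant", rule = 2)$y > 0.5
  } else rep(FALSE, nrow(rt))

  drifts <- NULL
  if (drift_correct) {
    ok <- rt$valid & rowSums(is.na(d)) == 0
    drifts <- lapply(seq_len(ncol(d)), function(j) {
      if (sum(ok) < 20) return(NULL)
      est <- estimate_residual_drift(rt$t[ok], d[ok, j],
                                     window = drift_window,
                                     chunk = drift_chunk,
                                     motion = motion_frames[ok])
      if (est$ok) {
        d[, j] <<- apply_drift_correction(rt$t, d[, j], est,
                                          t_ref = rt$t[ok][1])
      }
      est
    })
    names(drifts) <- dcols
  }

  tri <- triangulate(d[, 1], d[, 2], d[, 3], array$L)
  valid <- rt$valid & tri$valid
  g <- imu_gate(rt$t, tri$Z, motion_frames, valid)

  # reference height: first latched (stable) value, else first valid frames
  first_hold <- which(g$held)[1]
  z_ref <- if (!is.na(first_hold)) g$z_gated[first_hold] else {
    mean(tri$Z[valid][seq_len(min(20, sum(valid)))])
  }
  h_cm <- (z_ref - g$z_gated) * 100

  # invalid for more than 5 s in a row -> mark unreliable
  reliable <- rep(TRUE, nrow(rt))
  r <- rle(!valid)
  ends <- cumsum(r$lengths)
  frame_dt <- stats::median(diff(rt$t))
  for (i in which(r$values & r$lengths * frame_dt > 5)) {
    reliable[(ends[i] - r$lengths[i] + 1):ends[i]] <- FALSE
  }

  out <- data.frame(frame = rt$frame, t = rt$t, X = tri$X, Y = tri$Y,
                    Z = tri$Z, z_gated = g$z_gated, h_cm = h_cm,
                    gate_state = g$gate_state, valid = valid,
                    reliable = reliable)
  colnames(d) <- dcols
  structure(out, class = c("height_track", "data.frame"),
            range_track = rt, clock_map = clock_map,
            calibration = calibration, drift_estimates = drifts,
            d_abs = d, z_ref = z_ref)
}

#' @export
print.height_track <- function(x, ...) {
  cat(sprintf("Height track: %d frames over %.1f s, %.0f%% valid\n",
              nrow(x), max(x$t) - min(x$t), 100 * mean(x$valid)))
  cat(sprintf("  Z: median %.4f m; h: %.2f to %.2f cm from start\n",
              stats::median(x$Z, na.rm = TRUE),
              min(x$h_cm, na.rm = TRUE), max(x$h_cm, na.rm = TRUE)))
  invisible(x)
}

#' @export
summary.height_track <- function(object, ...) {
  cm <- attr(object, "clock_map")
  out <- list(
    n_frames = nrow(object), duration = max(object$t) - min(object$t),
    frac_valid = mean(object$valid),
    z_median = stats::median(object$Z, na.rm = TRUE),
    h_range_cm = range(object$h_cm, na.rm = TRUE),
    drift_ppm = if (!is.null(cm)) (cm$alpha - 1) * 1e6 else NA_real_)
  class(out) <- "summary.height_track"
  out
}

#' @export
print.summary.height_track <- function(x, ...) {
  cat(sprintf("Frames: %d (%.1f s), %.0f%% valid; clock drift %.2f ppm\n",
              x$n_frames, x$duration, 100 * x$frac_valid, x$drift_ppm))
  cat(sprintf("Median Z %.4f m; height change %.2f..%.2f cm\n",
              x$z_median, x$h_range_cm[1], x$h_range_cm[2]))
  invisible(x)
}

#' @export
plot.height_track <- function(x, ...) {
  graphics::par(mfrow = c(2, 1), mar = c(4, 4, 1, 1))
  graphics::plot(x$t, x$Z, type = "l", col = "grey60", xlab = "time (s)",
                 ylab = "Z (m)", ...)
  graphics::lines(x$t, x$z_gated, col = "firebrick", lwd = 2)
  graphics::legend("topright", c("raw", "gated"), lwd = c(1, 2),
                   col = c("grey60", "firebrick"), bty = "n")
  graphics::plot(x$t, x$h_cm, type = "l", xlab = "time (s)",
                 ylab = "height change (cm)")
  invisible(x)
}

#' Write a height track as CSV
#' @param ht a \code{"height_track"}.
#' @param path CSV file.
#' @export
write_height_track <- function(ht, path) {
  utils::write.csv(as.data.frame(ht), path, row.names = FALSE)
  invisible(path)
}

#' Per-plateau height changes from a tracked bed session
#'
#' Averages the gated height over each scripted dwell interval (trimmed at
#' both ends) and returns the height change of each plateau relative to the
#' first — the automated counterpart of the laser-tool height differences.
#'
#' @param ht a [run_tracker()] result.
#' @param plateaus data.frame(level_cm, t_start, t_end), e.g. the
#'   \code{"plateaus"} attribute of [scripted_bed_session()].
#' @param trim seconds trimmed from each end of a dwell (default 2).
#' @return data.frame(level_cm, h_cm, delta_h_cm, delta_h_true_cm).
#' @export
plateau_heights <- function(ht, plateaus, trim = 2) {
  h <- vapply(seq_len(nrow(plateaus)), function(k) {
    sel <- ht$t >= plateaus$t_start[k] + trim &
      ht$t <= plateaus$t_end[k] - trim / 2
    mean(ht$h_cm[sel])
  }, 0)
  data.frame(level_cm = plateaus$level_cm, h_cm = h,
             delta_h_cm = h - h[1],
             delta_h_true_cm = plateaus$level_cm - plateaus$level_cm[1])
}
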
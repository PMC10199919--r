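# Evaluation studies mirroring the bench and clinical protocols: static
# accuracy sweep, long-run drift ladder, scripted bed session with pressure
# correction.

default_clocks <- function(jitter = 20e-6) {
  clock_model(ppm_tx = -20, ppm_rx = 20, beacon_jitter_sd = jitter)
}

#' Render and calibrate a reference recording
#'
#' Static recording at the calibration stand-off used to estimate the
#' per-speaker offsets shared by a study's scenes.
#' @param cfg,array chirp configuration and speaker array.
#' @param clocks a [clock_model()].
#' @param snr_db calibration SNR (high: the device sits at the array).
#' @param duration s.
#' @param seed RNG seed.
#' @return a [calibrate()] result.
#' @export
calibration_run <- function(cfg = chirp_config(), array = speaker_array(),
                            clocks = default_clocks(), snr_db = 30,
                            duration = 2, seed = 1) {
  ref_pos <- c(0, 0, 0.05)
  sc <- acoustic_scene(array, cfg, static_trajectory(ref_pos),
                       noise_snr_db = snr_db, clocks = clocks)
  rec <- render_received(sc, duration, seed = seed)
  cmap <- beacon_align(rec$beacons, clocks)
  calibrate(rec, reference_position = ref_pos, clock_map = cmap)
}

#' Static-position accuracy sweep
#'
#' Places the device at seeded random positions 0.2–2 m from the array (small
#' lateral offsets, as over a bed), with one body-multipath reflection per
#' speaker (relative amplitude up to \code{rel_amp_max}, excess path
#' 5–20 cm), additive noise at 15–25 dB SNR, and 40 ppm relative clock drift
#' corrected via 200 Hz beacons. Each scene is tracked through the full
#' pipeline and the per-axis errors of the time-averaged position are
#' recorded.
#'
#' @param n_scenes number of scenes (default 100).
#' @param seed RNG seed.
#' @param duration per-scene recording length, s (default 4; the first second
#'   is warm-up).
#' @param rel_amp_max body-reflection relative amplitude cap (default 0.5).
#' @param cfg,array chirp configuration and speaker array.
#' @param calibration shared [calibrate()] result (computed if NULL).
#' @return data.frame with true and estimated coordinates and absolute
#'   per-axis errors (m) per scene.
#' @export
static_sweep <- function(n_scenes = 100, seed = 1, duration = 4,
                         rel_amp_max = 0.5, cfg = chirp_config(),
                         array = speaker_array(), calibration = NULL) {
  clocks <- default_clocks()
  if (is.null(calibration)) {
    calibration <- calibration_run(cfg, array, clocks, seed = seed)
  }
  draws <- with_seed(seed, {
    r <- stats::runif(n_scenes, 0.2, 2)
    # lateral placement up to bed scale (but within the field of view)
    data.frame(r = r,
               x = stats::runif(n_scenes, -1, 1) * pmin(0.3, 0.45 * r),
               y = stats::runif(n_scenes, -1, 1) * pmin(0.3, 0.45 * r),
               snr = stats::runif(n_scenes, 15, 25),
               rel1 = stats::runif(n_scenes, 0.1, rel_amp_max),
               ex1 = stats::runif(n_scenes, 0.05, 0.2))
  })
  rows <- lapply(seq_len(n_scenes), function(i) {
    x <- draws$x[i]; y <- draws$y[i]
    z <- sqrt(max(draws$r[i]^2 - x^2 - y^2, 0.01))
    body <- data.frame(excess = draws$ex1[i], rel_amp = draws$rel1[i])
    sc <- acoustic_scene(array, cfg, static_trajectory(c(x, y, z)),
                         body_paths = body, noise_snr_db = draws$snr[i],
                         clocks = clocks)
    rec <- render_received(sc, duration, seed = (seed * 1009L + i) %% 2^30)
    ht <- run_tracker(rec, calibration = calibration)
    sel <- ht$valid & ht$t > 1
    data.frame(scene = i, x = x, y = y, z = z, snr_db = draws$snr[i],
               X = mean(ht$X[sel]), Y = mean(ht$Y[sel]),
               Z = mean(ht$Z[sel]), n_frames = sum(sel))
  })
  out <- do.call(rbind, rows)
  out$err_x <- abs(out$X - out$x)
  out$err_y <- abs(out$Y - out$y)
  out$err_z <- abs(out$Z - out$z)
  out
}

#' Long-run drift ladder
#'
#' Renders one long static scene with 40 ppm relative clock drift and
#' measures the accumulated apparent drift of the first speaker's 1-D
#' distance under three corrections: none, beacon alignment, and beacon
#' alignment plus the 30-s-chunk regression post-processing. Drift is the
#' difference between the mean distance over the final and initial
#' \code{edge} seconds. (The first speaker's distance is used because under
#' fully uncorrected 40 ppm drift the later speakers' apparent delays leave
#' their chirp period within ten minutes.)
#'
#' @param seed RNG seed.
#' @param duration scene length, s (default 600).
#' @param edge averaging span at each end, s (default 30).
#' @param cfg,array chirp configuration and speaker array.
#' @return list(raw_cm, synced_cm, post_cm, tracks).
#' @export
drift_ladder <- function(seed = 1, duration = 600, edge = 30,
                         cfg = chirp_config(), array = speaker_array()) {
  clocks <- default_clocks()
  sc <- acoustic_scene(array, cfg, static_trajectory(c(0.02, -0.01, 1.0)),
                       body_paths = data.frame(excess = 0.1, rel_amp = 0.3),
                       noise_snr_db = 20, clocks = clocks)
  rec <- render_received(sc, duration, seed = seed)
  rec$xa <- analytic_signal(rec$x)

  accum <- function(ht) {
    t <- ht$t
    v <- attr(ht, "d_abs")[, 1]
    ok <- is.finite(v)
    a <- v[ok & t <= min(t) + edge]
    b <- v[ok & t >= max(t) - edge]
    abs(mean(b) - mean(a)) * 100
  }

  ht_raw <- run_tracker(rec, clock_map = NULL, drift_correct = FALSE)
  ht_sync <- run_tracker(rec, clock_map = "auto", drift_correct = FALSE)
  ht_post <- run_tracker(rec, clock_map = "auto", drift_correct = TRUE)
  list(raw_cm = accum(ht_raw),
       synced_cm = accum(ht_sync),
       post_cm = accum(ht_post),
       tracks = list(raw = ht_raw, synced = ht_sync, post = ht_post))
}

#' Scripted bed session with pressure correction
#'
#' Runs the clinical-protocol analogue end to end: a bed stepping through the
#' given heights (default 0–45 cm in 5 cm steps) with respiration-scale chest
#' motion, tracked acoustically; per-plateau height changes feed the
#' hydrostatic MAP correction of a simulated stationary transducer.
#'
#' @param seed RNG seed.
#' @param levels_cm plateau heights, cm (default seq(0, 45, 5)).
#' @param dwell s per plateau (default 10).
#' @param noise_sd transducer device noise, mmHg (default 0).
#' @param cfg,array chirp configuration and speaker array.
#' @param calibration shared calibration (computed if NULL).
#' @return list(plateaus, session, height_track): per-plateau tracked
#'   heights and step errors, and the corrected-pressure session with
#'   \code{MAP_corr} vs \code{MAP_true}.
#' @export
bed_session_benchmark <- function(seed = 1, levels_cm = seq(0, 45, 5),
                                  dwell = 10, noise_sd = 0,
                                  cfg = chirp_config(),
                                  array = speaker_array(),
                                  calibration = NULL) {
  clocks <- default_clocks()
  if (is.null(calibration)) {
    calibration <- calibration_run(cfg, array, clocks, seed = seed)
  }
  traj <- scripted_bed_session(levels_cm, dwell = dwell)
  plat <- attr(traj, "plateaus")
  sc <- acoustic_scene(array, cfg, traj,
                       body_paths = data.frame(excess = 0.08, rel_amp = 0.3),
                       noise_snr_db = 20, clocks = clocks)
  rec <- render_received(sc, max(traj$t) + 0.5, seed = seed)
  ht <- run_tracker(rec, calibration = calibration)
  ph <- plateau_heights(ht, plat)
  ph$step_cm <- c(NA, diff(ph$delta_h_cm))
  ph$step_true_cm <- c(NA, diff(ph$delta_h_true_cm))

  session <- simulate_pressure_session(ph$delta_h_true_cm,
                                       noise_sd = noise_sd, seed = seed)
  session <- correct_pressure_session(session, ph$delta_h_cm)
  list(plateaus = ph, session = session, height_track = ht)
}

#' Run the full benchmark suite
#'
#' Static sweep, drift ladder and bed-session pipeline with one seed;
#' optionally writes per-study CSVs and a JSON summary.
#'
#' @param seed RNG seed.
#' @param out_dir output directory, or NULL for no files.
#' @param n_static scenes in the static sweep.
#' @param ladder_duration drift-ladder scene length, s.
#' @return list(static, ladder, bed, summary).
#' @export
benchmark_suite <- function(seed = 1, out_dir = NULL, n_static = 100,
                            ladder_duration = 600) {
  st <- static_sweep(n_static, seed = seed)
  ld <- drift_ladder(seed = seed, duration = ladder_duration)
  bd <- bed_session_benchmark(seed = seed)
  summary <- list(
    static_median_err_z_cm = stats::median(st$err_z) * 100,
    static_median_err_x_cm = stats::median(st$err_x) * 100,
    static_median_err_y_cm = stats::median(st$err_y) * 100,
    drift_raw_cm = ld$raw_cm, drift_synced_cm = ld$synced_cm,
    drift_post_cm = ld$post_cm,
    bed_max_step_err_cm = max(abs(bd$plateaus$step_cm -
                                    bd$plateaus$step_true_cm), na.rm = TRUE),
    bed_max_map_err_mmHg = max(abs(bd$session$MAP_corr - bd$session$MAP_true)))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(st, file.path(out_dir, "static_sweep.csv"),
                     row.names = FALSE)
    utils::write.csv(bd$plateaus, file.path(out_dir, "bed_plateaus.csv"),
                     row.names = FALSE)
    utils::write.csv(bd$session, file.path(out_dir, "bed_session.csv"),
                     row.names = FALSE)
    writeLines(jsonlite::toJSON(summary, auto_unbox = TRUE, digits = NA),
               file.path(out_dir, "summary.json"))
  }
  list(static = st, ladder = ld, bed = bd, summary = summary)
}
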
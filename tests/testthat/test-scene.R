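test_that("single direct path delays the chirp by distance over c", {
  sc <- quick_scene(pos = c(0, 0, 1), L = 1e-6)  # co-located speakers
  rec <- render_received(sc, 0.5, seed = 1)
  cfg <- sc$cfg
  tx <- Re(generate_chirp(1, cfg))
  # circular cross-correlation over one period
  frame <- rec$x[(2 * cfg$n_frame + 1):(3 * cfg$n_frame)]
  X <- stats::fft(frame) * Conj(stats::fft(tx))
  cc <- Re(stats::fft(X, inverse = TRUE))
  lag <- which.max(cc) - 1
  expect_equal(lag, round(cfg$fs / 343))   # 2.915 ms at one-sample precision
})

test_that("dechirped spectrum separates two paths by their beat offset", {
  cfg <- chirp_config()
  sc <- quick_scene(pos = c(0, 0, 1),
                    body = data.frame(excess = 0.5, rel_amp = 0.3))
  rec <- render_received(sc, 0.5, seed = 1)
  frame <- rec$x[(2 * cfg$n_frame + 1):(3 * cfg$n_frame)]
  ds <- dechirp_and_separate(frame, cfg, active = 1)
  # windowed DFT oracle: second peak (B/T) * (0.5/343) above the direct
  sep_expect <- beat_freq(0.5 / 343, cfg)
  band <- which(ds$freq > ds$peaks$f_peak[1] + sep_expect / 2 &
                  ds$freq < ds$peaks$f_peak[1] + 2 * sep_expect)
  f2 <- ds$freq[band[which.max(ds$power[band])]]
  expect_equal(f2 - ds$peaks$f_peak[1], sep_expect, tolerance = 25)
})

test_that("rendered noise level matches the requested SNR", {
  sc <- quick_scene(pos = c(0.02, -0.01, 0.8), snr = 20)
  rec <- render_received(sc, 1, seed = 4)
  cfg <- sc$cfg
  frame <- rec$x[(5 * cfg$n_frame + 1):(6 * cfg$n_frame)]
  ds <- dechirp_and_separate(frame, cfg)
  expect_true(all(abs(ds$peaks$snr_db - 20) < 2))
})

test_that("rendering is deterministic under a fixed seed", {
  sc <- quick_scene(snr = 15)
  r1 <- render_received(sc, 0.5, seed = 42)
  r2 <- render_received(sc, 0.5, seed = 42)
  expect_identical(r1$x, r2$x)
  expect_identical(r1$beacons, r2$beacons)
  r3 <- render_received(sc, 0.5, seed = 43)
  expect_false(identical(r1$x, r3$x))
})

test_that("clothing attenuation scales amplitude without moving the beat peak", {
  cfg <- chirp_config()
  sc0 <- quick_scene(pos = c(0, 0, 1))
  sc1 <- quick_scene(pos = c(0, 0, 1), clothing_db = 6)
  f0 <- render_received(sc0, 0.3, seed = 1)
  f1 <- render_received(sc1, 0.3, seed = 1)
  fr0 <- f0$x[(3 * cfg$n_frame + 1):(4 * cfg$n_frame)]
  fr1 <- f1$x[(3 * cfg$n_frame + 1):(4 * cfg$n_frame)]
  d0 <- dechirp_and_separate(fr0, cfg, active = 1)
  d1 <- dechirp_and_separate(fr1, cfg, active = 1)
  expect_equal(d1$peaks$f_peak, d0$peaks$f_peak, tolerance = 1)
  expect_equal(sqrt(mean(fr1^2)) / sqrt(mean(fr0^2)), 10^(-6 / 20),
               tolerance = 0.01)
})

test_that("scripted bed sessions dwell at the prescribed levels", {
  traj <- scripted_bed_session(seq(0, 45, 5), dwell = 4, transition = 2)
  plat <- attr(traj, "plateaus")
  expect_equal(nrow(plat), 10)
  z <- traj_position(traj, plat$t_start + 2, respiration = FALSE)[, 3]
  expect_equal(diff(z), rep(-0.05, 9), tolerance = 1e-12)

  # respiration modulates the plateau by +/- a quarter of the stated swing
  tt <- seq(plat$t_start[1], plat$t_end[1], by = 0.01)
  zr <- traj_position(traj, tt)[, 3]
  expect_equal(max(zr) - min(zr), 0.005, tolerance = 2e-4)

  expect_error(scripted_bed_session(c(0, 10), dwell = -1), "dwell")
  expect_error(scripted_bed_session(c(0, 60)), "within")
})

test_that("accelerometer surrogate flags transitions, not plateaus", {
  traj <- scripted_bed_session(c(0, 5, 10), dwell = 6, transition = 2)
  t <- seq(0.05, max(traj$t), by = 0.043)
  imu <- acuheight:::imu_stream(traj, t)
  plat <- attr(traj, "plateaus")
  on_plateau <- t > plat$t_start[2] + 1 & t < plat$t_end[2] - 1
  in_transition <- t > plat$t_end[1] + 0.3 & t < plat$t_start[2] - 0.3
  expect_false(any(imu$motion[on_plateau]))
  expect_true(any(imu$motion[in_transition]))
})

test_that("static trajectories produce no motion flags after start", {
  traj <- static_trajectory(c(0, 0, 1))
  imu <- acuheight:::imu_stream(traj, seq(0.05, 5, by = 0.043))
  expect_false(any(imu$motion))
})

test_that("beacon logs drift, quantize and wrap like the hardware timers", {
  cl0 <- clock_model(0, 0, beacon_jitter_sd = 0)
  b0 <- simulate_beacons(cl0, 10, seed = 1)
  off <- b0$rx_ticks - b0$tx_ticks
  off <- off %% cl0$timer_max
  expect_lte(diff(range(off)), 1)   # constant up to quantization

  cl <- clock_model(ppm_tx = -20, ppm_rx = 20, beacon_jitter_sd = 0)
  b <- simulate_beacons(cl, 130, seed = 1)
  tx_s <- acuheight:::unwrap_ticks(b$tx_ticks, cl$timer_max) / cl$timer_freq
  rx_s <- acuheight:::unwrap_ticks(b$rx_ticks, cl$timer_max) / cl$timer_freq
  drift_per_min <- (rx_s - tx_s)[which.min(abs(b$t_true - 120))] -
    (rx_s - tx_s)[which.min(abs(b$t_true - 60))]
  expect_equal(drift_per_min, 2.4e-3, tolerance = 0.05e-3)

  expect_true(all(b$tx_ticks < cl$timer_max))
  wraps_per_s <- sum(diff(b$tx_ticks) < 0) / max(b$t_true)
  expect_equal(wraps_per_s, 20, tolerance = 0.5)
})

test_that("scene validation rejects unphysical configurations", {
  cfg <- chirp_config(); arr <- speaker_array()
  expect_error(
    acoustic_scene(arr, cfg, static_trajectory(c(0, 0, 1)),
                   body_paths = data.frame(excess = c(0.1, 0.1),
                                           rel_amp = c(0.6, 0.5))),
    "below the direct")
  expect_error(
    acoustic_scene(arr, cfg, static_trajectory(c(0, 0, 1)),
                   body_paths = data.frame(excess = -0.1, rel_amp = 0.2)),
    "excess")
  sc <- quick_scene()
  expect_error(render_received(sc, 0.01), "duration")
})

test_that("scene descriptions survive a JSON round trip", {
  sc <- quick_scene(pos = c(0.1, 0, 0.9), snr = 18,
                    body = data.frame(excess = 0.1, rel_amp = 0.3),
                    ppm = c(-20, 20))
  path <- withr::local_tempfile(fileext = ".json")
  scene_to_json(sc, path)
  back <- scene_from_json(path)
  expect_equal(back$noise_snr_db, 18)
  expect_equal(back$clocks$ppm_rx, 20)
  expect_equal(back$body_paths$excess, 0.1)
  expect_equal(back$traj$pos, sc$traj$pos)
})
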
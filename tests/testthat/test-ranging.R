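test_that("dechirp separates speakers at their base offsets", {
  cfg <- chirp_config()
  # zero-delay synthetic frame: sum of the three transmit chirps
  frame <- Re(generate_chirp(1, cfg)) + Re(generate_chirp(2, cfg)) +
    Re(generate_chirp(3, cfg))
  ds <- dechirp_and_separate(frame, cfg)
  base <- cfg$B * cfg$shift_fraction * (0:2)
  # peaks sit at the shift-only offsets (search band starts ~5 cm out, so
  # compare the raw spectrum maxima near each base offset)
  for (i in 1:3) {
    near <- which(abs(ds$freq - base[i]) < 40)
    f_pk <- ds$freq[near[which.max(ds$power[near])]]
    expect_equal(f_pk, base[i], tolerance = 15)
  }
})

test_that("a 1 m path appears 271 Hz above the speaker's base offset", {
  cfg <- chirp_config()
  sc <- quick_scene(pos = c(0, 0, 1), L = 1e-6)
  rec <- render_received(sc, 0.3, seed = 1)
  frame <- rec$x[(3 * cfg$n_frame + 1):(4 * cfg$n_frame)]
  ds <- dechirp_and_separate(frame, cfg, active = 1)
  expect_equal(ds$peaks$f_peak[1], beat_freq(1 / 343, cfg), tolerance = 6)
  expect_equal(ds$peaks$d_coarse[1], 1, tolerance = 0.07)
})

test_that("all-zero frames are flagged invalid", {
  cfg <- chirp_config()
  ds <- dechirp_and_separate(numeric(cfg$n_frame), cfg)
  expect_false(any(ds$peaks$valid))
  expect_error(dechirp_and_separate(numeric(10), cfg), "frame length")
})

test_that("band-pass length follows the SNR-adaptive group-delay rule", {
  cfg <- chirp_config()
  hi <- design_bandpass(15, 1000, cfg)
  lo <- design_bandpass(5, 1000, cfg)
  expect_equal(hi$n_taps, 1501)   # (N-1)/(2 fs) = 15 ms
  expect_equal(hi$delay, 0.015)
  expect_equal(lo$n_taps, 3001)   # 30 ms at low SNR
  expect_equal(lo$delay, 0.030)
})

test_that("band-pass passes in-band tones and rejects distant ones", {
  cfg <- chirp_config()
  fs <- cfg$fs
  n <- 20000
  t <- (0:(n - 1)) / fs
  f_c <- 1000
  gain_at <- function(f) {
    # tones live at -f on the dechirped axis (see design_bandpass)
    x <- exp(-2i * pi * f * t)
    y <- adaptive_bandpass(x, snr_db = 15, cfg, f_center = f_c)
    mid <- (n / 4):(3 * n / 4)
    sqrt(mean(Mod(y[mid])^2))
  }
  expect_lt(abs(20 * log10(gain_at(f_c))), 0.5)
  width <- 4 / cfg$T_chirp
  expect_lt(20 * log10(gain_at(f_c + 3 * width)), -40)
  expect_error(adaptive_bandpass(1:10, NA, cfg, 100), "finite")
})

test_that("group delay is compensated in the filtered output", {
  cfg <- chirp_config()
  n <- 20000
  t <- (0:(n - 1)) / cfg$fs
  # amplitude step on an in-band tone: the step edge must stay put
  env <- as.numeric(t > 0.2)
  x <- env * exp(-2i * pi * 1000 * t)
  y <- adaptive_bandpass(x, 15, cfg, 1000)
  edge <- which(Mod(y) > 0.5)[1]
  expect_lt(abs(edge / cfg$fs - 0.2), 0.003)
})

test_that("phase inversion recovers the time of flight from the model", {
  cfg <- chirp_config()
  expect_equal(phase_to_tof(0, cfg, coarse = 0), 0, tolerance = 1e-12)
  for (td in c(2e-4, 1e-3, 5e-3, 2e-2, 4e-2)) {
    phi <- forward_phase(cfg$T_chirp / 2, td, cfg)
    phi_w <- Arg(exp(1i * phi))   # wrapped measurement
    td_hat <- phase_to_tof(phi_w, cfg, coarse = td + 2e-5)
    expect_lt(abs(td_hat - td), 1e-7)
  }
  # no admissible root -> NA
  expect_error(phase_to_tof(0.1, cfg, coarse = cfg$T_chirp + 1), "anchor")
})

test_that("static tracking is stable and accurate to millimetres", {
  tr <- track_static(quick_scene(pos = c(0.02, -0.01, 1.0)), duration = 3)
  d_true <- true_dists(speaker_array(), c(0.02, -0.01, 1.0))
  expect_gt(mean(tr$rt$valid), 0.9)
  expect_true(all(abs(tr$d_mean - d_true) < 2e-3))
  expect_true(all(tr$d_sd < 2e-3))
})

test_that("tracked distances follow a height step within 2 mm", {
  arr <- speaker_array()
  traj <- scripted_bed_session(c(0, 5), dwell = 3, transition = 1.5,
                               start_pos = c(0.02, -0.01, 1.0),
                               respiration_pp = 0)
  sc <- quick_scene(traj = traj)
  rec <- render_received(sc, max(traj$t), seed = 2)
  rt <- track_distances(rec)
  df <- as.data.frame(rt)
  plat <- attr(traj, "plateaus")
  for (j in arr$active) {
    dj <- df[[paste0("d", j)]]
    d1 <- mean(dj[df$valid & df$t > 1 & df$t < plat$t_end[1]])
    d2 <- mean(dj[df$valid & df$t > plat$t_start[2] + 1])
    z1 <- true_dists(arr, c(0.02, -0.01, 1.0))[match(j, arr$active)]
    z2 <- true_dists(arr, c(0.02, -0.01, 0.95))[match(j, arr$active)]
    expect_lt(abs((d2 - d1) - (z2 - z1)), 2e-3)
  }
})

test_that("occlusion drops SNR, flags frames invalid, and holds distances", {
  sc <- quick_scene(pos = c(0, 0, 0.8), snr = 25,
                    occlusion = list(t0 = 1.5, t1 = 2.2, factor = 0.002))
  rec <- render_received(sc, 3, seed = 3)
  rt <- track_distances(rec)
  occluded <- rt$t > 1.6 & rt$t < 2.1
  before <- rt$t > 1.0 & rt$t < 1.4
  expect_gt(mean(rt$valid[before]), 0.9)
  expect_lt(mean(rt$valid[occluded]), 0.2)
  # held values: distances do not jump during the occlusion
  d1 <- as.data.frame(rt)$d1
  expect_lt(max(abs(diff(d1[occluded])), na.rm = TRUE), 0.05)
})

test_that("phase ranging beats the correlation peak under body multipath", {
  # one body reflection per speaker, up to half the direct amplitude and
  # 5-20 cm of excess path: the fine (phase) distance stays within 5 mm
  # while the coarse beat-peak distance errs by more
  cases <- expand.grid(excess = c(0.05, 0.12, 0.2), rel = c(0.3, 0.5))
  for (i in seq_len(nrow(cases))) {
    sc <- quick_scene(pos = c(0.03, 0.01, 0.9),
                      body = data.frame(excess = cases$excess[i],
                                        rel_amp = cases$rel[i]),
                      snr = 25)
    rec <- render_received(sc, 2.5, seed = 40 + i)
    cfg <- sc$cfg
    rt <- track_distances(rec)
    df <- as.data.frame(rt)
    d_true <- true_dists(sc$array, c(0.03, 0.01, 0.9))
    sel <- df$valid & df$t > 1
    fine_err <- abs(colMeans(df[sel, c("d1", "d2", "d3")]) - d_true)
    # coarse oracle: beat-peak distance from a mid-recording frame
    frame <- rec$x[(20 * cfg$n_frame + 1):(21 * cfg$n_frame)]
    ds <- dechirp_and_separate(frame, cfg)
    coarse_err <- abs(ds$peaks$d_coarse - d_true)
    expect_true(all(fine_err < 5e-3),
                label = sprintf("fine error (excess %.2f, rel %.1f)",
                                cases$excess[i], cases$rel[i]))
    expect_lt(max(fine_err), max(coarse_err))
  }
})

test_that("estimated distance is nondecreasing for a receding device", {
  traj <- trajectory(c(0, 1, 9, 10), rbind(c(0, 0, 0.8), c(0, 0, 0.8),
                                           c(0, 0, 1.1), c(0, 0, 1.1)))
  sc <- quick_scene(traj = traj)
  rec <- render_received(sc, 10, seed = 5)
  rt <- track_distances(rec)
  df <- as.data.frame(rt)
  sel <- df$valid & df$t > 0.5
  expect_true(all(diff(df$d1[sel]) > -2e-4))
})
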
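test_that("equal distances place the device on the array axis", {
  tri <- triangulate(1.2, 1.2, 1.2, L = 0.1)
  expect_equal(tri$X, 0)
  expect_equal(tri$Y, 0)
  expect_equal(tri$Z, 1.2)
  expect_true(tri$valid)
})

test_that("swapping the baseline speakers swaps the lateral axes", {
  d <- true_dists(speaker_array(), c(0.05, -0.03, 0.8))
  a <- triangulate(d[1], d[2], d[3], 0.1)
  b <- triangulate(d[1], d[3], d[2], 0.1)
  expect_equal(a$X, b$Y)
  expect_equal(a$Y, b$X)
  expect_equal(a$Z, b$Z)
})

test_that("far-field triangulation is close to exact trilateration", {
  arr <- speaker_array(L = 0.1)
  pos <- c(0.05, -0.03, 0.8)
  d <- true_dists(arr, pos)
  tri <- triangulate(d[1], d[2], d[3], arr$L)
  # the exact-geometry oracle recovers the position to numerical precision
  exact <- trilaterate_exact(d, arr$positions[arr$active, ])
  expect_lt(max(abs(exact - pos)), 1e-9)
  # the closed-form far-field solution is within its stated bounds of truth
  expect_lt(abs(tri$X - pos[1]), 0.015)
  expect_lt(abs(tri$Y - pos[2]), 0.015)
  expect_lt(abs(tri$Z - pos[3]), 0.005)
})

test_that("far-field error over a position grid is bounded by the plane-wave
           bias for any array size", {
  set.seed(8)
  for (L in c(0.1, 0.2, 0.4)) {
    arr <- speaker_array(L = L)
    for (i in 1:25) {
      r <- runif(1, 0.4, 2)
      pos <- c(runif(2, -0.15, 0.15), 0)
      pos[3] <- sqrt(r^2 - sum(pos[1:2]^2))
      d <- true_dists(arr, pos)
      tri <- triangulate(d[1], d[2], d[3], L)
      expect_lt(max(abs(trilaterate_exact(d, arr$positions[arr$active, ]) -
                          pos)), 1e-9)
      # height bias of the difference method ~ L^2/(4 r), inflated off-axis
      expect_lt(abs(tri$Z - pos[3]), 3.2 * L^2 / (4 * r) + 1e-3)
    }
  }
})

test_that("height changes cancel the far-field bias to under 2 mm", {
  arr <- speaker_array(L = 0.1)
  for (z in c(0.3, 0.6, 1.0, 1.5)) {
    p1 <- c(0.04, -0.02, z)
    p2 <- c(0.04, -0.02, z - 0.05)
    d1 <- true_dists(arr, p1); d2 <- true_dists(arr, p2)
    dz <- triangulate(d1[1], d1[2], d1[3], arr$L)$Z -
      triangulate(d2[1], d2[2], d2[3], arr$L)$Z
    expect_lt(abs(dz - 0.05), 2e-3)
  }
})

test_that("height is invariant under array rotation with relabeling", {
  arr <- speaker_array(L = 0.12)
  p <- c(0.06, -0.04, 0.9)
  # rotate the device by 90 degrees about z and relabel the speakers so the
  # geometry is unchanged: new s1 sees what old s3 saw, etc.
  p_rot <- c(-p[2], p[1], p[3])
  d_all <- sqrt(rowSums(sweep(arr$positions, 2, p)^2))
  d_rot <- sqrt(rowSums(sweep(arr$positions, 2, p_rot)^2))
  z1 <- triangulate(d_all[1], d_all[2], d_all[3], arr$L)$Z
  # after rotation: slot 1 <- old 3, slot 2 <- old 1, slot 3 <- old 4
  z2 <- triangulate(d_rot[1], d_rot[2], d_rot[3], arr$L)$Z
  expect_equal(z2, z1, tolerance = 2e-3)
})

test_that("inconsistent distances are flagged, not propagated", {
  tri <- triangulate(1.0, 0.2, 1.0, L = 0.1)
  expect_false(tri$valid)
  expect_true(is.na(tri$Z))
})

test_that("calibration recovers per-speaker offsets", {
  sc <- quick_scene(pos = c(0, 0, 0.05), snr = 30)
  rec <- render_received(sc, 2, seed = 9)
  cal <- calibrate(rec, reference_position = c(0, 0, 0.05))
  expect_true(all(abs(cal$D) < 2e-3))   # no processing bias beyond noise

  # shifting the assumed reference position injects known geometric offsets
  ref2 <- c(0, 0, 0.08)
  cal2 <- calibrate(rec, reference_position = ref2)
  inject <- true_dists(sc$array, c(0, 0, 0.05)) - true_dists(sc$array, ref2)
  expect_lt(max(abs(unname(cal2$D - cal$D) - unname(inject))), 2e-3)
})

test_that("calibration is rejected while the device moves", {
  traj <- scripted_bed_session(c(0, 5), dwell = 1, transition = 1,
                               start_pos = c(0, 0, 0.05),
                               respiration_pp = 0)
  sc <- quick_scene(traj = traj)
  rec <- render_received(sc, 3, seed = 10)
  expect_error(calibrate(rec, c(0, 0, 0.05)), "motion")
})

test_that("IMU gate freezes height through occlusions without motion", {
  t <- seq(0, 20, by = 0.043)
  z <- rep(1, length(t)) + rnorm(length(t), 0, 5e-4)
  motion <- rep(FALSE, length(t))
  valid <- !(t > 8 & t < 10)
  z[t > 8 & t < 10] <- 0.7    # occlusion corrupts the acoustics
  g <- imu_gate(t, z, motion, valid)
  settled <- g$t > 3
  expect_lt(diff(range(g$z_gated[settled])), 1e-6)
  expect_true(all(g$gate_state[settled] == "idle"))
})

test_that("IMU gate tracks motion and re-latches within 2 s of motion end", {
  t <- seq(0, 20, by = 0.043)
  z_true <- ifelse(t < 8, 1, ifelse(t < 10, 1 - 0.05 * (t - 8) / 2, 0.95))
  z <- z_true + rnorm(length(t), 0, 3e-4)
  motion <- t >= 8 & t <= 10
  g <- imu_gate(t, z, motion, rep(TRUE, length(t)))
  expect_equal(g$z_gated[which.min(abs(t - 7))], 1, tolerance = 2e-3)
  after <- t > 12.5
  expect_equal(mean(g$z_gated[after]), 0.95, tolerance = 2e-3)
  expect_true(all(g$gate_state[after] == "idle"))
})

test_that("IMU gate keeps tracking until an occlusion clears", {
  t <- seq(0, 25, by = 0.043)
  z_true <- ifelse(t < 8, 1, ifelse(t < 10, 1 - 0.05 * (t - 8) / 2, 0.95))
  z <- z_true + rnorm(length(t), 0, 3e-4)
  motion <- t >= 8 & t <= 10
  valid <- !(t >= 9 & t <= 13)  # occlusion outlasts the motion by 3 s
  z[!valid] <- 1.3              # corrupted acoustics during occlusion
  g <- imu_gate(t, z, motion, valid)
  late <- t > 16
  expect_equal(mean(g$z_gated[late]), 0.95, tolerance = 2e-3)
})

test_that("the full tracker is deterministic under a fixed seed", {
  sc <- quick_scene(snr = 18, body = data.frame(excess = 0.1, rel_amp = 0.3),
                    ppm = c(-20, 20))
  rec1 <- render_received(sc, 3, seed = 11)
  rec2 <- render_received(sc, 3, seed = 11)
  ht1 <- run_tracker(rec1)
  ht2 <- run_tracker(rec2)
  expect_identical(as.data.frame(ht1), as.data.frame(ht2))
})

test_that("calibration offsets survive a JSON round trip", {
  cal <- structure(list(D = c(d1 = 0.001, d2 = -0.002, d3 = 0.0005),
                        reference_position = c(0, 0, 0.05),
                        n_frames = 40L),
                   class = "calibration_offsets")
  path <- withr::local_tempfile(fileext = ".json")
  calibration_to_json(cal, path)
  back <- calibration_from_json(path)
  expect_equal(back$D, cal$D)
  expect_equal(back$reference_position, cal$reference_position)
})
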
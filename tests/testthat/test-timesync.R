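test_that("drift resampling with alpha = 1 is the identity", {
  set.seed(1)
  x <- rnorm(1024)
  y <- resample_with_drift(x, 1)
  expect_true(is.numeric(y))
  expect_lt(max(abs(y - x)) / max(abs(x)), 1e-9)
})

test_that("drift resampling scales a tone's frequency by alpha", {
  fs <- 50000
  n <- 4096
  x <- sin(2 * pi * 20000 * (0:(n - 1)) / fs)
  y <- resample_with_drift(x, 1.001)
  S <- Mod(stats::fft(y))[1:(n / 2)]
  f_dom <- (which.max(S) - 1) * fs / n
  expect_equal(f_dom, 20020, tolerance = fs / n)
  expect_error(resample_with_drift(x, 0.5), "alpha")
  expect_error(resample_with_drift(c(x, NA), 1), "finite")
})

test_that("resampling by the drift factor re-aligns a stretched chirp", {
  # a receiver sampling delta slow records chirp(t (1+delta)); resampling by
  # alpha = 1/(1+delta) restores the clean waveform (interior samples, away
  # from the periodic-basis edges)
  cfg <- chirp_config()
  n <- 2500
  delta <- 1e-3
  t <- (0:(n - 1)) / cfg$fs
  clean <- Re(acuheight:::chirp_wave_at(t, 1, cfg))
  drifted <- Re(acuheight:::chirp_wave_at(t * (1 + delta), 1, cfg))
  fixed <- Re(resample_with_drift(drifted, 1 / (1 + delta)))
  mid <- (n %/% 5):(4 * n %/% 5)
  rms <- function(x) sqrt(mean(x^2))
  expect_lt(rms(fixed[mid] - clean[mid]), 0.25 * rms(drifted[mid] - clean[mid]))
})

test_that("beacon alignment recovers the relative clock rate and offset", {
  cl0 <- clock_model(0, 0, beacon_jitter_sd = 0)
  m0 <- beacon_align(simulate_beacons(cl0, 10, seed = 1), cl0)
  expect_equal(m0$alpha, 1, tolerance = 1e-9)

  cl <- clock_model(ppm_tx = -20, ppm_rx = 20)
  m <- beacon_align(simulate_beacons(cl, 60, seed = 2), cl)
  alpha_true <- (1 - 20e-6) / (1 + 20e-6)
  expect_equal(m$alpha, alpha_true, tolerance = 1e-7)
  # residual drift after alignment is far below the raw 2.4 ms/min
  expect_lt(abs(m$alpha - alpha_true) * 60, 1e-3 * 2.4e-3)

  # mapping is continuous across timer wraps (no 50 ms jumps)
  b <- simulate_beacons(cl, 2, seed = 3)
  tx_u <- acuheight:::unwrap_ticks(b$tx_ticks, cl$timer_max)
  expect_true(all(diff(tx_u) > 0))
  expect_lt(max(abs(diff(tx_u) / cl$timer_freq - 1 / cl$beacon_rate)), 1e-3)

  expect_error(beacon_align(b[1, ], cl), "at least 2")
  bad <- b; bad$rx_ticks <- rev(bad$rx_ticks)
  expect_error(beacon_align(bad, cl), "monotonic")
})

test_that("residual drift regression recovers injected linear drift", {
  t <- seq(0, 300, by = 0.043)
  static <- rep(100, length(t))
  e0 <- estimate_residual_drift(t, static)
  expect_true(e0$ok)
  expect_equal(e0$slope, 0, tolerance = 1e-12)

  set.seed(5)
  h <- 100 + 0.1 * t + rnorm(length(t), 0, 0.05)
  e1 <- estimate_residual_drift(t, h)
  expect_equal(e1$slope, 0.1, tolerance = 0.005)

  # invariant to adding a constant
  e2 <- estimate_residual_drift(t, h + 57)
  expect_equal(e2$slope, e1$slope)

  # applying the correction flattens the series
  fixed <- apply_drift_correction(t, h, e1)
  expect_lt(abs(mean(tail(fixed, 100)) - mean(head(fixed, 100))), 0.5)
})

test_that("motion-corrupted chunks fall in the discarded upper half", {
  t <- seq(0, 300, by = 0.043)
  set.seed(6)
  h <- 50 + 0.1 * t + rnorm(length(t), 0, 0.05)
  # corrupt 40% of the 10 chunks with motion-burst noise
  for (c0 in c(30, 90, 150, 270)) {
    ii <- t >= c0 & t < c0 + 30
    h[ii] <- h[ii] + rnorm(sum(ii), 0, 3)
  }
  e <- estimate_residual_drift(t, h)
  expect_equal(e$slope, 0.1, tolerance = 0.005)
})

test_that("odd chunk counts keep the lower floor(n/2) chunks", {
  t <- seq(0, 150 - 0.043, by = 0.043)  # 5 chunks of 30 s
  set.seed(7)
  h <- 0.2 * t + rnorm(length(t), 0, 0.01)
  e <- estimate_residual_drift(t, h, window = 150)
  expect_equal(e$n_chunks, 5)
  expect_equal(nrow(e$chunks), 5)
  expect_equal(e$slope, 0.2, tolerance = 0.005)
})

test_that("short histories and all-motion histories yield no estimate", {
  t <- seq(0, 20, by = 0.043)
  e <- estimate_residual_drift(t, rnorm(length(t)))
  expect_false(e$ok)
  expect_equal(e$slope, 0)

  t2 <- seq(0, 300, by = 0.043)
  e2 <- estimate_residual_drift(t2, rnorm(length(t2)),
                                motion = rep(TRUE, length(t2)))
  expect_false(e2$ok)
})

test_that("motion-aware chunking never straddles a transition", {
  # staircase rising 5 units every 20 s: every 30 s chunk contains a step,
  # so without motion flags the staircase masquerades as drift and even the
  # lower-residual-half rule cannot reject it
  t <- seq(0, 240, by = 0.043)
  step <- floor(t / 20)
  h <- 5 * step
  motion <- (t %% 20) > 19   # transitions flagged by the IMU
  e_blind <- estimate_residual_drift(t, h, window = 240)
  expect_gt(abs(e_blind$slope), 0.05)
  e_aware <- estimate_residual_drift(t, h, window = 240, motion = motion)
  expect_equal(e_aware$slope, 0, tolerance = 1e-10)
})

test_that("drift slope converts to the equivalent resampling factor", {
  expect_equal(drift_slope_to_alpha(0), 1)
  expect_equal(drift_slope_to_alpha(34.3), 1.001)
})
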
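# Independent oracles and small scene builders shared across tests.

# Exact trilateration from the three sphere equations (independent of the
# package's far-field difference method): subtracting sphere equations
# pairwise gives linear equations in x and y for the square-corner layout
# s1 = (-a,-a,0), s2 = (+a,-a,0), s3 = (-a,+a,0) with a = L/2.
trilaterate_exact <- function(d, speakers) {
  a <- speakers[2, 1]               # +L/2
  L <- 2 * a
  x <- (d[1]^2 - d[2]^2) / (2 * L)
  y <- (d[1]^2 - d[3]^2) / (2 * L)
  z <- sqrt(d[1]^2 - (x + a)^2 - (y + a)^2)
  unname(c(x, y, z))
}

# geometric distances from a position to the active speakers
true_dists <- function(array, pos) {
  sp <- array$positions[array$active, , drop = FALSE]
  sqrt(rowSums(sweep(sp, 2, pos)^2))
}

# beat-frequency oracle: a delay tau appears at (B/T) tau in the dechirped
# spectrum
beat_freq <- function(tau, cfg) cfg$B / cfg$T_chirp * tau

# quadratic FMCW phase evaluated directly (the model the ranging stage
# inverts)
eq_phase <- function(t, t_d, cfg) {
  -2 * pi * (cfg$B / cfg$T_chirp * t * t_d + cfg$f0 * t_d -
               cfg$B / (2 * cfg$T_chirp) * t_d^2)
}

# standard small scene: static device, optional multipath/noise/drift
quick_scene <- function(pos = c(0.02, -0.01, 1.0), snr = Inf,
                        body = NULL, ppm = c(0, 0), occlusion = NULL,
                        clothing_db = 0, respiration_pp = 0,
                        traj = NULL, L = 0.1) {
  cfg <- chirp_config()
  arr <- speaker_array(L = L)
  if (is.null(traj)) {
    traj <- static_trajectory(pos, respiration_pp = respiration_pp)
  }
  acoustic_scene(arr, cfg, traj, body_paths = body, noise_snr_db = snr,
                 clocks = clock_model(ppm_tx = ppm[1], ppm_rx = ppm[2]),
                 occlusion = occlusion, clothing_db = clothing_db)
}

# render + track + absolute-distance means for a static scene
track_static <- function(scene, duration = 3, seed = 1, sync = TRUE,
                         warmup = 1) {
  rec <- render_received(scene, duration, seed = seed)
  cmap <- if (sync) beacon_align(rec$beacons, scene$clocks) else NULL
  rt <- track_distances(rec, clock_map = cmap)
  sel <- rt$valid & rt$t > warmup
  df <- as.data.frame(rt)
  dcols <- paste0("d", scene$array$active)
  list(rt = rt, rec = rec, sel = sel,
       d_mean = colMeans(df[sel, dcols, drop = FALSE]),
       d_sd = vapply(df[sel, dcols, drop = FALSE], stats::sd, 0))
}
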
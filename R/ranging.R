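# Per-speaker direct-path ranging: dechirp + DFT speaker separation (step 1),
# SNR-adaptive linear-phase band-pass, FMCW-phase time of flight (step 2).

hann_window <- function(n) 0.5 - 0.5 * cos(2 * pi * (0:(n - 1)) / (n - 1))

# Analytic (positive-frequency) signal via FFT Hilbert transform, processed
# in overlapping chunks so multi-minute streams stay cheap; interior samples
# are exact to edge-leakage level.
analytic_signal <- function(x, chunk = 2^20L, overlap = 4096L) {
  n <- length(x)
  if (is.complex(x)) return(x)
  if (n <= chunk) return(hilbert_fft(x))
  out <- complex(length.out = n)
  s <- 1L
  while (s <= n) {
    e <- min(s + chunk - 1L, n)
    lo <- max(1L, s - overlap)
    hi <- min(n, e + overlap)
    seg <- hilbert_fft(x[lo:hi])
    out[s:e] <- seg[(s - lo + 1L):(e - lo + 1L)]
    s <- e + 1L
  }
  out
}

hilbert_fft <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

# Parabolic (log-magnitude) interpolation of a spectral peak.
# Returns fractional bin offset in [-0.5, 0.5] and interpolated log power.
parabolic_peak <- function(logp, i) {
  if (i <= 1 || i >= length(logp)) return(list(delta = 0, val = logp[i]))
  a <- logp[i - 1]; b <- logp[i]; c <- logp[i + 1]
  den <- a - 2 * b + c
  delta <- if (abs(den) < 1e-12) 0 else 0.5 * (a - c) / den
  delta <- max(-0.5, min(0.5, delta))
  list(delta = delta, val = b - 0.25 * (a - c) * delta)
}

#' Dechirp one frame and separate the speakers in the beat spectrum
#'
#' Multiplies one chirp period of the received signal by the conjugate
#' reference chirp (speaker 1, unshifted) and takes a windowed DFT. Each
#' speaker's direct path appears as a beat peak near its base offset
#' \eqn{(i-1) B \cdot \mathrm{shift\_fraction}}; the beat frequency above the
#' offset is \eqn{(B/T)\,t_d}. Reports, per active speaker, the interpolated
#' peak frequency, the coarse total delay and distance, and the SNR (beat peak
#' power referred back to the time domain over the local noise floor).
#'
#' @param frame real vector of length \code{cfg$n_frame} (one chirp period).
#' @param cfg a [chirp_config()].
#' @param active indices of the transmitting speakers (default 1:3).
#' @param c speed of sound, m/s (for the coarse distance).
#' @param pad zero-padding factor for the DFT (default 4).
#' @return list with \code{freq} (Hz), \code{power} (spectrum |S|^2),
#'   \code{peaks}: data.frame(speaker, f_peak, tau, d_coarse, snr_db, valid).
#' @export
dechirp_and_separate <- function(frame, cfg, active = 1:3, c = 343, pad = 4) {
  stop_if_not(length(frame) == cfg$n_frame,
              "frame length must equal one chirp period")
  if (all(frame == 0)) {
    peaks <- data.frame(speaker = active, f_peak = NA_real_, tau = NA_real_,
                        d_coarse = NA_real_, snr_db = -Inf, valid = FALSE)
    return(list(freq = NULL, power = NULL, peaks = peaks))
  }
  ref <- Conj(generate_chirp(1, cfg))
  mixed <- analytic_signal(frame) * ref
  sp <- frame_spectrum(mixed, cfg, pad)
  peaks <- do.call(rbind, lapply(active, function(s) {
    band <- speaker_band(s, cfg, c)
    pk <- band_peak(sp, band, cfg)
    data.frame(speaker = s, f_peak = pk$f_peak, tau = pk$tau_mod,
               d_coarse = c * (pk$tau_mod - speaker_shift(s, cfg)),
               snr_db = pk$snr_db, valid = is.finite(pk$snr_db))
  }))
  list(freq = sp$freq, power = sp$power, peaks = peaks, mixed = mixed)
}

# Windowed zero-padded beat spectrum of a dechirped frame. The dechirp
# convention (conjugate reference) puts a delay tau at instantaneous
# frequency -(B/T) tau, so the spectrum is taken of the conjugated mixture:
# peaks then appear at +(B/T) tau on the `freq` axis. The white-noise floor
# is estimated once per frame from a quiet region of the beat axis (negative
# beat frequencies away from the sweep-reset lines, where no deterministic
# energy lives).
frame_spectrum <- function(mixed, cfg, pad = 4) {
  n <- length(mixed)
  w <- hann_window(n)
  nfft <- 2^ceiling(log2(pad * n))
  S <- stats::fft(c(Conj(mixed) * w, complex(length.out = nfft - n)))
  freq <- (0:(nfft - 1)) * cfg$fs / nfft
  power <- Re(S)^2 + Im(S)^2
  # quiet region of the beat axis: above every speaker's slot (beats reach
  # ~(B/T)(max shift + max range delay) < 3.3 kHz; sweep-reset lines are
  # negative) yet inside the fully-covered noise band of the dechirped
  # analytic mixture
  i_quiet <- (floor(4500 / cfg$fs * nfft) + 1):(floor(8000 / cfg$fs * nfft))
  floor_med <- stats::median(power[i_quiet]) / log(2)
  list(S = S, power = power, freq = freq, w = w,
       sumw = sum(w), sumw2 = sum(w^2), nfft = nfft,
       floor_med = floor_med)
}

# beat-frequency search band for speaker s: delays from ~5 cm out to just
# under the next speaker's shift slot
speaker_band <- function(s, cfg, c = 343, d_min = 0.05, margin = 0.9) {
  sh <- speaker_shift(s, cfg)
  slot <- cfg$shift_fraction * cfg$T_chirp
  (cfg$B / cfg$T_chirp) * c(sh + d_min / c, sh + margin * slot)
}

# Peak + SNR within a frequency band of a frame spectrum. A delay tau's beat
# tone occupies only the trailing (T - tau) of the frame (the leading part is
# the previous sweep), so the tone amplitude is referred to the effective
# window mass over that span; SNR is the per-speaker time-domain direct-path
# SNR implied by the tone amplitude and the frame's white-noise floor.
band_peak <- function(sp, band, cfg) {
  df <- cfg$fs / sp$nfft
  i_lo <- max(1L, ceiling(band[1] / df) + 1L)
  i_hi <- min(sp$nfft, floor(band[2] / df) + 1L)
  if (i_hi - i_lo < 2) {
    return(list(f_peak = NA_real_, tau_mod = NA_real_, snr_db = -Inf))
  }
  ii <- i_lo:i_hi
  p <- sp$power[ii]
  imax <- ii[which.max(p)]
  tri <- log(pmax(sp$power[max(1, imax - 1):min(sp$nfft, imax + 1)],
                  .Machine$double.xmin))
  if (length(tri) == 3) {
    pb <- parabolic_peak(tri, 2)
  } else {
    pb <- list(delta = 0, val = log(max(sp$power[imax],
                                        .Machine$double.xmin)))
  }
  f_peak <- sp$freq[imax] + pb$delta * df
  peak_pow <- exp(pb$val)
  tau_mod <- f_peak * cfg$T_chirp / cfg$B
  n <- length(sp$w)
  n_glitch <- min(n, max(0, round(tau_mod * cfg$fs)))
  sumw_eff <- sp$sumw - sum(sp$w[seq_len(n_glitch)])
  alpha2 <- peak_pow / max(sumw_eff, 1)^2
  sigma2 <- sp$floor_med / (4 * sp$sumw2)
  snr_db <- if (sigma2 > 0) pow_to_db((alpha2 / 2) / sigma2) else Inf
  list(f_peak = f_peak, tau_mod = tau_mod, snr_db = snr_db)
}

#' Design / apply the SNR-adaptive band-pass filter
#'
#' A linear-phase FIR band-pass centered on a speaker's beat peak. The filter
#' group delay is chosen from the SNR: above 10 dB a 15 ms delay (1501 taps at
#' 50 kHz), at or below 10 dB a longer 30 ms delay (3001 taps) buys a narrower
#' transition at the cost of latency. The passband spans
#' \code{width_bins} frame-rate bins (\code{width_bins/T} Hz) around the
#' center. The complex (single-sideband) filter passes the beat line and
#' rejects both distant-multipath beats and the sum-frequency mixing image.
#' Group delay is compensated, so the output is time-aligned with the input.
#'
#' @param x complex dechirped signal (any length >= the filter).
#' @param snr_db per-frame SNR, dB.
#' @param cfg a [chirp_config()].
#' @param f_center passband center frequency, Hz.
#' @param width_bins passband width in 1/T bins (default 4).
#' @return filtered complex vector, same length as \code{x}.
#' @export
adaptive_bandpass <- function(x, snr_db, cfg, f_center, width_bins = 4) {
  stop_if_not(is.finite(snr_db), "snr_db must be finite")
  flt <- design_bandpass(snr_db, f_center, cfg, width_bins)
  apply_fir_centered(x, flt$h, flt$M)
}

#' @rdname adaptive_bandpass
#' @param delay override the group delay, s (default from SNR rule).
#' @return for \code{design_bandpass}: list(h, n_taps, M, delay).
#' @export
design_bandpass <- function(snr_db, f_center, cfg, width_bins = 4,
                            delay = NULL) {
  if (is.null(delay)) delay <- if (snr_db > 10) 0.015 else 0.030
  n_taps <- round(2 * cfg$fs * delay) + 1
  M <- (n_taps - 1) / 2
  half_bw <- (width_bins / 2) / cfg$T_chirp
  h_lp <- signal::fir1(n_taps - 1, half_bw / (cfg$fs / 2), type = "low")
  h_lp <- h_lp / sum(h_lp)   # exact unity passband-centre gain
  k <- 0:(n_taps - 1)
  # beat line of delay tau lives at -(B/T) tau in the dechirped mixture, so
  # a positive beat-axis center f_center modulates the prototype to -f_center
  h <- h_lp * exp(-2i * pi * f_center * (k - M) / cfg$fs)
  list(h = h, n_taps = n_taps, M = M, delay = delay)
}

# full group-delay-compensated FIR: out[n] = sum_k h[k+1] x[n + M - k]
apply_fir_centered <- function(x, h, M) {
  n <- length(x); nh <- length(h)
  nfft <- stats::nextn(n + nh - 1, 2)
  X <- stats::fft(c(x, complex(length.out = nfft - n)))
  H <- stats::fft(c(h, complex(length.out = nfft - nh)))
  y <- stats::fft(X * H, inverse = TRUE) / nfft
  y[(1 + M):(n + M)]
}

# single-point evaluation of the centered FIR at sample index n0 (1-based)
# within `x`; requires n0-M >= 1 and n0+M <= length(x)
fir_at <- function(x, h, M, n0) {
  sum(h * x[seq(n0 + M, n0 - M)])
}

#' Invert the FMCW phase model for the time of flight
#'
#' Solves the quadratic phase model of [forward_phase()] for the arrival time
#' \eqn{t_d}, given the (wrapped or unwrapped) phase of the band-pass-filtered
#' dechirped signal sampled at time \code{t_phase} within the chirp. The
#' measured phase is 2-pi ambiguous; candidate unwrap counts are generated
#' around an anchor — the previous frame's delay when available, otherwise the
#' coarse beat-peak delay — and the root nearest the anchor in \[0, T\] is
#' returned.
#'
#' @param phase measured phase, radians.
#' @param cfg a [chirp_config()].
#' @param prior previous-frame delay, s, or NULL.
#' @param coarse coarse beat-peak delay, s (used when \code{prior} is NULL).
#' @param t_phase phase sampling time within the chirp, s (default T/2).
#' @return \code{t_d} in seconds, or NA if no root lies in \[0, T\].
#' @export
phase_to_tof <- function(phase, cfg, prior = NULL, coarse = 0,
                         t_phase = cfg$T_chirp / 2) {
  stop_if_not(is.finite(phase), "phase must be finite")
  anchor <- if (!is.null(prior)) prior else coarse
  stop_if_not(anchor >= 0 && anchor <= cfg$T_chirp,
              "anchor delay outside [0, T]")
  td <- tof_candidates(phase, anchor, t_phase, cfg)
  if (is.na(td) || td < -1e-9 || td > cfg$T_chirp + 1e-9) return(NA_real_)
  min(max(td, 0), cfg$T_chirp)
}

# core inversion: candidate unwrap counts around the anchor, quadratic roots,
# nearest-to-anchor selection. anchor and result live in mod-T delay space.
tof_candidates <- function(phase, anchor, t_phase, cfg) {
  phi_a <- forward_phase_unchecked(t_phase, anchor, cfg)
  m0 <- round((phase - phi_a) / (2 * pi))
  q <- cfg$B / cfg$T_chirp * t_phase + cfg$f0
  a <- cfg$B / (2 * cfg$T_chirp)
  best <- NA_real_; best_d <- Inf
  for (m in m0 + (-1:1)) {
    P <- -(phase - 2 * pi * m) / (2 * pi)
    disc <- q^2 - 4 * a * P
    if (disc < 0) next
    td <- (q - sqrt(disc)) / (2 * a)
    if (abs(td - anchor) < best_d) {
      best <- td; best_d <- abs(td - anchor)
    }
  }
  best
}

# Initialization of the per-speaker delay. A single-frame beat peak can be
# pulled past half a wavelength by an unresolved body reflection a few cm
# behind the direct path, which would lock the phase stage an integer number
# of 2-pi cycles off. Since the dechirped mixture repeats every frame, the
# steady (post-sweep-reset) segment of K frames is averaged coherently to
# raise SNR, and a two-tone least-squares fit around the coarse peak
# separates the direct path (the lower beat frequency) from the reflection.
init_coarse_delays <- function(xa, tau_of_n, n_of_tau, cfg, active, c,
                               K = 32, guard = 1e-3) {
  Tc <- cfg$T_chirp
  nf <- cfg$n_frame
  K <- min(K, floor((tau_of_n(length(xa)) - Tc) / Tc) - 1)
  if (K < 1) return(rep(NA_real_, length(active)))
  starts <- vapply(seq_len(K) + 1, function(k) {
    ceiling(n_of_tau((k - 1) * Tc))
  }, 0)
  if (any(starts < 1) || max(starts) + nf - 1 > length(xa)) {
    return(rep(NA_real_, length(active)))
  }
  idxs <- lapply(starts, function(n0) n0:(n0 + nf - 1L))
  frames <- lapply(idxs, function(idx) {
    Conj(xa[idx] * Conj(chirp_wave_at(tau_of_n(idx), 1, cfg)))
  })
  sp1 <- frame_spectrum(Conj(frames[[1]]), cfg)
  pks <- lapply(active, function(s) {
    band_peak(sp1, speaker_band(s, cfg, c), cfg)
  })
  taus <- vapply(pks, `[[`, 0, "tau_mod")
  if (!all(is.finite(taus))) return(rep(NA_real_, length(active)))
  # common steady window: past every speaker's sweep reset, so each
  # speaker's tone and every cross-speaker tone is a clean cisoid that the
  # line-spectrum fit can model and subtract
  i0 <- min(nf - 200L, ceiling((max(taus) + guard) * cfg$fs) + 1L)
  seg <- Reduce(`+`, lapply(frames, function(f) f[i0:nf])) / K
  t_in <- (seq(i0, nf) - 1) / cfg$fs

  # pass 1: per-speaker line-spectrum fit of each beat cluster
  pass1 <- lapply(seq_along(active), function(j) {
    refine_direct_tone(seg, t_in, pks[[j]]$f_peak)
  })

  # pass 2: re-fit all clusters jointly at full rate, subtract the OTHER
  # speakers' clusters (their reflections included), and re-refine. This
  # removes the cross-cluster residual that otherwise flattens the
  # maximum-likelihood basin around the direct tone.
  allf <- unlist(lapply(pass1, `[[`, "comps"))
  owner <- rep(seq_along(active), vapply(pass1, function(p)
    length(p$comps), 0L))
  keep <- !duplicated(round(allf / 3))
  allf <- allf[keep]; owner <- owner[keep]
  E <- exp(2i * pi * outer(t_in, allf))
  cc_all <- tryCatch(qr.solve(E, seg), error = function(e) NULL)
  vapply(seq_along(active), function(j) {
    f_dir <- if (is.null(cc_all)) {
      pass1[[j]]$f_dir
    } else {
      oth <- which(owner != j)
      seg_j <- if (length(oth)) {
        seg - as.vector(E[, oth, drop = FALSE] %*% cc_all[oth])
      } else seg
      refine_direct_tone(seg_j, t_in, pass1[[j]]$f_dir)$f_dir
    }
    f_dir * Tc / cfg$B
  }, 0)
}

# Matrix-pencil (ESPRIT-style) line-spectrum fit of the dechirped steady
# segment: the direct beat tone plus up to a few body reflections a few tens
# of Hz above it. The segment is shifted to baseband around the coarse peak
# and boxcar-decimated (the beat content spans well under 100 Hz); the
# signal-subspace rank comes from the singular-value profile. The direct
# path is the lowest-frequency component of substantial amplitude — a body
# reflection is at most ~0.5 relative, spurious components far less.
refine_direct_tone <- function(seg, t_in, f_coarse, decim = 12L,
                               max_order = 8L, sv_tol = 0.02,
                               amp_gate = 0.35, window = 25) {
  fallback <- list(f_dir = f_coarse, comps = f_coarse)
  y0 <- seg * exp(-2i * pi * f_coarse * t_in)
  nd <- floor(length(y0) / decim)
  if (nd < 12) return(fallback)
  y <- vapply(seq_len(nd), function(i) {
    mean(y0[((i - 1) * decim + 1):(i * decim)])
  }, complex(1))
  dt <- decim * (t_in[2] - t_in[1])
  L <- floor(nd / 2)
  A <- t(vapply(seq_len(nd - L), function(i) y[i:(i + L)],
                complex(L + 1)))
  Y0 <- A[, 1:L, drop = FALSE]
  Y1 <- A[, 2:(L + 1), drop = FALSE]
  sv <- svd(Y0)
  p <- min(max_order, sum(sv$d >= sv_tol * sv$d[1]))
  if (p < 1) return(fallback)
  Zr <- diag(1 / sv$d[1:p], p) %*% Conj(t(sv$u[, 1:p, drop = FALSE])) %*%
    Y1 %*% sv$v[, 1:p, drop = FALSE]
  z <- eigen(Zr, only.values = TRUE)$values
  f_hat <- Arg(z) / (2 * pi * dt) + f_coarse
  # complex amplitudes by least squares on the decimated samples
  td <- (seq_len(nd) - 1) * dt + t_in[1]
  E <- exp(2i * pi * outer(td, f_hat - f_coarse))
  cc <- qr.solve(E, y)
  amps <- Mod(cc)
  in_cluster <- f_hat > f_coarse - window & f_hat < f_coarse + 3 * window
  keep <- which(in_cluster & amps >= amp_gate * max(amps))
  if (!length(keep)) return(fallback)
  f_dir <- min(f_hat[keep])
  i_dir <- which(f_hat == f_dir)[1]
  # The pencil may still have merged an unresolved close reflection into the
  # direct component (pulling it a few Hz late). Subtract the other resolved
  # components and re-examine the direct line with an exact two-tone
  # maximum-likelihood grid fit, which has no resolution floor at high SNR;
  # the refinement is kept only when the second tone clearly improves the
  # single-tone residual.
  others <- setdiff(seq_along(f_hat), i_dir)
  y_res <- if (length(others)) {
    y - as.vector(E[, others, drop = FALSE] %*% cc[others])
  } else y
  comps <- f_hat[setdiff(which(in_cluster), i_dir)]
  fit1 <- ls2_refine(y_res, td, f_dir - f_coarse)
  f1 <- fit1$f1
  if (fit1$accepted) {
    comps <- c(comps, f_coarse + fit1$f2)
    # one deflation pass: remove the fitted reflection and re-fit, in case a
    # second unresolved reflection still pulls the direct tone
    y_res2 <- y_res - fit1$c2 * exp(2i * pi * fit1$f2 * td)
    fit2 <- ls2_refine(y_res2, td, fit1$f1)
    f1 <- fit2$f1
    if (fit2$accepted) comps <- c(comps, f_coarse + fit2$f2)
  }
  list(f_dir = f_coarse + f1, comps = unique(c(f_coarse + f1, comps)))
}

# Exact (unregularized) two-cisoid least-squares fit on the decimated
# segment: direct tone at f1 <= merged-peak + 2 Hz, reflection 6-30 Hz
# later. Returns list(f1, f2, c2, accepted); the two-tone solution is
# accepted on an F-type criterion — the residual improvement per extra
# complex parameter must clearly exceed the remaining residual variance —
# so a genuine unresolved reflection is split off while a pure tone in
# noise is left alone.
ls2_refine <- function(y, td, f_merge, f_min = 12) {
  n <- length(y)
  dt <- td[2] - td[1]
  t0 <- td[1]
  gram <- function(df) {
    if (abs(df) < 1e-12) return(complex(real = n))
    r <- exp(2i * pi * df * dt)
    exp(2i * pi * df * t0) * (1 - r^n) / (1 - r)
  }
  proj_at <- function(f) sum(Conj(exp(2i * pi * f * td)) * y)
  e_tot <- sum(Mod(y)^2)
  # best single tone near the merged peak
  fs1 <- seq(f_merge - 8, f_merge + 8, by = 0.2)
  p1s <- vapply(fs1, proj_at, complex(1))
  best1 <- max(Mod(p1s)^2 / n)
  f1s <- seq(f_merge - 8, f_merge + 2, by = 0.4)
  seps <- seq(6, 30, by = 0.8)
  pall <- vapply(sort(unique(as.vector(outer(f1s, c(0, seps), `+`)))),
                 proj_at, complex(1))
  fall <- sort(unique(as.vector(outer(f1s, c(0, seps), `+`))))
  best2 <- list(score = -Inf, f1 = f_merge, f2 = NA_real_,
                c2 = complex(real = 0))
  for (f1 in f1s) {
    pa <- pall[match(f1, fall)]
    for (s1 in seps) {
      pb <- pall[match(f1 + s1, fall)]
      g <- gram(s1)
      det <- n^2 - Mod(g)^2
      if (det < 0.05 * n^2) next
      c1 <- (n * pa - g * pb) / det
      c2 <- (n * pb - Conj(g) * pa) / det
      score <- Re(Conj(c1) * pa + Conj(c2) * pb)
      if (score > best2$score && Mod(c1) >= 0.6 * Mod(c2) &&
          Mod(c2) >= 0.12 * Mod(c1)) {
        best2 <- list(score = score, f1 = f1, f2 = f1 + s1, c2 = c2)
      }
    }
  }
  resid1 <- max(e_tot - best1, 0)
  resid2 <- max(e_tot - best2$score, .Machine$double.eps)
  f_stat <- ((resid1 - resid2) / 2) / (resid2 / max(n - 4, 1))
  if (is.finite(f_stat) && f_stat > f_min) {
    list(f1 = best2$f1, f2 = best2$f2, c2 = best2$c2, accepted = TRUE)
  } else {
    list(f1 = f_merge, f2 = NA_real_, c2 = complex(real = 0),
         accepted = FALSE)
  }
}

#' Track per-speaker distances through a recording
#'
#' Runs the per-frame pipeline — dechirp + DFT separation, SNR-adaptive
#' band-pass, phase inversion — for each active speaker, on frames segmented
#' by the (optionally beacon-aligned) transmitter timeline. Emits raw 1-D
#' distances \eqn{\tilde d_i(t)} (speaker-to-microphone plus a constant
#' pipeline offset removed later by calibration) at the chirp frame rate.
#'
#' Frames whose SNR falls below \code{snr_min}, or whose phase inversion finds
#' no usable root, are flagged invalid and hold the previous distance.
#'
#' @param rec a [render_received()] recording, or list(x, fs).
#' @param cfg,array chirp configuration and speaker array (defaults from the
#'   recording's scene).
#' @param clock_map a [beacon_align()] result, or NULL for the identity
#'   (unsynchronized) timeline.
#' @param c speed of sound, m/s.
#' @param snr_min validity threshold, dB (default 3).
#' @param width_bins passband width for [design_bandpass()].
#' @param t_phase_frac phase sampling time as a fraction of the chirp
#'   (default 0.5, i.e. t = T/2).
#' @param allow_unwrap let delays track continuously beyond one period
#'   (needed to follow large uncorrected clock drift); if FALSE delays are
#'   confined to \[0, T\].
#' @return object of class \code{"range_track"}: data.frame(frame, t, d1..,
#'   snr1.., valid) with one distance column per active speaker; attributes
#'   \code{cfg}, \code{array}, \code{c}, \code{clock_map}.
#' @export
track_distances <- function(rec, cfg = NULL, array = NULL, clock_map = NULL,
                            c = 343, snr_min = 3, width_bins = 4,
                            t_phase_frac = 0.5, allow_unwrap = TRUE) {
  if (is.null(cfg)) cfg <- rec$scene$cfg
  if (is.null(array)) array <- rec$scene$array
  if (!is.null(rec$scene$c)) c <- rec$scene$c
  if (is.null(clock_map)) clock_map <- identity_clock_map()
  # reuse a precomputed analytic signal when tracking one recording several
  # ways (e.g. the drift ladder)
  x <- if (!is.null(rec$xa)) rec$xa else analytic_signal(rec$x)
  N <- length(x)
  fs <- cfg$fs
  Tc <- cfg$T_chirp
  nf <- cfg$n_frame
  active <- array$active
  nsp <- length(active)
  M_max <- round(2 * fs * 0.030) / 2          # 30 ms group delay in samples
  pad_n <- M_max + 2

  # sample index (1-based) at which tx time tau occurs
  n_of_tau <- function(tau) (tau - clock_map$offset) / clock_map$alpha * fs + 1
  tau_of_n <- function(n) clock_map$alpha * (n - 1) / fs + clock_map$offset

  n_frames <- floor((tau_of_n(N) - 1e-9) / Tc)
  stop_if_not(n_frames >= 1, "waveform shorter than one frame")

  t_out <- numeric(n_frames)
  d_out <- matrix(NA_real_, n_frames, nsp)
  snr_out <- matrix(NA_real_, n_frames, nsp)
  valid <- matrix(FALSE, n_frames, nsp)
  # unwrapped total delay per speaker, initialized from a coherent
  # multi-frame window (assumes the session opens on a quiet interval)
  prior <- init_coarse_delays(x, tau_of_n, n_of_tau, cfg, active, c)
  filt_cache <- new.env(parent = emptyenv())

  for (k in seq_len(n_frames)) {
    tau0 <- (k - 1) * Tc
    t_out[k] <- tau0 + Tc / 2
    n_start <- ceiling(n_of_tau(tau0))
    lo <- n_start - pad_n
    hi <- n_start + nf - 1 + pad_n
    if (lo < 1 || hi > N) {
      d_out[k, ] <- d_out[max(k - 1, 1), ]
      next
    }
    idx <- lo:hi
    ref <- Conj(chirp_wave_at(tau_of_n(idx), 1, cfg))
    mixed <- x[idx] * ref
    off <- n_start - lo                       # frame start within `mixed`
    frame_m <- mixed[off + seq_len(nf)]
    if (all(frame_m == 0)) {
      d_out[k, ] <- d_out[max(k - 1, 1), ]
      next
    }
    sp <- frame_spectrum(frame_m, cfg, pad = 2)
    n_s <- round(n_of_tau(tau0 + t_phase_frac * Tc))
    t_in <- tau_of_n(n_s) - tau0
    n_s_loc <- n_s - lo + 1

    for (j in seq_len(nsp)) {
      s <- active[j]
      sh <- speaker_shift(s, cfg)
      if (!is.na(prior[j])) {
        fc_prior <- (cfg$B / Tc) * (prior[j] %% Tc)
        band <- fc_prior + c(-60, 60)
      } else {
        band <- speaker_band(s, cfg, c)
      }
      pk <- band_peak(sp, band, cfg)
      snr_out[k, j] <- pk$snr_db
      ok <- is.finite(pk$snr_db) && pk$snr_db >= snr_min
      if (ok) {
        delay <- if (pk$snr_db > 10) 0.015 else 0.030
        Mf <- round(fs * delay)
        if (n_s_loc - Mf >= 1 && n_s_loc + Mf <= length(mixed)) {
          fc_q <- round(pk$f_peak)            # 1 Hz cache quantization
          key <- paste0(Mf, "_", fc_q)
          flt <- filt_cache[[key]]
          if (is.null(flt)) {
            flt <- design_bandpass(pk$snr_db, fc_q, cfg, width_bins)
            filt_cache[[key]] <- flt
          }
          v <- fir_at(mixed, flt$h, Mf, n_s_loc)
          phi <- Arg(v)
          anchor <- if (!is.na(prior[j])) prior[j] else pk$tau_mod
          td_mod <- tof_candidates(phi, anchor %% Tc, t_in, cfg)
          if (!is.na(td_mod)) {
            td_tot <- td_mod + Tc * round((anchor - td_mod) / Tc)
            if (!allow_unwrap && (td_tot < 0 || td_tot > Tc)) {
              ok <- FALSE
            } else {
              d_out[k, j] <- c * (td_tot - sh)
              valid[k, j] <- TRUE
              prior[j] <- td_tot
            }
          } else ok <- FALSE
        } else ok <- FALSE
      }
      if (!valid[k, j] && k > 1) d_out[k, j] <- d_out[k - 1, j]
    }
  }

  out <- data.frame(frame = seq_len(n_frames), t = t_out)
  for (j in seq_len(nsp)) out[[paste0("d", active[j])]] <- d_out[, j]
  for (j in seq_len(nsp)) out[[paste0("snr", active[j])]] <- snr_out[, j]
  out$valid <- rowSums(valid) == nsp
  structure(out, class = c("range_track", "data.frame"),
            cfg = cfg, array = array, c = c, clock_map = clock_map)
}

#' @export
print.range_track <- function(x, ...) {
  cat(sprintf("Range track: %d frames (%.1f s), %.0f%% valid\n",
              nrow(x), max(x$t) - min(x$t), 100 * mean(x$valid)))
  dcols <- grep("^d[0-9]+$", names(x), value = TRUE)
  for (dc in dcols) {
    cat(sprintf("  %s: median %.4f m\n", dc,
                stats::median(x[[dc]], na.rm = TRUE)))
  }
  invisible(x)
}

#' Write / read a range track as CSV
#' @param rt a \code{"range_track"}.
#' @param path CSV file.
#' @export
write_range_track <- function(rt, path) {
  utils::write.csv(as.data.frame(rt), path, row.names = FALSE)
  invisible(path)
}
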
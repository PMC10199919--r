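---
title: "Acoustic FMCW height tracking and hydrostatic pressure correction: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Acoustic FMCW height tracking and hydrostatic pressure correction: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(acuheight)
```

## The measurement problem

Invasive arterial pressure is read through a fluid-filled line against a
transducer. The reading is only meaningful when the transducer sits level
with the patient's hydrostatic reference point (the right atrium): every
centimetre of height mismatch adds 0.735 mmHg of hydrostatic bias, so a
10 cm leveling error — common in practice — corrupts the mean arterial
pressure (MAP) by about 7.4 mmHg. `acuheight` implements an automatic
alternative: a pole-mounted speaker array emits inaudible chirps, a
coin-cell wearable on the patient's chest records them, and the tracked
height of the wearable drives a software correction of the stationary
transducer's reading.

The package contains both the estimation pipeline and a seeded scene
simulator, so every stage can be exercised end to end with known ground
truth.

## Signal model

Each of three active speakers on a square array of side $L$ transmits a
periodic linear chirp sweeping $f_0 = 18$ kHz to $f_1 = 22$ kHz
(bandwidth $B = 4$ kHz) over $T = 43$ ms, speaker $i$ delayed by
$(i-1)\,T/5$. The wearable's microphone samples at 50 kHz (a 3.2 MHz PDM
clock decimated by 64). The received signal is a sum over speakers and
propagation paths of attenuated, delayed chirp copies plus noise; the
simulator renders it by evaluating the chirp phase in continuous time at
the delayed, clock-warped emission instants, which is exact for arbitrary
sub-sample delays and slow device motion.

Dechirping (multiplying by the conjugate reference chirp) turns each path
delay $t_d$ into a beat tone at $(B/T)\,t_d$ whose phase at time $t$
within the chirp is

$$\phi(t) \;=\; -2\pi\!\left(\tfrac{B}{T}\,t\,t_d + f_0\,t_d -
\tfrac{B}{2T}\,t_d^2\right).$$

The tracker's fine ranging inverts this quadratic for $t_d$ from the phase
sampled at $t = T/2$ (configurable), selecting among the $2\pi$-ambiguous
candidates (spaced about $1/(f_0{+}B/2) = 50\ \mu s$, i.e. 1.7 cm) the one
nearest the previous frame's delay, or a coarse initialization at start-up.

### Initialization and body multipath

Reflections from the patient's body arrive a few centimetres behind the
direct path — beat offsets of 10–60 Hz, below the $1/T = 23$ Hz resolution
of a single frame — and can pull the single-frame beat peak past half a
wavelength, which would start the phase tracker an integer number of
cycles off. Initialization therefore works on the common steady window of
the dechirped frame (past every speaker's sweep reset, where each
speaker's beat cluster is a clean set of cisoids), coherently averaged
over 32 frames, and proceeds in two passes. Pass one estimates each
cluster's line spectrum with a matrix-pencil (ESPRIT-type) fit after
decimation; when the pencil has merged a close reflection into the direct
component, an exact two-tone least-squares fit — which has no resolution
floor at high SNR — splits it, accepted on an F-type criterion (residual
improvement per extra parameter against the remaining residual variance)
so that a pure tone in noise is left alone. Pass two re-fits all clusters
jointly at full rate, subtracts the other speakers' clusters (reflections
included) from each speaker's view, and repeats the refinement — without
this, cross-cluster residual flattens the likelihood basin and limits the
direct-tone accuracy to the ambiguity threshold. The direct path is
always the lowest-frequency component of substantial amplitude (a body
reflection is at most about half the direct amplitude; the simulator
enforces that summed body multipath stays below the direct path, matching
the occlusion-free operating assumption). Residual initialization errors
of one wavelength survive in adversarial configurations with several
near-coincident reflections; they appear as a centimetre-scale height
offset for that session and are the main tail contributor in the
benchmark error distribution.

### SNR-adaptive filtering

Before the phase readout, each speaker's beat line is isolated by a
linear-phase FIR band-pass whose group delay follows the per-frame SNR:
15 ms (1501 taps at 50 kHz) above 10 dB, 30 ms (3001 taps) at or below,
trading latency for a narrower transition when conditions are poor. The
passband spans 4 frame-rate bins (93 Hz) around the peak; group delay is
compensated exactly, and the complex (single-sideband) filter also rejects
the mixing image. Reported SNR refers the beat-line amplitude (scaled by
the effective window mass of the tone's span within the frame) to the
white-noise floor estimated from a quiet region of the beat axis.

## Clock-drift correction

Both devices run free $\pm 20$ ppm oscillators; the worst-case 40 ppm
relative error accumulates 2.4 ms of timing drift per minute — at
343 m/s an apparent range drift of 0.82 m per minute, which unconstrained
reaches metre scale within minutes. Correction is two-stage:

1. **Beacon alignment.** The transmitter broadcasts ~200 Hz radio beacons
   carrying its free-running 16 MHz timer (wrapping at 800 000 ticks,
   ~20 Hz). Both tick streams are unwrapped and transmitter time is
   regressed on receiver time; the slope is the drift factor. The tracker
   applies the mapping by evaluating its dechirp reference on the mapped
   transmitter timeline, which is algebraically equivalent to resampling
   the received stream by the drift factor (the frequency-shifted-basis
   resampling is implemented as its own operation,
   `resample_with_drift()`), but exact and linear-time. With 62.5 ns tick
   quantization and ~20 µs beacon jitter averaged over thousands of
   beacons, the residual timeline error is microseconds-scale or below.

2. **Regression post-processing.** Any residual drift appears as a slow
   linear trend in the per-speaker distances. The trailing 5 minutes of
   history are split into 30 s chunks, a line is fitted per chunk, chunks
   are ranked by residual sum of squares, and the mean slope of the better
   (lower-residual) half — `floor(n/2)` of them when n is odd — is
   subtracted forward in the distance domain. Chunks are confined to
   motion-free stretches (IMU-flagged), since a bed transition inside a
   chunk would masquerade as drift; static stretches shorter than ~3/4 of
   a chunk contribute nothing, so a session with no long quiet interval
   simply gets no correction. The distance-domain slope $s$ (cm/s) is
   equivalent to a sampling drift factor $\alpha = 1 + s/(100c)$ to first
   order; the distance-domain form is applied because it is directly
   testable. The correction is applied to each per-speaker distance
   rather than to the height (both routes are exposed; the per-speaker
   route also repairs the lateral coordinates).

In this simulator the beacon stage alone already reaches sub-millimetre
residuals on a 10-minute static scene, so the regression stage's marginal
contribution on that scene is small; its value is demonstrated separately
by parameter-recovery tests with injected drift and corrupted chunks.

## From distances to height

Calibration places the wearable at a known stand-off (default 5 cm on the
array axis — "right next to" the array, but a defined geometry) and
records per-speaker offsets $D_i$ = mean raw distance minus true geometric
distance; subsequent distances are absolute. With
$\bar d = (d_1{+}d_2{+}d_3)/3$,

$$X = \bar d\,(d_1 - d_2)/L,\quad Y = \bar d\,(d_1 - d_3)/L,\quad
Z = \sqrt{\bar d^2 - X^2 - Y^2}.$$

Speakers are laid out so the $d_1{-}d_2$ pair forms the x baseline and
$d_1{-}d_3$ the y baseline with positive sign — the layout is part of the
geometry contract, chosen so these equations return $(+x, +y)$.

This plane-wave (far-field) solution biases $Z$ upward by roughly
$L^2/(4\,\mathrm{range})$. That drove the default array size: at
$L = 0.2$ m the bias is 1.25 cm at 0.8 m range — already above the
benchmark's accuracy bar by geometry alone — while at the default
$L = 0.1$ m (a compact pole-head array) it stays at or below ~0.3 cm over
most of the 0.2–2 m working range. Height *changes*, the clinically
relevant quantity, cancel the bias to well under a millimetre. Frames
whose distances are geometrically inconsistent (negative radicand) are
flagged invalid and hold the previous height; more than 5 s of continuous
invalidity marks the segment unreliable.

### IMU gating

An ultra-low-power accelerometer distinguishes occlusions from true
height changes: with no motion flagged, the output height is held
constant regardless of the acoustics; when motion is flagged, tracking
resumes and continues until the height stabilizes (standard deviation
below 0.3 cm over a 2 s window with no motion and no invalid frames), at
which point the window mean is latched. If an occlusion outlasts the
motion, tracking simply continues until the occlusion clears and the
height stabilizes. The simulator's accelerometer surrogate flags frames
where $|\ddot z|$ exceeds 0.05 m/s² (no threshold is prescribed by the
hardware model; this is the simplest testable surrogate), latched across
sub-half-second gaps the way a wake interrupt would be.

## Pressure correction

With $\Delta_{transducer} = MAP_{c,0} - MAP_{p,0}$ read once at the lowest
bed height, and $\Delta h$ the tracked height change in cm,

$$MAP = MAP_s - 0.735\,\Delta h + \Delta_{transducer}.$$

The 0.735 mmHg/cm factor is treated as a fixed constant of the blood
column (no temperature or density adjustment). All computation is full
precision; display rounding (half away from zero, so 7.35 → 7.4) happens
only at the reporting layer. Only mean pressure is corrected — systolic
and diastolic extremes are sensitive to waveform damping and are out of
scope.

## The scene simulator

`render_received()` emulates what the wearable records: per-speaker direct
paths that follow the scripted trajectory, body reflections specified as
excess path length (they ride along with the device) and relative
amplitude, optional fixed distant reflections, scripted occlusion
intervals (the direct amplitude is scaled down while reflections persist),
clothing attenuation as a scalar dB on the through-body paths, white
Gaussian noise scaled to a per-speaker direct-path SNR, optional
out-of-band alarm tones, both clock drifts, quantized and jittered
beacons, respiration as a sinusoidal z modulation (`respiration_pp =
0.005` means a 0.5 cm swing, ±0.25 cm), and an IMU stream. Identical
seeds give bit-identical output.

What it does not emulate — and what passing tests therefore cannot show —
includes room-acoustics reverberation beyond the explicit path list,
speaker/microphone transfer functions, Doppler within a chirp (device
speeds are cm/s), radio packet loss, and real patient/clinician behavior.
The clinical numbers reported for the real system (bias 0.19 mmHg,
SD 2.8 mmHg over 243 paired measurements) depend on patient physiology
(beat-to-beat MAP variation, chest motion) and dual-transducer plumbing;
the simulator represents these only as parametric noise terms, so the
package's clinical-scale checks are parameter-recovery checks, not
reproductions of patient data.

## Study conditions and problem sizes

The evaluation studies fix these conditions:

* **Static sweep** (`static_sweep()`): device-to-array range uniform on
  0.2–2 m with lateral offsets up to ±0.3 m (bed scale), one body
  reflection per speaker with relative amplitude 0.1–0.5 and excess path
  5–20 cm, SNR 15–25 dB, ±20 ppm clocks on both sides, 200 Hz beacons,
  4 s per scene with a 1 s warm-up, shared calibration. 100 scenes in the
  acceptance run, 40 in the test suite.
* **Drift ladder** (`drift_ladder()`): one 10-minute static scene at
  40 ppm relative drift, tracked three ways (no sync, beacon sync,
  beacon + regression); accumulated drift is the difference of 30 s
  end-window means of the first speaker's distance (under fully
  uncorrected drift the later speakers' apparent delays leave their chirp
  period within ten minutes, so the first speaker provides the clean
  unwrapped readout).
* **Bed session** (`bed_session_benchmark()`): ten plateaus at 0–45 cm in
  5 cm steps, 10 s dwell and 2 s raised-cosine transitions (compressed
  dwells keep the session under two minutes; the protocol they emulate
  dwells far longer), respiration on, transducer device noise off for the
  height-recovery check, beat-to-beat MAP variability 1.5 mmHg,
  inter-transducer offset drawn from N(0.8, 1.9²) mmHg per session.

## Numerical choices and edge cases

* Fractional delays: closed-form phase evaluation in continuous time (no
  interpolation error), rather than frequency-domain phase shifts — same
  intent, stronger guarantee.
* Frame segmentation trusts the transmit schedule on the beacon-aligned
  timeline rather than detecting chirp boundaries; the localizer knows
  its own schedule.
* Phase-stage validity: frames below 3 dB SNR, or with no admissible
  quadratic root, hold the last distance and are flagged.
* The phase tracker may follow delays beyond one chirp period
  (`allow_unwrap`), needed only when drift is deliberately left
  uncorrected.
* Ties and degeneracies: odd chunk counts keep `floor(n/2)` chunks;
  chunks need ≥10 samples and ≥3/4 of the nominal span; calibration
  requires ≥10 valid frames and no motion flags.
* ICC is ICC(2,1), two-way single-measure absolute agreement (the
  standard for method comparison); ICC(3,1) is available via `icc_type`.
* The update rate is the native frame rate 1/T ≈ 23 Hz with
  non-overlapping frames; overlapping frames would raise it and are noted
  as an extension.

## Known limitations

* The λ/2 integer ambiguity is resolved statistically, not provably; an
  adversarial pair of close reflections can still offset a session by
  1.7 cm (a few percent of benchmark scenes).
* The far-field height bias grows as $L^2/(4\,\mathrm{range})$ and is not
  subtracted, because the closed-form equations are the method; at ranges
  below ~0.3 m it approaches a centimetre even at $L = 0.1$ m.
* Drift regression needs ≥30 s motion-free stretches; sessions in
  constant motion receive no residual correction.
* The simulator's direct-path-dominance constraint is an operating
  assumption, not a law of hospital rooms; heavy occlusion is handled by
  gating, not by ranging through the occluder.
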
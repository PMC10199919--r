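# acuheight

Acoustic FMCW height tracking of a chest-worn wearable, with automatic
hydrostatic correction of invasive arterial pressure.

## The problem

Invasive arterial blood pressure is read against a transducer that must sit
level with the patient's hydrostatic reference point (the right atrium).
Every centimetre of height mismatch biases the reading by 0.735 mmHg — a
10 cm leveling error is a 7.4 mmHg error in mean arterial pressure (MAP) —
and in practice the transducer is re-leveled by hand every time the bed
moves. `acuheight` implements a system that tracks the height of a
coin-cell wearable microphone relative to a pole-mounted speaker array
emitting inaudible 18–22 kHz frequency-modulated continuous-wave (FMCW)
chirps, and uses the tracked height to correct the stationary transducer's
MAP in software. It is aimed at researchers in physiological monitoring and
acoustic localization who want a complete, testable reference
implementation with a ground-truth simulator.

## The method in brief

Three speakers on a square of side *L* transmit a periodic chirp
(f₀ = 18 kHz → f₁ = 22 kHz, T = 43 ms), speaker *i* shifted by (i−1)T/5.
Dechirping the received signal maps each path delay *t_d* to a beat tone at
(B/T)·t_d with phase

φ(t) = −2π( (B/T)·t·t_d + f₀·t_d − (B/2T)·t_d² ),

which is inverted for *t_d* (sub-millimetre precision; an SNR-adaptive
linear-phase FIR first isolates the direct path from body multipath). Clock
drift between the two free-running ±20 ppm oscillators is corrected by
radio time-sync beacons plus a sliding-window regression on the height
history. With calibrated per-speaker offsets, positions follow from the
difference equations

X = d̄(d₁−d₂)/L, Y = d̄(d₁−d₃)/L, Z = √(d̄² − X² − Y²),

gated by an accelerometer so occlusions cannot masquerade as height
changes. The corrected pressure is

MAP = MAP_s − 0.735·Δh + Δ_transducer.

A seeded scene simulator renders everything the wearable records (paths,
multipath, noise, clock drift, beacons, respiration, IMU), so the full
pipeline runs end to end against known truth.

## Worked example

```r
library(acuheight)
cfg   <- chirp_config()                     # 18-22 kHz, 43 ms, 50 kHz
array <- speaker_array(L = 0.1)             # 10 cm square, speakers 1-3 active
clocks <- clock_model(ppm_tx = -20, ppm_rx = 20)

# a patient 0.9 m below the array, one body reflection, 20 dB SNR
scene <- acoustic_scene(array, cfg,
                        static_trajectory(c(0.03, -0.02, 0.9)),
                        body_paths = data.frame(excess = 0.10, rel_amp = 0.3),
                        noise_snr_db = 20, clocks = clocks)
rec <- render_received(scene, duration = 4, seed = 1)
cal <- calibration_run(cfg, array, clocks, seed = 1)
ht  <- run_tracker(rec, calibration = cal)
print(ht)
#> Height track: 93 frames over 4.0 s, 98% valid
#>   Z: median 0.9029 m; h: -0.03 to 0.04 cm from start
```

The tracked height sits 2.9 mm above the true 0.9 m — the plane-wave
far-field bias of the difference-based triangulation at this range (height
*changes* cancel it) — and the height-change track stays within ±0.04 cm on
a static scene. The clock map recovered ≈ −39 ppm of relative drift from
the beacon log (the scene injected 40 ppm).

```r
# hydrostatic MAP correction for a 20 cm bed raise read on a stationary
# transducer (baseline offset 1.5 mmHg between the two transducers)
corrected_map(MAP_s = 94.7, delta_h_cm = 20, delta_transducer = 1.5)
#> [1] 81.5
round_half_up(height_to_pressure(10), 1)
#> [1] 7.4
```

Higher-level studies: `static_sweep()` (position-accuracy benchmark),
`drift_ladder()` (10-minute drift with none / beacon / beacon+regression
correction), `bed_session_benchmark()` (scripted 0–45 cm bed protocol
through to corrected MAP), and `agreement()` (bias ± SD, error CDF,
ICC(2,1)). A thin command-line front end over these functions is installed
at `inst/cli/acuheight.R` (`simulate`, `track`, `correct`, `bench`).

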
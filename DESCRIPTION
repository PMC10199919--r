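Package: acuheight
Title: Acoustic FMCW Height Tracking for Automatic Arterial-Pressure
    Transducer Leveling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Simulates and processes near-ultrasonic frequency-modulated
    continuous-wave (FMCW) chirps transmitted from a small speaker array to a
    wearable microphone, recovering the 3-D position of the wearable from
    per-speaker time-of-flight estimates.  Includes a two-stage clock-drift
    correction (radio time-sync beacons plus sliding-window regression on the
    height history), phase-based fine ranging that rejects body multipath,
    IMU-gated height tracking, hydrostatic correction of invasive mean
    arterial pressure read from a stationary transducer, a duty-cycled power
    model for the wearable, and method-agreement statistics (bias, SD,
    intraclass correlation).  A seeded acoustic/clinical scene simulator
    generates received waveforms, IMU and beacon sidecars, and paired
    transducer pressure series for end-to-end evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    signal,
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
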
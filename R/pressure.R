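# Hydrostatic correction of invasive mean arterial pressure (MAP) measured by
# a stationary transducer, using the tracked height of the patient's
# hydrostatic reference point.

#' Hydrostatic conversion constant, mmHg per cm of blood column
#' @export
MMHG_PER_CM <- 0.735

#' Inter-transducer baseline offset
#'
#' Difference between the clinical (patient-levelled) and stationary
#' transducers read simultaneously at the lowest bed height:
#' \code{MAP_c0 - MAP_p0}. Added back when correcting the stationary reading.
#'
#' @param MAP_c0 baseline clinical-transducer mean, mmHg.
#' @param MAP_p0 baseline stationary-transducer mean, mmHg.
#' @return offset, mmHg.
#' @export
transducer_offset <- function(MAP_c0, MAP_p0) {
  stop_if_not(is.finite(MAP_c0) && is.finite(MAP_p0),
              "missing baseline measurement")
  MAP_c0 - MAP_p0
}

#' Convert a height difference to its hydrostatic pressure equivalent
#'
#' Each centimetre of blood-column height corresponds to 0.735 mmHg; a 10 cm
#' transducer-height error is a 7.4 mmHg pressure error (to one decimal), a
#' 0.5 cm respiration-scale height variation 0.4 mmHg.
#'
#' @param delta_h_cm height difference, cm.
#' @return pressure, mmHg (full precision; use [round_half_up()] for display).
#' @export
height_to_pressure <- function(delta_h_cm) {
  stop_if_not(all(is.finite(delta_h_cm)), "height must be finite")
  MMHG_PER_CM * delta_h_cm
}

#' Hydrostatically corrected mean arterial pressure
#'
#' \deqn{MAP = MAP_s - 0.735\,\Delta h + \Delta_{transducer}.}
#' The identical formula serves the laser-derived heights and the acoustic
#' tracker's heights; only the height source differs.
#'
#' @param MAP_s stationary-transducer reading, mmHg.
#' @param delta_h_cm height of the reference point above its baseline, cm.
#' @param delta_transducer [transducer_offset()] value, mmHg (default 0).
#' @return corrected MAP, mmHg.
#' @export
corrected_map <- function(MAP_s, delta_h_cm, delta_transducer = 0) {
  stop_if_not(all(is.finite(MAP_s)) && all(is.finite(delta_h_cm)) &&
                all(is.finite(delta_transducer)), "inputs must be finite")
  MAP_s - height_to_pressure(delta_h_cm) + delta_transducer
}

#' Simulate a paired two-transducer pressure session
#'
#' Generates, per bed plateau, the clinical transducer reading (levelled with
#' the patient: the ground truth plus device noise) and the stationary
#' transducer reading (fixed at the lowest height: truth plus the hydrostatic
#' column of the bed excursion, plus a per-session inter-transducer offset and
#' device noise). Beat-to-beat MAP variability perturbs the underlying truth
#' between plateaus.
#'
#' @param delta_h_true_cm true bed heights above the first plateau, cm.
#' @param map_base underlying mean arterial pressure, mmHg (default 80).
#' @param beat_sd beat-to-beat MAP variability between measurements, mmHg
#'   (default 1.5).
#' @param offset_mean,offset_sd distribution of the per-session
#'   inter-transducer offset, mmHg (defaults 0.8 and 1.9, the scale observed
#'   when two transducers are levelled together).
#' @param noise_sd per-reading transducer device noise, mmHg (default 0.5,
#'   i.e. within the +/- 1 mmHg device specification); 0 disables it.
#' @param seed RNG seed.
#' @return data.frame(plateau, delta_h_true_cm, MAP_true, MAP_c, MAP_s) with
#'   attribute \code{"offset"} (the drawn inter-transducer offset).
#' @export
simulate_pressure_session <- function(delta_h_true_cm, map_base = 80,
                                      beat_sd = 1.5, offset_mean = 0.8,
                                      offset_sd = 1.9, noise_sd = 0.5,
                                      seed = 1) {
  n <- length(delta_h_true_cm)
  with_seed(seed, {
    offset <- stats::rnorm(1, offset_mean, offset_sd)
    map_true <- map_base + stats::rnorm(n, 0, beat_sd)
    map_c <- map_true + stats::rnorm(n, 0, noise_sd)
    map_s <- map_true + MMHG_PER_CM * delta_h_true_cm - offset +
      stats::rnorm(n, 0, noise_sd)
    out <- data.frame(plateau = seq_len(n),
                      delta_h_true_cm = delta_h_true_cm,
                      MAP_true = map_true, MAP_c = map_c, MAP_s = map_s)
    attr(out, "offset") <- offset
    out
  })
}

#' Correct a pressure session with tracked heights
#'
#' Applies the full correction chain to a simulated (or recorded) session:
#' the inter-transducer offset from the first plateau's baselines, then the
#' hydrostatic correction with the supplied height changes.
#'
#' @param session data.frame as from [simulate_pressure_session()].
#' @param delta_h_cm height changes used for correction (tracker or laser),
#'   cm, one per row of \code{session}.
#' @return \code{session} with columns \code{delta_h_cm}, \code{MAP_corr}
#'   added, and attribute \code{"delta_transducer"}.
#' @export
correct_pressure_session <- function(session, delta_h_cm) {
  stop_if_not(length(delta_h_cm) == nrow(session),
              "one height change per session row")
  dtr <- transducer_offset(session$MAP_c[1], session$MAP_s[1])
  session$delta_h_cm <- delta_h_cm
  session$MAP_corr <- corrected_map(session$MAP_s, delta_h_cm, dtr)
  attr(session, "delta_transducer") <- dtr
  session
}
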
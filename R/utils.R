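# internal helpers shared across modules

#' Round half away from zero
#'
#' Display rounding used for reported pressures: ties round away from zero
#' (so 7.35 -> 7.4), unlike [base::round()]'s round-half-even. A small
#' relative guard absorbs binary representation error in values that are
#' exact in decimal.
#'
#' @param x numeric vector.
#' @param digits decimal places (default 1).
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

db_to_lin <- function(db) 10^(db / 20)
lin_to_db <- function(x) 20 * log10(x)
pow_to_db <- function(p) 10 * log10(p)

#' @keywords internal
stop_if_not <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)

# Evaluate an RNG-dependent expression under a fixed seed without disturbing
# the caller's RNG stream.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed) %% .Machine$integer.max)
  force(expr)
}

# Linear interpolation of a piecewise-linear knot sequence, constant beyond
# the end knots.
interp_knots <- function(t_knots, v_knots, t) {
  stats::approx(t_knots, v_knots, xout = t, rule = 2)$y
}
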
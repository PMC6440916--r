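#' Terraced stimulus function of deviation from the optimal concentration
#'
#' Sum of two logistic terms centered at `-W1` and `+W1`, minus one:
#' `stim(x) = 1/(1 + exp(-K (x - W1))) + 1/(1 + exp(-K (x + W1))) - 1`.
#' The function is odd, strictly increasing, bounded in (-1, 1), and has a
#' plateau near zero for deviations well inside the half-width `W1`, so small
#' or brief departures from the optimum do not trigger the downstream
#' adaptive response.
#'
#' @param x deviation(s) from the optimal concentration (same units as the
#'   species: mg/dL for calcium and phosphate, D units for 1,25D).
#' @param K logistic steepness (> 0, inverse concentration units).
#' @param W1 half-width of the central plateau (> 0, concentration units).
#' @return stimulus value(s) in (-1, 1); 0 at `x = 0`.
#' @export
#' @examples
#' stim(0, K = 2.5, W1 = 2.5)      # 0: optimal conditions
#' stim(-1.1, K = 2.5, W1 = 2.5)   # phosphate at the low end of its range
stim <- function(x, K, W1) {
  if (K <= 0 || W1 <= 0) stop("K and W1 must be positive", call. = FALSE)
  stats::plogis(K * (x - W1)) + stats::plogis(K * (x + W1)) - 1
}

#' Mean slope of a stimulus function over an interval
#'
#' Difference quotient `(stim(x2) - stim(x1)) / (x2 - x1)`, used to verify
#' that the stimulus stays nearly flat across a species' physiological
#' reference range.
#'
#' @param K,W1 stimulus constants, as in [stim()].
#' @param x1,x2 interval endpoints as deviations from the optimum, `x2 > x1`.
#' @return the mean slope (per concentration unit).
#' @export
mean_stimulus_slope <- function(K, W1, x1, x2) {
  stopifnot(x2 > x1)
  (stim(x2, K, W1) - stim(x1, K, W1)) / (x2 - x1)
}

#' Time derivative of a bounded effect state
#'
#' Effect states integrate a stimulus with a characteristic lag while staying
#' inside (-1, 1): `de/dt = (s (1 - sign(s) e) - e) tau`, with `sign(0) = 0`.
#' The relaxation scalar `tau` (per minute) sets the critical time after
#' which a sustained stimulus produces a response.
#'
#' @param e current effect state(s), `|e| < 1`.
#' @param s stimulus value(s) in `[-1, 1]`.
#' @param tau relaxation scalar (> 0, per minute).
#' @return `de/dt` (per minute).
#' @export
effect_state_rhs <- function(e, s, tau) {
  if (any(tau <= 0)) stop("tau must be positive", call. = FALSE)
  (s * (1 - sign(s) * e) - e) * tau
}

#' Fixed point of the effect-state dynamics under a constant stimulus
#'
#' Closed form `e* = s / (1 + |s|)`; used for initialization and as the
#' analytic check for convergence tests.
#'
#' @param s constant stimulus value(s), `|s| <= 1`.
#' @return the equilibrium effect state(s), inside `(-1, 1)` and of the same
#'   sign as `s`.
#' @export
effect_state_steady <- function(s) {
  s / (1 + abs(s))
}
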
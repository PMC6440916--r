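#' Signaling-pathway activity dynamics
#'
#' Each CaSR signaling pathway (intracellular PTH degradation, PTH
#' production, cell proliferation) carries an activity `chi` with optimum 1,
#' driven by its own calcium and phosphate effect states:
#' `dchi/dt = p (chi_in - pi_in) chi + n (1 - chi)`. Calcium enters through
#' the sensed concentration, phosphate through the raw serum value; 1,25D
#' acts only indirectly via the receptor feedback on sensed calcium. The
#' three pathways share this form but differ in their relaxation scalars,
#' giving response times of minutes (degradation), hours (production), and
#' days to weeks (proliferation).
#'
#' @param chi pathway activity (unitless, optimum 1).
#' @param chi_in,pi_in calcium and phosphate effect states of this pathway.
#' @param pp pathway parameter block (e.g. `params$pathways$production`).
#' @return `dchi/dt` (per minute).
#' @export
pathway_rhs <- function(chi, chi_in, pi_in, pp) {
  pp$p * (chi_in - pi_in) * chi + pp$n * (1 - chi)
}

# Linear interpolation between the extreme rate (activity 0) and the basal
# rate (activity 1), clamped to the physiologic band outside [0, 1].
rate_band <- function(activity, basal, extreme) {
  if (length(activity) == 1L) {
    x <- if (activity >= 1) 1 else if (activity <= 0) 0 else activity
    return(extreme + (basal - extreme) * x)
  }
  extreme + (basal - extreme) * pmin(pmax(activity, 0), 1)
}

#' Intracellular PTH degradation rate
#'
#' Basal `A` at full CaSR signaling (activity >= 1), falling linearly to the
#' minimum `B = A/2` as signaling is lost; clamped to `[B, A]` outside the
#' unit activity interval.
#'
#' @param c_d degradation-pathway signaling activity.
#' @param pp degradation parameter block (`params$pathways$degradation`).
#' @return degradation rate (per minute).
#' @export
#' @examples
#' pp <- default_parameters()$pathways$degradation
#' degradation_rate(1, pp)  # basal, 0.012/min
#' degradation_rate(0, pp)  # minimum, 0.006/min
degradation_rate <- function(c_d, pp) {
  rate_band(c_d, pp$A, pp$B)
}

#' PTH production rate
#'
#' Basal `A` at full CaSR signaling, rising linearly to the maximum
#' `B = 2A` when signaling is lost; clamped to `[A, B]`.
#'
#' @param c_p production-pathway signaling activity.
#' @param pp production parameter block (`params$pathways$production`).
#' @return production rate (model PTH amount units per unit secretory cell
#'   mass per minute).
#' @export
production_rate <- function(c_p, pp) {
  rate_band(c_p, pp$A, pp$B)
}

#' Cell proliferation rate
#'
#' Basal `A` at full CaSR signaling, rising linearly to the maximum
#' `B = 2A` when signaling is lost; clamped to `[A, B]`.
#'
#' @param c_pr proliferation-pathway signaling activity.
#' @param pp proliferation parameter block (`params$pathways$proliferation`).
#' @return proliferation rate (per minute).
#' @export
proliferation_rate <- function(c_pr, pp) {
  rate_band(c_pr, pp$A, pp$B)
}
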
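#' Receptor sensitivity map
#'
#' Affine map from total receptor expression (CaSR + VDR, optimum 2) to the
#' fraction of the blood concentration the gland effectively senses:
#' `sens(x) = a_s + (1 - a_s) x / 2`. Full expression gives sensitivity 1;
#' complete loss of expression floors at `a_s`. Expression can transiently
#' exceed its optimum, so inputs outside [0, 2] are clamped (with a warning
#' from this R-level function; the compiled integrator clamps silently).
#'
#' @param x sum of the dimensionless CaSR and VDR expressions.
#' @param a_s sensitivity floor, in (0, 1].
#' @return sensitivity value(s) in `[a_s, 1]`.
#' @export
#' @examples
#' sens(1.6, 0.5)  # 0.9: the gland senses 90% of the actual concentration
sens <- function(x, a_s) {
  stopifnot(a_s > 0, a_s <= 1)
  if (any(x < 0 | x > 2)) {
    warning("receptor expression sum outside [0, 2]; clamped", call. = FALSE)
    x <- pmin(pmax(x, 0), 2)
  }
  a_s + (1 - a_s) * (x / 2)
}

#' Receptor expression dynamics
#'
#' CaSR and VDR expressions (optimum normalized to 1) are coupled by mutual
#' positive feedback and suppressed by phosphate:
#' `dCaSR/dt = p_ca (chi_in + (VDR - 1) - pi_in) CaSR + n_ca (1 - CaSR)` and
#' symmetrically for VDR with the 1,25D effect state `delta_in`. The
#' multiplicative form keeps both expressions positive; no ceiling is
#' imposed.
#'
#' @param casr,vdr dimensionless receptor expressions (> 0).
#' @param chi_in,delta_in,pi_in effect states of sensed calcium, sensed
#'   1,25D, and raw phosphate.
#' @param ep expression parameter block (`params$expression`).
#' @return named numeric vector `c(casr = dCaSR/dt, vdr = dVDR/dt)`.
#' @export
expression_rhs <- function(casr, vdr, chi_in, delta_in, pi_in, ep) {
  c(casr = ep$p_ca * (chi_in + (vdr - 1) - pi_in) * casr + ep$n_ca * (1 - casr),
    vdr  = ep$p_d * (delta_in + (casr - 1) - pi_in) * vdr + ep$n_d * (1 - vdr))
}

#' Sensed-concentration dynamics
#'
#' The sensed calcium and 1,25D track the blood values scaled by the
#' receptor sensitivity with a first-order lag of one minute:
#' `dCS/dt = sens(CaSR + VDR) C - CS`, `dDS/dt = sens(CaSR + VDR) D - DS`.
#' A gland with reduced receptor expression "senses" less calcium than is
#' present, which shifts the apparent release set-point.
#'
#' @param cs,ds current sensed calcium (mg/dL) and sensed 1,25D (D units).
#' @param casr,vdr receptor expressions.
#' @param C,D blood ionized calcium (mg/dL) and 1,25D (D units).
#' @param a_s sensitivity floor.
#' @return named numeric vector `c(cs = dCS/dt, ds = dDS/dt)` (per minute).
#' @export
sensed_rhs <- function(cs, ds, casr, vdr, C, D, a_s) {
  sv <- sens_clamped(casr + vdr, a_s)
  c(cs = sv * C - cs, ds = sv * D - ds)
}

# silent clamped variant used inside RHS compositions
sens_clamped <- function(x, a_s) {
  if (length(x) == 1L) {
    if (x < 0) x <- 0 else if (x > 2) x <- 2
    return(a_s + (1 - a_s) * (x / 2))
  }
  a_s + (1 - a_s) * (pmin(pmax(x, 0), 2) / 2)
}
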
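#' Sigmoidal PTH release rate
#'
#' The classic steep sigmoidal calcium-PTH relation:
#' `release(CS) = B + (A - B) / (1 + (CS / S_r)^m)`, evaluated in log space
#' because the Hill-type exponent `m = 50` overflows naive powers. Release is
#' maximal (`A`) at vanishing sensed calcium, minimal (`B`) at high calcium,
#' and halfway at the set-point `S_r`. Reduced receptor expression lowers
#' sensed calcium and thereby shifts the apparent set-point without changing
#' `S_r` itself.
#'
#' @param cs_mmol sensed calcium in mmol/L (convert inputs with
#'   [ca_mgdl_to_mmol()]); must be non-negative.
#' @param gp gland parameter block (`params$gland`).
#' @return release rate(s) in pmol/min, strictly decreasing in `cs_mmol` and
#'   bounded in `[B, A]`.
#' @export
#' @examples
#' gp <- default_parameters()$gland
#' release_rate(gp$s_r, gp)  # Hill midpoint (A + B)/2
release_rate <- function(cs_mmol, gp) {
  if (any(!is.finite(cs_mmol)) || any(cs_mmol < 0)) {
    stop("sensed calcium must be non-negative and finite", call. = FALSE)
  }
  # plogis(-m log(cs/sr)) == 1 / (1 + (cs/sr)^m), robust for m = 50
  z <- -gp$m * log(cs_mmol / gp$s_r)  # log(0) = -Inf gives z = Inf, release = A
  gp$B + (gp$A - gp$B) * stats::plogis(z)
}

#' PTH pool dynamics (stored gland pool and serum pool)
#'
#' `dPTG/dt = k_p S - release(CS) PTG - k_d PTG` and
#' `dPTH/dt = release(CS) PTG - k_cl PTH`: secretory-active cells produce
#' PTH into the gland store, release empties the store into serum in
#' proportion to the sigmoidal release rate, and serum PTH is cleared with a
#' single first-order rate.
#'
#' @param ptg stored PTH (model amount units).
#' @param pth serum PTH (model concentration units).
#' @param s secretory-active cell mass (normalized).
#' @param cs_mmol sensed calcium (mmol/L).
#' @param k_p current production rate (from [production_rate()]).
#' @param k_d current degradation rate (from [degradation_rate()]).
#' @param gp gland parameter block.
#' @return named numeric vector `c(ptg = dPTG/dt, pth = dPTH/dt)`.
#' @export
pth_pools_rhs <- function(ptg, pth, s, cs_mmol, k_p, k_d, gp) {
  rel <- release_rate(cs_mmol, gp)
  c(ptg = k_p * s - rel * ptg - k_d * ptg,
    pth = rel * ptg - gp$k_cl * pth)
}

#' Cell-population dynamics with dynamic carrying capacity
#'
#' Two compartments cycle between secretory-active (`S`) and quiescent (`Q`)
#' states; only quiescent cells proliferate (Gompertz-type, against the
#' carrying capacity `K`) or undergo apoptosis:
#' `dS/dt = -k_sq S + k_qs Q`,
#' `dQ/dt = k_sq S - k_qs Q - k_a Q + k_pr Q ln(K / (S + Q))`,
#' `dK/dt = k_k max(0, (S + Q)/(S0 + Q0) - 1)^(2/3)`.
#' The capacity only ever grows (the max(0, .) clamp), making hyperplasia
#' irreversible: once the gland has enlarged, resolving the stimulus stops
#' further growth but does not shrink the gland.
#'
#' @param s,q,k_cap current secretory, quiescent, and capacity states.
#' @param k_pr current proliferation rate (from [proliferation_rate()]).
#' @param gp gland parameter block.
#' @param s0q0 reference healthy gland size `S0 + Q0` (see
#'   [cell_steady_state()]).
#' @return named numeric vector `c(s = dS/dt, q = dQ/dt, k_cap = dK/dt)`.
#' @export
cells_rhs <- function(s, q, k_cap, k_pr, gp, s0q0) {
  excess <- (s + q) / s0q0 - 1
  c(s = -gp$k_sq * s + gp$k_qs * q,
    q = gp$k_sq * s - gp$k_qs * q - gp$k_a * q + k_pr * q * log(k_cap / (s + q)),
    k_cap = gp$k_k * if (excess > 0) excess^(2 / 3) else 0)
}

#' Closed-form cell-population steady state
#'
#' With capacity `K = 1`, the equilibrium gland size is
#' `S + Q = exp(-k_a / k_pr)` (apoptosis balanced against Gompertz growth),
#' split between the compartments by the cycling rates,
#' `S : Q = k_qs : k_sq`, so the active fraction is
#' `k_qs / (k_qs + k_sq)`.
#'
#' @param gp gland parameter block.
#' @param k_pr_basal basal proliferation rate (> 0), normally
#'   `params$pathways$proliferation$A`.
#' @return list with components `s` and `q` (normalized cell masses).
#' @export
#' @examples
#' p <- default_parameters()
#' cell_steady_state(p$gland, p$pathways$proliferation$A)
cell_steady_state <- function(gp, k_pr_basal) {
  stopifnot(k_pr_basal > 0)
  total <- exp(-gp$k_a / k_pr_basal)
  s <- total * gp$k_qs / (gp$k_qs + gp$k_sq)
  list(s = s, q = total - s)
}
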
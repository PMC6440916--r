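#' Names and ordering of the 21-component model state
#'
#' The ordering is frozen for serialization: receptor block (CaSR and VDR
#' expression, the three expression effect states, sensed calcium, sensed
#' 1,25D), then one block of (activity, calcium effect state, phosphate
#' effect state) per signaling pathway in the order degradation, production,
#' proliferation, then the gland block (stored PTH, serum PTH, secretory
#' cells, quiescent cells, carrying capacity).
#'
#' @return character vector of length 21.
#' @export
.state_names <- c("casr", "vdr", "chi_in", "delta_in", "pi_in", "cs", "ds",
                  "chi_d", "chi_in_d", "pi_in_d",
                  "chi_p", "chi_in_p", "pi_in_p",
                  "chi_pr", "chi_in_pr", "pi_in_pr",
                  "ptg", "pth", "s", "q", "k_cap")

state_names <- function() .state_names

# Flatten a ptg_params object into the fixed-order numeric vector consumed by
# the compiled core. Order must match the indices in src/ptg_core.cpp.
flatten_params <- function(params) {
  validate_parameters(params)
  st <- params$stimulus; ex <- params$expression
  pw <- params$pathways; g <- params$gland
  block <- function(b) c(b$p, b$n, b$tau_ca, b$tau_p, b$A, b$B)
  s0q0 <- exp(-g$k_a / pw$proliferation$A)
  c(st$ca$K, st$ca$W1, st$ca$optimum,
    st$p$K, st$p$W1, st$p$optimum,
    st$d$K, st$d$W1, st$d$optimum,
    ex$p_ca, ex$n_ca, ex$p_d, ex$n_d, ex$tau_c, ex$tau_d, ex$tau_p,
    block(pw$degradation), block(pw$production), block(pw$proliferation),
    g$k_sq, g$k_qs, g$k_a, g$k_k, g$A, g$B, g$s_r, g$m, g$k_cl, g$a_s,
    s0q0)
}

#' Full right-hand side of the coupled 21-state system
#'
#' Pure-R composition of the module right-hand sides: receptor expression and
#' sensed concentrations, the three signaling pathways, the PTH pools, and
#' the cell populations. Sensed calcium drives the release function and all
#' calcium effect states; raw phosphate drives all phosphate effect states;
#' sensed 1,25D drives only the VDR expression effect state. The compiled
#' integrator uses an independent C++ transcription of the same equations;
#' the two are cross-checked in the test suite.
#'
#' @param t time in minutes.
#' @param state named numeric state vector in [state_names()] order.
#' @param profile a `ptg_profile`.
#' @param params a `ptg_params`.
#' @return named numeric vector of time derivatives (per minute).
#' @export
full_rhs <- function(t, state, profile, params) {
  inp <- profile_value_fast(profile, t)
  st <- params$stimulus; ex <- params$expression
  pw <- params$pathways; g <- params$gland
  y <- unname(state)

  s_ca <- stim(y[6] - st$ca$optimum, st$ca$K, st$ca$W1)   # sensed calcium
  s_p  <- stim(inp$p - st$p$optimum, st$p$K, st$p$W1)     # raw phosphate
  s_d  <- stim(y[7] - st$d$optimum, st$d$K, st$d$W1)      # sensed 1,25D

  dexp <- expression_rhs(y[1], y[2], y[3], y[4], y[5], ex)
  dsen <- sensed_rhs(y[6], y[7], y[1], y[2], inp$ca, inp$d, g$a_s)

  dpath <- function(i, pp) {
    c(pathway_rhs(y[i], y[i + 1], y[i + 2], pp),
      effect_state_rhs(y[i + 1], s_ca, pp$tau_ca),
      effect_state_rhs(y[i + 2], s_p, pp$tau_p))
  }
  k_d <- degradation_rate(y[8], pw$degradation)
  k_p <- production_rate(y[11], pw$production)
  k_pr <- proliferation_rate(y[14], pw$proliferation)

  cs_mmol <- ca_mgdl_to_mmol(max(y[6], 0))
  dpools <- pth_pools_rhs(y[17], y[18], y[19], cs_mmol, k_p, k_d, g)
  s0q0 <- exp(-g$k_a / pw$proliferation$A)
  dcells <- cells_rhs(y[19], y[20], y[21], k_pr, g, s0q0)

  out <- c(dexp[1], dexp[2],
           effect_state_rhs(y[3], s_ca, ex$tau_c),
           effect_state_rhs(y[4], s_d, ex$tau_d),
           effect_state_rhs(y[5], s_p, ex$tau_p),
           dsen[1], dsen[2],
           dpath(8, pw$degradation),
           dpath(11, pw$production),
           dpath(14, pw$proliferation),
           dpools[1], dpools[2],
           dcells[1], dcells[2], dcells[3])
  names(out) <- .state_names
  out
}

#' Optimal steady state of the full system
#'
#' At optimal constant inputs every stimulus is zero, so all effect states
#' are 0, all receptor expressions and pathway activities are 1, sensed
#' calcium and 1,25D equal the blood optima, the cell populations sit at the
#' closed-form equilibrium of [cell_steady_state()] with capacity 1, and the
#' PTH pools sit at the fixed point of the pool equations. All simulations
#' start here unless an explicit state is supplied.
#'
#' @param params a `ptg_params`.
#' @return named numeric state vector in [state_names()] order.
#' @export
#' @examples
#' y0 <- steady_state(default_parameters())
#' y0["s"] / (y0["s"] + y0["q"])  # active-cell fraction, 0.2
steady_state <- function(params) {
  validate_parameters(params)
  g <- params$gland
  css <- cell_steady_state(g, params$pathways$proliferation$A)
  c_opt <- params$stimulus$ca$optimum
  d_opt <- params$stimulus$d$optimum
  rel <- release_rate(ca_mgdl_to_mmol(c_opt), g)
  k_p <- params$pathways$production$A
  k_d <- params$pathways$degradation$A
  ptg0 <- k_p * css$s / (rel + k_d)
  pth0 <- rel * ptg0 / g$k_cl
  setNames(c(1, 1, 0, 0, 0, c_opt, d_opt,
             1, 0, 0, 1, 0, 0, 1, 0, 0,
             ptg0, pth0, css$s, css$q, 1),
           state_names())
}

#' Integrate the model under a prescribed input profile
#'
#' Integrates the coupled system with an adaptive embedded Dormand-Prince
#' 5(4) method (compiled), restarting exactly at every profile breakpoint and
#' at every requested output time so that input kinks are never stepped over.
#' The run is fully deterministic.
#'
#' @param params a `ptg_params`.
#' @param profile a `ptg_profile`.
#' @param t_span length-2 numeric, start and end time in minutes; defaults to
#'   `c(0, duration)` of the profile.
#' @param output_grid strictly increasing output times within `t_span`;
#'   defaults to 1001 equally spaced points.
#' @param init_state optional initial state (named as [state_names()]);
#'   defaults to [steady_state()].
#' @param rtol,atol relative and absolute integration tolerances.
#' @param max_steps step budget per integration segment before the run is
#'   aborted with the failing time and state.
#' @return a `ptg_trajectory`: a data.frame with one row per output time and
#'   columns `time_min`, the inputs (`ca_mgdl`, `p_mgdl`, `d_units`), the 21
#'   states, and the derived rates `k_d`, `k_p`, `k_pr`, `release`. The `pth`
#'   column is scaled by `gland.pth_scale`. Run metadata (parameters,
#'   tolerances) is attached as attribute `meta`.
#' @export
#' @examples
#' traj <- simulate_ptg(default_parameters(),
#'                      acute_hypocalcemia_profile(0.05, 30, 90),
#'                      t_span = c(0, 240),
#'                      output_grid = seq(0, 240, by = 1))
#' max(traj$pth)
simulate_ptg <- function(params, profile, t_span = NULL, output_grid = NULL,
                         init_state = NULL, rtol = 1e-8, atol = 1e-10,
                         max_steps = 5e7) {
  stopifnot(inherits(profile, "ptg_profile"))
  if (is.null(t_span)) t_span <- c(0, profile_duration(profile))
  stopifnot(length(t_span) == 2L, t_span[2] > t_span[1])
  if (is.null(output_grid)) {
    output_grid <- seq(t_span[1], t_span[2], length.out = 1001)
  }
  output_grid <- as.numeric(output_grid)
  if (any(diff(output_grid) <= 0)) {
    stop("output_grid must be strictly increasing", call. = FALSE)
  }
  if (output_grid[1] < t_span[1] || output_grid[length(output_grid)] > t_span[2]) {
    stop("output_grid must lie within t_span", call. = FALSE)
  }
  y0 <- if (is.null(init_state)) steady_state(params) else {
    stopifnot(length(init_state) == 21L)
    as.numeric(init_state[state_names()])
  }
  par <- flatten_params(params)
  knots <- profile$times[profile$times > t_span[1] & profile$times < t_span[2]]
  ymat <- ptg_integrate_cpp(as.numeric(y0), par,
                            profile$times, profile$ca, profile$p, profile$d,
                            t_span[1], as.numeric(knots), output_grid,
                            rtol, atol, as.double(max_steps))
  colnames(ymat) <- state_names()
  assemble_trajectory(output_grid, ymat, profile, params,
                      list(rtol = rtol, atol = atol))
}

assemble_trajectory <- function(times, ymat, profile, params, solver) {
  inp <- profile_value(profile, times)
  pw <- params$pathways; g <- params$gland
  out <- data.frame(time_min = times,
                    ca_mgdl = inp$ca, p_mgdl = inp$p, d_units = inp$d)
  out <- cbind(out, as.data.frame(ymat))
  out$pth <- out$pth * g$pth_scale
  out$k_d <- degradation_rate(ymat[, "chi_d"], pw$degradation)
  out$k_p <- production_rate(ymat[, "chi_p"], pw$production)
  out$k_pr <- proliferation_rate(ymat[, "chi_pr"], pw$proliferation)
  out$release <- release_rate(ca_mgdl_to_mmol(pmax(ymat[, "cs"], 0)), g)
  attr(out, "meta") <- list(parameters = unclass(params), solver = solver)
  # scenario builders may annotate phase windows; keep them with the result
  attr(out, "phases") <- attr(profile, "phases")
  class(out) <- c("ptg_trajectory", "data.frame")
  out
}

#' Fixed-step classical Runge-Kutta (RK4) integration
#'
#' Reference integrator used as an independent numerical oracle for the
#' adaptive compiled solver: fourth-order fixed-step stepping of the pure-R
#' [full_rhs()] composition. Slow, intended for short validation runs only.
#'
#' @param params,profile,init_state as in [simulate_ptg()].
#' @param t0,t1 integration window in minutes; `(t1 - t0)/dt` must be an
#'   integer number of steps.
#' @param dt fixed step size in minutes.
#' @param record_every store the state every this many steps (the initial
#'   state is always stored).
#' @return data.frame with column `time_min` and the 21 state columns.
#' @export
integrate_rk4 <- function(params, profile, t0, t1, dt, init_state = NULL,
                          record_every = 1L) {
  y <- if (is.null(init_state)) unname(steady_state(params)) else
    as.numeric(init_state[state_names()])
  n <- round((t1 - t0) / dt)
  stopifnot(abs(n * dt - (t1 - t0)) < 1e-9 * max(1, abs(t1 - t0)))
  f <- function(t, y) unname(full_rhs(t, y, profile, params))
  keep <- seq(0L, n, by = record_every)
  out <- matrix(NA_real_, nrow = length(keep), ncol = 22L)
  out[1L, ] <- c(t0, y)
  row <- 1L
  t <- t0
  for (i in seq_len(n)) {
    k1 <- f(t, y)
    k2 <- f(t + dt / 2, y + dt / 2 * k1)
    k3 <- f(t + dt / 2, y + dt / 2 * k2)
    k4 <- f(t + dt, y + dt * k3)
    y <- y + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    t <- t0 + i * dt
    if (i %% record_every == 0L) {
      row <- row + 1L
      out[row, ] <- c(t, y)
    }
  }
  colnames(out) <- c("time_min", state_names())
  as.data.frame(out)
}
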
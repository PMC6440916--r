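#' Acute hypocalcemia protocol
#'
#' Linear calcium ramp down from the optimum by a given fraction over
#' `ramp_minutes`, then a hypocalcemic clamp; phosphate and 1,25D stay
#' optimal. The classic validation pair is a fast ramp (5% in 30 min, 90-min
#' clamp), which produces a prominent PTH overshoot from the stored pool, and
#' a slow ramp (5% in 120 min) with only a small overshoot.
#'
#' @param drop_fraction fractional calcium reduction, in (0, 1).
#' @param ramp_minutes duration of the linear ramp (> 0).
#' @param clamp_minutes duration of the clamp after the ramp (>= 0); the
#'   profile extends at the clamped level beyond it.
#' @param params a `ptg_params` supplying the optimal input levels.
#' @return a `ptg_profile` of duration `ramp_minutes + clamp_minutes`.
#' @export
#' @examples
#' acute_hypocalcemia_profile(0.05, 30, 90)    # fast protocol
#' acute_hypocalcemia_profile(0.05, 120, 0)    # slow protocol
acute_hypocalcemia_profile <- function(drop_fraction, ramp_minutes,
                                       clamp_minutes,
                                       params = default_parameters()) {
  stopifnot(drop_fraction > 0, drop_fraction < 1, ramp_minutes > 0,
            clamp_minutes >= 0)
  c_opt <- params$stimulus$ca$optimum
  input_profile(c(0, ramp_minutes),
                ca = c(c_opt, (1 - drop_fraction) * c_opt),
                p = params$stimulus$p$optimum,
                d = params$stimulus$d$optimum,
                duration = ramp_minutes + clamp_minutes)
}

#' Hysteresis protocol: hypocalcemia, brief normocalcemia, hypocalcemia
#'
#' Three-phase calcium profile emulating the induced-hypocalcemia hysteresis
#' experiments: a drop below baseline held for `t_hypo1` minutes, a return to
#' the optimum held for `t_normo` minutes, and a second identical drop held
#' for `t_hypo2` minutes, with linear transitions of `ramp_minutes` each.
#' Because the brief normocalcemic interval is too short to refill the gland
#' PTH store, the second hypocalcemia produces no secretion peak.
#'
#' @param drop absolute calcium drop from the optimum, mg/dL (0 gives a flat
#'   profile).
#' @param t_hypo1,t_normo,t_hypo2 phase plateau durations in minutes.
#' @param ramp_minutes duration of each linear transition.
#' @param params a `ptg_params`.
#' @return a `ptg_profile`; phase windows are attached as attribute `phases`
#'   (list of `c(start, end)` for the two hypocalcemic plateaus).
#' @export
hysteresis_profile <- function(drop = 0.8, t_hypo1 = 120, t_normo = 60,
                               t_hypo2 = 120, ramp_minutes = 10,
                               params = default_parameters()) {
  stopifnot(drop >= 0, t_hypo1 > 0, t_normo > 0, t_hypo2 > 0,
            ramp_minutes > 0)
  c_opt <- params$stimulus$ca$optimum
  lo <- c_opt - drop
  stopifnot(lo >= 0)
  r <- ramp_minutes
  times <- cumsum(c(0, r, t_hypo1, r, t_normo, r, t_hypo2))
  ca <- c(c_opt, lo, lo, c_opt, c_opt, lo, lo)
  prof <- input_profile(times, ca = ca,
                        p = params$stimulus$p$optimum,
                        d = params$stimulus$d$optimum,
                        duration = times[7])
  attr(prof, "phases") <- list(hypo1 = c(times[1], times[3]),
                               normo = c(times[3], times[5]),
                               hypo2 = c(times[5], times[7]))
  prof
}

#' Chronic mild hypocalcemia protocol
#'
#' Calcium is lowered by `delta` mg/dL over a short ramp and clamped low for
#' `days` days; phosphate and 1,25D stay optimal. With the default
#' (0.25 mg/dL for 200 days) all four adaptation layers engage in sequence
#' and serum PTH keeps rising slowly without reaching a steady state.
#'
#' @param delta absolute calcium reduction, mg/dL (0 gives a flat profile).
#' @param days clamp duration in days.
#' @param ramp_minutes duration of the initial ramp.
#' @param params a `ptg_params`.
#' @return a `ptg_profile` of duration `days * 1440` minutes.
#' @export
chronic_hypocalcemia_profile <- function(delta = 0.25, days = 200,
                                         ramp_minutes = 1,
                                         params = default_parameters()) {
  stopifnot(delta >= 0, days > 0, ramp_minutes > 0)
  c_opt <- params$stimulus$ca$optimum
  stopifnot(c_opt - delta >= 0)
  input_profile(c(0, ramp_minutes),
                ca = c(c_opt, c_opt - delta),
                p = params$stimulus$p$optimum,
                d = params$stimulus$d$optimum,
                duration = days * 1440)
}

#' Chronic kidney disease protocol: rising phosphate, falling 1,25D
#'
#' Calcium is held at its optimum while phosphate rises and 1,25D falls, the
#' canonical drivers of secondary hyperparathyroidism when renal phosphate
#' clearance and 1,25D synthesis fail. Trajectories may be given either as
#' `c(start, end)` pairs (linear ramp over the whole horizon) or as data
#' frames with columns `time` (minutes) and `value`; both inputs must cover
#' the same horizon.
#'
#' @param p_trajectory phosphate course, mg/dL (default ramp 4.5 to 9).
#' @param d_trajectory 1,25D course, D units (default ramp 45 to 15).
#' @param days horizon in days.
#' @param params a `ptg_params`.
#' @return a `ptg_profile` of duration `days * 1440` minutes.
#' @export
#' @examples
#' high <- ckd_profile(c(4.5, 9), c(45, 15), days = 200)
#' moderate <- ckd_profile(c(4.5, 6), c(45, 15), days = 200)
ckd_profile <- function(p_trajectory = c(4.5, 9), d_trajectory = c(45, 15),
                        days = 200, params = default_parameters()) {
  stopifnot(days > 0)
  horizon <- days * 1440
  as_course <- function(x, what) {
    if (is.data.frame(x)) {
      stopifnot(all(c("time", "value") %in% names(x)))
      if (abs(max(x$time) - horizon) > 1e-9 * horizon) {
        stop("'", what, "' horizon does not match 'days'", call. = FALSE)
      }
      x[order(x$time), c("time", "value")]
    } else {
      stopifnot(is.numeric(x), length(x) == 2L)
      data.frame(time = c(0, horizon), value = x)
    }
  }
  pc <- as_course(p_trajectory, "p_trajectory")
  dc <- as_course(d_trajectory, "d_trajectory")
  times <- sort(unique(c(pc$time, dc$time)))
  ev <- function(course) {
    if (nrow(course) == 1L) rep(course$value, length(times))
    else stats::approx(course$time, course$value, xout = times, rule = 2)$y
  }
  input_profile(times, ca = params$stimulus$ca$optimum,
                p = ev(pc), d = ev(dc), duration = horizon)
}

#' Mild combined hypocalcemia and hyperphosphatemia
#'
#' Scenario default used for the proliferation-timescale robustness check:
#' calcium lowered by `ca_delta` mg/dL and phosphate raised by `p_delta`
#' mg/dL (short ramps, then clamped), 1,25D optimal.
#'
#' @param ca_delta,p_delta absolute input shifts, mg/dL.
#' @param days horizon in days.
#' @param ramp_minutes ramp duration.
#' @param params a `ptg_params`.
#' @return a `ptg_profile`.
#' @export
mild_hypo_hyperphos_profile <- function(ca_delta = 0.25, p_delta = 0.5,
                                        days = 30, ramp_minutes = 1,
                                        params = default_parameters()) {
  stopifnot(ca_delta >= 0, p_delta >= 0, days > 0)
  input_profile(c(0, ramp_minutes),
                ca = c(params$stimulus$ca$optimum,
                       params$stimulus$ca$optimum - ca_delta),
                p = c(params$stimulus$p$optimum,
                      params$stimulus$p$optimum + p_delta),
                d = params$stimulus$d$optimum,
                duration = days * 1440)
}

#' Interior-peak detector
#'
#' A peak is a strict interior local maximum exceeding the pre-perturbation
#' baseline by a configurable fractional threshold. A monotone rise to a
#' clamp level has no interior maximum and therefore no peak.
#'
#' @param time,value trajectory columns (equal length, time increasing).
#' @param baseline reference level (e.g. the value at time 0).
#' @param threshold fractional exceedance over baseline required (default 5%).
#' @return list with `detected` (logical), `peak_value`, `peak_time` (`NA` if
#'   no peak).
#' @export
detect_peak <- function(time, value, baseline, threshold = 0.05) {
  stopifnot(length(time) == length(value), length(value) >= 3L)
  n <- length(value)
  interior <- which(value[2:(n - 1)] > value[1:(n - 2)] &
                    value[2:(n - 1)] > value[3:n]) + 1L
  interior <- interior[value[interior] > baseline * (1 + threshold)]
  if (length(interior) == 0L) {
    return(list(detected = FALSE, peak_value = NA_real_, peak_time = NA_real_))
  }
  best <- interior[which.max(value[interior])]
  list(detected = TRUE, peak_value = value[best], peak_time = time[best])
}

#' Evaluate the qualitative scenario checks
#'
#' Runs the four qualitative comparisons that mirror the published validation
#' scenarios on precomputed trajectories:
#' (a) the fast acute ramp gives a strictly larger PTH peak than the slow
#' ramp; (b) the hysteresis run shows a peak during the first hypocalcemia
#' and none during the second; (c) chronic hypocalcemia leaves PTH still
#' rising at the end of the horizon; (d) the high-phosphate CKD arm keeps
#' PTH at or above the moderate arm throughout. Every check is always
#' evaluated; identical inputs yield an `equal` relation rather than an
#' error.
#'
#' @param trajectory_fast,trajectory_slow acute-protocol trajectories
#'   (`ptg_trajectory`).
#' @param trajectory_hysteresis hysteresis-protocol trajectory; phase windows
#'   are read from its profile attribute if present, otherwise from
#'   `hysteresis_phases`.
#' @param trajectory_chronic chronic-hypocalcemia trajectory.
#' @param trajectory_ckd_high,trajectory_ckd_moderate the two CKD arms, on a
#'   common output grid.
#' @param hysteresis_phases optional list with elements `hypo1` and `hypo2`,
#'   each `c(start, end)` in minutes.
#' @param threshold peak-detection threshold (fraction over baseline).
#' @param slope_window_min window (minutes) at the end of the chronic run
#'   over which the terminal PTH slope is measured.
#' @return a `ptg_report`: list with a `checks` data.frame (name, passed,
#'   relation, measured quantities), `peaks`, and `terminal` values.
#' @export
evaluate_checks <- function(trajectory_fast, trajectory_slow,
                            trajectory_hysteresis, trajectory_chronic,
                            trajectory_ckd_high, trajectory_ckd_moderate,
                            hysteresis_phases = NULL, threshold = 0.05,
                            slope_window_min = 7200) {
  rel_of <- function(a, b) if (a > b) "greater" else if (a < b) "less" else "equal"

  # (a) fast vs slow acute peak
  pf <- max(trajectory_fast$pth)
  ps <- max(trajectory_slow$pth)
  chk_a <- list(name = "acute_fast_peak_gt_slow", passed = pf > ps,
                relation = rel_of(pf, ps), measured = pf / ps)

  # (b) hysteresis: first peak present, second absent
  if (is.null(hysteresis_phases)) {
    hysteresis_phases <- attr(trajectory_hysteresis, "phases")
  }
  if (is.null(hysteresis_phases)) {
    stop("hysteresis phase windows are required", call. = FALSE)
  }
  hy <- trajectory_hysteresis
  base <- hy$pth[1]
  in_win <- function(w) hy$time_min >= w[1] & hy$time_min <= w[2]
  p1 <- detect_peak(hy$time_min[in_win(hysteresis_phases$hypo1)],
                    hy$pth[in_win(hysteresis_phases$hypo1)], base, threshold)
  p2 <- detect_peak(hy$time_min[in_win(hysteresis_phases$hypo2)],
                    hy$pth[in_win(hysteresis_phases$hypo2)], base, threshold)
  max2 <- max(hy$pth[in_win(hysteresis_phases$hypo2)])
  chk_b <- list(name = "hysteresis_first_peak_only",
                passed = p1$detected && !p2$detected &&
                  (!is.na(p1$peak_value) && max2 < p1$peak_value),
                relation = if (p1$detected && !p2$detected) "greater" else
                  rel_of(p1$detected, p2$detected),
                measured = if (p1$detected) max2 / p1$peak_value else NA_real_)

  # (c) chronic run: PTH still rising at the end
  tc <- trajectory_chronic
  t_end <- max(tc$time_min)
  tail_idx <- tc$time_min >= t_end - slope_window_min
  slope <- stats::coef(stats::lm(pth ~ time_min, data = tc[tail_idx, ]))[2]
  chk_c <- list(name = "chronic_pth_still_rising", passed = slope > 0,
                relation = rel_of(slope, 0), measured = unname(slope))

  # (d) high-phosphate arm dominates the moderate arm throughout
  hi <- trajectory_ckd_high; mo <- trajectory_ckd_moderate
  if (nrow(hi) != nrow(mo) || max(abs(hi$time_min - mo$time_min)) > 1e-9) {
    stop("CKD arms must share an output grid", call. = FALSE)
  }
  dom <- all(hi$pth >= mo$pth * (1 - 1e-9))
  chk_d <- list(name = "ckd_high_p_dominates", passed = dom,
                relation = if (all(hi$pth == mo$pth)) "equal" else
                  if (dom) "greater" else "less",
                measured = max(hi$pth / mo$pth))

  checks <- do.call(rbind, lapply(list(chk_a, chk_b, chk_c, chk_d),
                                  as.data.frame))
  structure(list(
    checks = checks,
    peaks = list(acute_fast = pf, acute_slow = ps,
                 hysteresis_first = p1, hysteresis_second = p2),
    terminal = c(chronic_pth = tc$pth[nrow(tc)],
                 ckd_high_pth = hi$pth[nrow(hi)],
                 ckd_moderate_pth = mo$pth[nrow(mo)])
  ), class = "ptg_report")
}

#' @export
print.ptg_report <- function(x, ...) {
  cat("<ptg_report>\n")
  df <- x$checks
  for (i in seq_len(nrow(df))) {
    cat(sprintf("  [%s] %-28s relation=%s measured=%.6g\n",
                if (df$passed[i]) "ok" else "FAIL", df$name[i],
                df$relation[i], df$measured[i]))
  }
  invisible(x)
}

#' One-at-a-time parameter sensitivity sweep
#'
#' Reruns a scenario once per (parameter, factor) combination with that
#' single parameter multiplied by the factor, and reports the maximum
#' relative deviation of serum PTH from the unperturbed reference run over
#' the output grid. The reference run is computed once.
#'
#' @param params a `ptg_params`.
#' @param targets character vector of dotted parameter keys (see
#'   [update_parameters()]).
#' @param factors positive multipliers (default halve and double).
#' @param profile scenario input profile.
#' @param t_end horizon in minutes (default: profile duration).
#' @param output_grid evaluation grid (default 1001 points).
#' @param ... further arguments passed to [simulate_ptg()].
#' @return data.frame with columns `parameter`, `factor`, `max_rel_dev`,
#'   sorted by decreasing deviation.
#' @export
#' @examples
#' \donttest{
#' sweep <- sensitivity_sweep(default_parameters(),
#'                            c("pathways.production.p", "expression.p_ca"),
#'                            factors = c(0.5, 2),
#'                            profile = ckd_profile(days = 7), t_end = 7 * 1440)
#' }
sensitivity_sweep <- function(params, targets, factors = c(0.5, 2),
                              profile, t_end = NULL, output_grid = NULL, ...) {
  stopifnot(all(factors > 0), all(targets %in% param_keys()))
  if (is.null(t_end)) t_end <- profile_duration(profile)
  if (is.null(output_grid)) output_grid <- seq(0, t_end, length.out = 1001)
  ref <- simulate_ptg(params, profile, t_span = c(0, t_end),
                      output_grid = output_grid, ...)
  grid <- expand.grid(parameter = targets, factor = factors,
                      stringsAsFactors = FALSE)
  grid$max_rel_dev <- vapply(seq_len(nrow(grid)), function(i) {
    key <- grid$parameter[i]
    fac <- grid$factor[i]
    pert <- apply_overrides(params,
                            setNames(list(get_by_key(params, key) * fac), key))
    traj <- simulate_ptg(pert, profile, t_span = c(0, t_end),
                         output_grid = output_grid, ...)
    max(abs(traj$pth - ref$pth) / ref$pth)
  }, numeric(1))
  grid[order(-grid$max_rel_dev), ]
}
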
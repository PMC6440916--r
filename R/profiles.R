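#' Piecewise-linear input profile
#'
#' Prescribed time courses of the three model inputs: arterial ionized
#' calcium `C(t)` (mg/dL), serum phosphate `P(t)` (mg/dL), and plasma 1,25D
#' `D(t)` (D units). Values are interpolated linearly between breakpoints and
#' held constant before the first and after the last breakpoint, so ramps are
#' exact piecewise-linear segments and clamps are flat extensions. The
#' integrator restarts at every breakpoint, so kinks are never smoothed.
#'
#' @param times strictly increasing breakpoint times in minutes.
#' @param ca,p,d input values at the breakpoints (scalars are recycled);
#'   all non-negative.
#' @param duration nominal scenario duration in minutes (defaults to the last
#'   breakpoint); stored as an attribute used by scenario runners.
#' @return an object of class `ptg_profile`.
#' @export
#' @examples
#' # 30-min linear calcium ramp down 5%, then clamped
#' input_profile(c(0, 30), ca = c(5, 4.75), p = 4.5, d = 45)
input_profile <- function(times, ca, p, d, duration = max(times)) {
  n <- length(times)
  stopifnot(n >= 1L, all(is.finite(times)))
  if (n > 1L && any(diff(times) <= 0)) {
    stop("breakpoint times must be strictly increasing", call. = FALSE)
  }
  rec <- function(x, what) {
    if (length(x) == 1L) x <- rep(x, n)
    if (length(x) != n) stop("'", what, "' must have length 1 or length(times)",
                             call. = FALSE)
    if (any(!is.finite(x)) || any(x < 0)) {
      stop("'", what, "' values must be non-negative and finite", call. = FALSE)
    }
    x
  }
  structure(list(times = as.numeric(times), ca = rec(ca, "ca"),
                 p = rec(p, "p"), d = rec(d, "d")),
            duration = as.numeric(duration), class = "ptg_profile")
}

#' Constant input profile
#'
#' @param ca,p,d constant input levels; defaults are the optimal values of
#'   [default_parameters()].
#' @param duration nominal duration in minutes.
#' @return a `ptg_profile` with a single breakpoint at time 0.
#' @export
constant_profile <- function(ca = 5, p = 4.5, d = 45, duration = 1440) {
  input_profile(0, ca = ca, p = p, d = d, duration = duration)
}

#' Evaluate an input profile
#'
#' @param profile a `ptg_profile`.
#' @param t time(s) in minutes.
#' @return data.frame with columns `time`, `ca`, `p`, `d`.
#' @export
profile_value <- function(profile, t) {
  stopifnot(inherits(profile, "ptg_profile"))
  ev <- function(v) {
    if (length(profile$times) == 1L) return(rep(v, length(t)))
    stats::approx(profile$times, v, xout = t, rule = 2)$y
  }
  data.frame(time = t, ca = ev(profile$ca), p = ev(profile$p),
             d = ev(profile$d))
}

#' @export
print.ptg_profile <- function(x, ...) {
  cat(sprintf("<ptg_profile> %d breakpoint(s), duration %g min\n",
              length(x$times), attr(x, "duration")))
  cat(sprintf("  Ca [%g, %g] mg/dL; P [%g, %g] mg/dL; D [%g, %g] units\n",
              min(x$ca), max(x$ca), min(x$p), max(x$p), min(x$d), max(x$d)))
  invisible(x)
}

# scalar-time evaluator without data.frame overhead, for RHS hot paths
profile_value_fast <- function(profile, t) {
  tk <- profile$times
  n <- length(tk)
  if (n == 1L || t <= tk[1]) {
    return(list(ca = profile$ca[1], p = profile$p[1], d = profile$d[1]))
  }
  if (t >= tk[n]) {
    return(list(ca = profile$ca[n], p = profile$p[n], d = profile$d[n]))
  }
  hi <- findInterval(t, tk, rightmost.closed = FALSE) + 1L
  w <- (t - tk[hi - 1L]) / (tk[hi] - tk[hi - 1L])
  list(ca = profile$ca[hi - 1L] + w * (profile$ca[hi] - profile$ca[hi - 1L]),
       p = profile$p[hi - 1L] + w * (profile$p[hi] - profile$p[hi - 1L]),
       d = profile$d[hi - 1L] + w * (profile$d[hi] - profile$d[hi - 1L]))
}

#' Nominal duration of an input profile
#'
#' @param profile a `ptg_profile`.
#' @return duration in minutes (scalar).
#' @export
profile_duration <- function(profile) attr(profile, "duration")
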
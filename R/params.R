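#' Default model parameters
#'
#' Returns the complete parameter set of the model: stimulus-function
#' constants and optimal concentrations for calcium, phosphate, and 1,25D;
#' receptor-expression intensities and relaxation scalars; one parameter
#' block per CaSR signaling pathway (degradation, production, proliferation);
#' and the gland block (cell cycling, apoptosis, carrying-capacity rate,
#' sigmoidal release, clearance, sensitivity floor).
#'
#' The published parameter table is internally inconsistent with its own
#' printed cell-population steady state (S0 + Q0 = 0.9672 forces the
#' apoptosis-to-basal-proliferation ratio to 1/30). The defaults adopt a
#' reconciled reading: apoptosis `k_a = 1e-3`/min (literal), basal
#' proliferation `A = 0.03`/min (derived from the 1/30 ratio), and basal PTH
#' production `A = 132` model amount units per unit secretory mass per
#' minute. Every deviation from a literal table entry is recorded in
#' `reconciliation_notes`. Extreme pathway rates are derived, not free:
#' `B = 0.5 * A` for degradation and `B = 2 * A` for production and
#' proliferation.
#'
#' Serum PTH is reported in model units; `gland.pth_scale` (default 1) is an
#' optional linear calibration applied to the serum PTH trajectory column.
#' The sensitivity floor `gland.a_s` (default 0.5) is the value of the
#' receptor sensitivity map when expression is fully lost.
#'
#' @return An object of class `ptg_params`: a named list with components
#'   `stimulus` (`ca`, `p`, `d`, each with `K`, `W1`, `optimum`),
#'   `expression`, `pathways` (`degradation`, `production`,
#'   `proliferation`), `gland`, and `reconciliation_notes`.
#' @seealso [load_parameters()], [update_parameters()], [write_parameters()]
#' @export
#' @examples
#' p <- default_parameters()
#' p$gland$A      # maximal release rate, pmol/min
#' p$gland$s_r    # release set-point, mmol/L
default_parameters <- function() {
  notes <- c(
    "k_a = 1e-3/min taken literally; basal proliferation rate set to A_pr = 0.03/min so that k_a/k_pr = 1/30 reproduces the printed steady state S0 + Q0 = exp(-1/30) = 0.9672 (the literal table rows kp0 = 3e-3/min and proliferation A = 0.003/min contradict that steady state).",
    "The table row 'Apr 132' is read as the basal PTH production rate A_p = 132 model amount units per unit secretory cell mass per minute (label swap with the proliferation row).",
    "Stored-gland PTH PTG0 = 565 and steady serum PTH = 3.15 pmol/L as printed are not derivable from the pool equations with the tabulated rates; serum PTH is reported in model units with an optional linear calibration gland.pth_scale (default 1).",
    "The sensitivity-map floor A_S is never tabulated; default a_s = 0.5, configurable.",
    "1,25D is carried in a single abstract 'D unit' matching the tabulated scale (optimum 45, stimulus half-width 45); the source mixes pg/mL, ng/mL, and ng/dL.",
    "All relaxation scalars and intensities tabulated as 'unitless' are interpreted as per-minute multipliers; time is minutes throughout."
  )
  p <- list(
    stimulus = list(
      ca = list(K = 2,   W1 = 2,   optimum = 5),    # mg/dL
      p  = list(K = 2.5, W1 = 2.5, optimum = 4.5),  # mg/dL
      d  = list(K = 0.2, W1 = 45,  optimum = 45)    # D units
    ),
    expression = list(
      p_ca = 5e-3, n_ca = 5e-3, p_d = 5e-7, n_d = 5e-7,
      tau_c = 1e-4, tau_d = 1e-4, tau_p = 1e-1
    ),
    pathways = list(
      degradation   = list(p = 25, n = 0.5, tau_ca = 1e-1, tau_p = 5e-2,
                           A = 0.012, B = NA_real_),
      production    = list(p = 25, n = 0.5, tau_ca = 1e-3, tau_p = 1e-4,
                           A = 132, B = NA_real_),
      proliferation = list(p = 25, n = 0.5, tau_ca = 5e-5, tau_p = 5e-4,
                           A = 0.03, B = NA_real_)
    ),
    gland = list(
      k_sq = 2e-3, k_qs = 5e-4, k_a = 1e-3, k_k = 5e-5,
      A = 0.12, B = 0.001, s_r = 1.1881, m = 50, k_cl = 0.632,
      a_s = 0.5, pth_scale = 1
    ),
    reconciliation_notes = notes
  )
  class(p) <- "ptg_params"
  p <- derive_pathway_extremes(p)
  validate_parameters(p)
  p
}

# Extreme pathway rates are tied to the basal rates by the model definition:
# degradation falls to half basal, production and proliferation double.
derive_pathway_extremes <- function(params) {
  params$pathways$degradation$B <- 0.5 * params$pathways$degradation$A
  params$pathways$production$B <- 2 * params$pathways$production$A
  params$pathways$proliferation$B <- 2 * params$pathways$proliferation$A
  params
}

#' Validate a parameter set
#'
#' Checks every structural invariant of a `ptg_params` object: positivity of
#' all rates, steepnesses, half-widths, and optima; the release ordering
#' `A > B > 0`; the sensitivity floor in (0, 1]; and the derived pathway
#' extremes (`B = A/2` for degradation, `B = 2A` for production and
#' proliferation).
#'
#' @param params a `ptg_params` object.
#' @return `params`, invisibly; errors on the first violated invariant.
#' @export
validate_parameters <- function(params) {
  stopifnot(inherits(params, "ptg_params"))
  pos <- function(x, what) {
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
      stop("parameter '", what, "' must be a single positive finite number, got ",
           deparse(x), call. = FALSE)
    }
  }
  for (sp in names(params$stimulus)) {
    s <- params$stimulus[[sp]]
    pos(s$K, paste0("stimulus.", sp, ".K"))
    pos(s$W1, paste0("stimulus.", sp, ".W1"))
    pos(s$optimum, paste0("stimulus.", sp, ".optimum"))
  }
  for (nm in names(params$expression)) {
    pos(params$expression[[nm]], paste0("expression.", nm))
  }
  for (pw in names(params$pathways)) {
    b <- params$pathways[[pw]]
    for (nm in c("p", "n", "tau_ca", "tau_p", "A", "B")) {
      pos(b[[nm]], paste0("pathways.", pw, ".", nm))
    }
    want <- if (pw == "degradation") 0.5 * b$A else 2 * b$A
    if (abs(b$B - want) > 1e-12 * b$A) {
      stop("pathways.", pw, ".B must equal ",
           if (pw == "degradation") "0.5" else "2", " * A", call. = FALSE)
    }
  }
  g <- params$gland
  for (nm in c("k_sq", "k_qs", "k_a", "k_k", "A", "B", "s_r", "m", "k_cl",
               "a_s", "pth_scale")) {
    pos(g[[nm]], paste0("gland.", nm))
  }
  if (!(g$A > g$B)) stop("gland.A must exceed gland.B", call. = FALSE)
  if (g$a_s > 1) stop("gland.a_s must lie in (0, 1]", call. = FALSE)
  if (length(params$reconciliation_notes) < 1L) {
    stop("reconciliation_notes must document the adopted table corrections",
         call. = FALSE)
  }
  invisible(params)
}

# Dotted keys a configuration file may set. Pathway extremes B are derived.
param_keys <- function() {
  c(as.vector(outer(c("stimulus.ca.", "stimulus.p.", "stimulus.d."),
                    c("K", "W1", "optimum"), paste0)),
    paste0("expression.",
           c("p_ca", "n_ca", "p_d", "n_d", "tau_c", "tau_d", "tau_p")),
    as.vector(outer(paste0("pathways.",
                           c("degradation", "production", "proliferation"), "."),
                    c("p", "n", "tau_ca", "tau_p", "A"), paste0)),
    paste0("gland.", c("k_sq", "k_qs", "k_a", "k_k", "A", "B", "s_r", "m",
                       "k_cl", "a_s", "pth_scale")))
}

flatten_config <- function(x, prefix = character()) {
  if (is.list(x)) {
    out <- list()
    for (nm in names(x)) {
      out <- c(out, flatten_config(x[[nm]], c(prefix, nm)))
    }
    return(out)
  }
  key <- paste(prefix, collapse = ".")
  setNames(list(x), key)
}

set_by_key <- function(params, key, value) {
  path <- strsplit(key, ".", fixed = TRUE)[[1]]
  params[[path]] <- value
  params
}

get_by_key <- function(params, key) {
  params[[strsplit(key, ".", fixed = TRUE)[[1]]]]
}

#' Override parameters by dotted key
#'
#' @param params a `ptg_params` object.
#' @param ... named scalar overrides; names are dotted keys such as
#'   `gland.k_cl` or `pathways.production.p`. Unknown keys are an error.
#'   Pathway extreme rates `B` are re-derived from the basal rates after the
#'   overrides are applied.
#' @return the modified, re-validated `ptg_params`.
#' @export
#' @examples
#' p <- update_parameters(default_parameters(), gland.k_cl = 0.316)
update_parameters <- function(params, ...) {
  overrides <- list(...)
  apply_overrides(params, overrides)
}

apply_overrides <- function(params, overrides) {
  if (length(overrides) == 0L) return(params)
  known <- param_keys()
  for (key in names(overrides)) {
    if (!key %in% known) {
      stop("unknown parameter key '", key, "'", call. = FALSE)
    }
    val <- overrides[[key]]
    if (!is.numeric(val) || length(val) != 1L) {
      stop("value for '", key, "' must be a single number", call. = FALSE)
    }
    params <- set_by_key(params, key, as.numeric(val))
  }
  params <- derive_pathway_extremes(params)
  validate_parameters(params)
  params
}

#' Load parameters from a configuration file or list
#'
#' Reads a YAML configuration whose keys form a subset of the documented
#' parameter keys (dotted, e.g. `gland.k_cl: 0.316`, or equivalently nested
#' maps) and returns [default_parameters()] with those overrides applied.
#' Unknown keys and invariant-violating values are errors, not warnings.
#'
#' @param config path to a YAML file, or a named list of overrides. An empty
#'   config returns the defaults unchanged.
#' @return a `ptg_params` object.
#' @export
load_parameters <- function(config = list()) {
  if (is.character(config)) {
    config <- yaml::read_yaml(config)
    if (is.null(config)) config <- list()
  }
  stopifnot(is.list(config))
  overrides <- flatten_config(config)
  apply_overrides(default_parameters(), overrides)
}

#' Write parameters to a YAML configuration file
#'
#' Writes every configurable key (see [load_parameters()]); reloading the
#' file reproduces the parameter set exactly. Derived pathway extremes and
#' reconciliation notes are not written (they are reconstructed on load).
#'
#' @param params a `ptg_params` object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_parameters <- function(params, path) {
  validate_parameters(params)
  vals <- lapply(param_keys(), function(k) get_by_key(params, k))
  flat <- setNames(vals, param_keys())
  yaml::write_yaml(flat, path, precision = 15L)
  invisible(path)
}

#' Export parameters (including provenance notes) as JSON
#'
#' @param params a `ptg_params` object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_parameters_json <- function(params, path) {
  jsonlite::write_json(unclass(params), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Convert calcium from mg/dL to mmol/L
#'
#' Calcium inputs and the optimal calcium are carried in mg/dL while the
#' release set-point is tabulated in mmol/L; 1 mmol/L of calcium is
#' 4.008 mg/dL.
#'
#' @param x calcium concentration(s) in mg/dL; must be non-negative.
#' @return concentration(s) in mmol/L.
#' @export
#' @examples
#' ca_mgdl_to_mmol(4.008)  # 1
ca_mgdl_to_mmol <- function(x) {
  if (any(!is.finite(x)) || any(x < 0)) {
    stop("calcium concentration must be non-negative and finite", call. = FALSE)
  }
  x / 4.008
}

#' @export
print.ptg_params <- function(x, ...) {
  g <- x$gland
  cat("<ptg_params>\n")
  cat(sprintf("  release: A = %g, B = %g pmol/min; set-point S_r = %g mmol/L; m = %g\n",
              g$A, g$B, g$s_r, g$m))
  cat(sprintf("  clearance k_cl = %g/min; sensitivity floor a_s = %g\n",
              g$k_cl, g$a_s))
  cat(sprintf("  cells: k_sq = %g, k_qs = %g, k_a = %g, k_k = %g (per min)\n",
              g$k_sq, g$k_qs, g$k_a, g$k_k))
  for (pw in names(x$pathways)) {
    b <- x$pathways[[pw]]
    cat(sprintf("  %-13s: A = %g, B = %g; p = %g, n = %g; tau_ca = %g, tau_p = %g\n",
                pw, b$A, b$B, b$p, b$n, b$tau_ca, b$tau_p))
  }
  cat(sprintf("  optima: Ca %g mg/dL, P %g mg/dL, D %g units\n",
              x$stimulus$ca$optimum, x$stimulus$p$optimum, x$stimulus$d$optimum))
  cat(sprintf("  %d reconciliation note(s)\n", length(x$reconciliation_notes)))
  invisible(x)
}
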
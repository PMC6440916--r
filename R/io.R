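#' Write a trajectory to CSV
#'
#' Frozen column order (time, the three inputs, the 21 states, the four
#' derived rates), floating-point values at 12 significant digits. Two runs
#' with identical arguments produce byte-identical files: the model is fully
#' deterministic.
#'
#' @param trajectory a `ptg_trajectory` (or any data.frame with its columns).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(trajectory, path) {
  cols <- trajectory_columns()
  missing <- setdiff(cols, names(trajectory))
  if (length(missing) > 0L) {
    stop("trajectory is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(cols, collapse = ","), con)
  if (nrow(trajectory) > 0L) {
    fmt <- vapply(cols, function(cl) {
      sprintf("%.12g", trajectory[[cl]])
    }, character(nrow(trajectory)))
    if (nrow(trajectory) == 1L) fmt <- matrix(fmt, nrow = 1L)
    writeLines(apply(fmt, 1L, paste, collapse = ","), con)
  }
  invisible(path)
}

trajectory_columns <- function() {
  c("time_min", "ca_mgdl", "p_mgdl", "d_units", state_names(),
    "k_d", "k_p", "k_pr", "release")
}

#' Read a trajectory CSV written by [write_trajectory()]
#'
#' @param path file path.
#' @return data.frame with the frozen trajectory columns.
#' @export
read_trajectory <- function(path) {
  out <- utils::read.csv(path, colClasses = "numeric")
  stopifnot(identical(names(out), trajectory_columns()))
  out
}

#' Write run metadata as a JSON sidecar
#'
#' Records everything needed to re-run a simulation bit-comparably: the full
#' parameter snapshot, the scenario name and settings, the solver options,
#' and the package version. The pipeline is deterministic; there are no
#' random seeds to record.
#'
#' @param path output file path.
#' @param params a `ptg_params`.
#' @param scenario list of scenario name and settings.
#' @param solver list of solver options (tolerances, grid size).
#' @return `path`, invisibly.
#' @export
write_run_metadata <- function(path, params, scenario, solver) {
  meta <- list(
    parameters = unclass(params),
    scenario = scenario,
    solver = solver,
    code_version = as.character(utils::packageVersion("ptgsim")),
    written = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  jsonlite::write_json(meta, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

# registry of named CLI scenarios: profile builder + default horizon (min)
scenario_registry <- function(params) {
  list(
    "acute-fast" = list(
      profile = acute_hypocalcemia_profile(0.05, 30, 90, params),
      minutes = 1440),
    "acute-slow" = list(
      profile = acute_hypocalcemia_profile(0.05, 120, 0, params),
      minutes = 1440),
    "hysteresis" = list(
      profile = hysteresis_profile(params = params),
      minutes = profile_duration(hysteresis_profile(params = params))),
    "chronic-hypocalcemia" = list(
      profile = chronic_hypocalcemia_profile(0.25, 200, params = params),
      minutes = 200 * 1440),
    "ckd-high-p" = list(
      profile = ckd_profile(c(4.5, 9), c(45, 15), 200, params),
      minutes = 200 * 1440),
    "ckd-moderate-p" = list(
      profile = ckd_profile(c(4.5, 6), c(45, 15), 200, params),
      minutes = 200 * 1440)
  )
}

# an output grid that resolves the fast release transient and still covers
# months: 1-min resolution over the first day, ~2000 points thereafter
default_output_grid <- function(t_end) {
  fine <- seq(0, min(t_end, 1440), by = 1)
  if (t_end <= 1440) return(fine)
  sort(unique(c(fine, seq(1440, t_end, length.out = 2000))))
}

cli_usage <- function() {
  paste(
    "usage: ptgsim <subcommand> [options]",
    "",
    "subcommands:",
    "  run          --scenario NAME [--days N | --minutes N] --out DIR",
    "               [--params FILE]",
    "  steady-state [--params FILE]",
    "  sensitivity  --targets KEY[,KEY...] [--factors F[,F...]]",
    "               --scenario NAME [--days N | --minutes N] --out DIR",
    "               [--params FILE]",
    "",
    "scenarios: acute-fast, acute-slow, hysteresis, chronic-hypocalcemia,",
    "           ckd-high-p, ckd-moderate-p",
    sep = "\n")
}

parse_cli_args <- function(argv) {
  out <- list()
  i <- 1L
  while (i <= length(argv)) {
    a <- argv[i]
    if (!startsWith(a, "--")) stop("unexpected argument '", a, "'", call. = FALSE)
    if (i == length(argv)) stop("missing value for ", a, call. = FALSE)
    out[[substring(a, 3)]] <- argv[i + 1L]
    i <- i + 2L
  }
  out
}

#' Command-line entry point
#'
#' Dispatches the `run`, `steady-state`, and `sensitivity` subcommands used
#' by the `inst/cli/ptgsim` script. `run` writes a trajectory CSV and a JSON
#' metadata sidecar into the output directory; `steady-state` prints the
#' optimal steady state as JSON; `sensitivity` writes the sweep table as CSV
#' plus a metadata sidecar.
#'
#' @param argv character vector of command-line arguments (subcommand first).
#' @return integer exit status: 0 on success, non-zero with a diagnostic on
#'   failure.
#' @export
#' @examples
#' \donttest{
#' out <- tempfile(); dir.create(out)
#' ptgsim_main(c("run", "--scenario", "acute-fast",
#'               "--minutes", "240", "--out", out))
#' }
ptgsim_main <- function(argv = commandArgs(trailingOnly = TRUE)) {
  status <- tryCatch({
    if (length(argv) == 0L) {
      message(cli_usage())
      return(invisible(1L))
    }
    sub <- argv[1]
    opts <- parse_cli_args(argv[-1])
    params <- if (!is.null(opts$params)) load_parameters(opts$params) else
      default_parameters()
    switch(sub,
      "run" = cli_run(opts, params),
      "steady-state" = cli_steady_state(params),
      "sensitivity" = cli_sensitivity(opts, params),
      stop("unknown subcommand '", sub, "'", call. = FALSE)
    )
    0L
  }, error = function(e) {
    message("ptgsim error: ", conditionMessage(e))
    1L
  })
  invisible(status)
}

cli_horizon <- function(opts, default_minutes) {
  if (!is.null(opts$minutes)) as.numeric(opts$minutes)
  else if (!is.null(opts$days)) as.numeric(opts$days) * 1440
  else default_minutes
}

cli_run <- function(opts, params) {
  if (is.null(opts$scenario)) stop("run requires --scenario", call. = FALSE)
  if (is.null(opts$out)) stop("run requires --out", call. = FALSE)
  reg <- scenario_registry(params)
  sc <- reg[[opts$scenario]]
  if (is.null(sc)) {
    stop("unknown scenario '", opts$scenario, "' (choose one of ",
         paste(names(reg), collapse = ", "), ")", call. = FALSE)
  }
  t_end <- cli_horizon(opts, sc$minutes)
  grid <- default_output_grid(t_end)
  traj <- simulate_ptg(params, sc$profile, t_span = c(0, t_end),
                       output_grid = grid)
  dir.create(opts$out, recursive = TRUE, showWarnings = FALSE)
  write_trajectory(traj, file.path(opts$out, "trajectory.csv"))
  write_run_metadata(file.path(opts$out, "run.json"), params,
                     scenario = list(name = opts$scenario, minutes = t_end),
                     solver = attr(traj, "meta")$solver)
  message("wrote ", file.path(opts$out, "trajectory.csv"))
}

cli_steady_state <- function(params) {
  y0 <- steady_state(params)
  cat(jsonlite::toJSON(as.list(y0), auto_unbox = TRUE, digits = NA,
                       pretty = TRUE), "\n")
}

cli_sensitivity <- function(opts, params) {
  if (is.null(opts$targets)) stop("sensitivity requires --targets", call. = FALSE)
  if (is.null(opts$scenario)) stop("sensitivity requires --scenario", call. = FALSE)
  if (is.null(opts$out)) stop("sensitivity requires --out", call. = FALSE)
  reg <- scenario_registry(params)
  sc <- reg[[opts$scenario]]
  if (is.null(sc)) stop("unknown scenario '", opts$scenario, "'", call. = FALSE)
  targets <- strsplit(opts$targets, ",", fixed = TRUE)[[1]]
  factors <- if (!is.null(opts$factors)) {
    as.numeric(strsplit(opts$factors, ",", fixed = TRUE)[[1]])
  } else c(0.5, 2)
  t_end <- cli_horizon(opts, sc$minutes)
  sweep <- sensitivity_sweep(params, targets, factors, sc$profile,
                             t_end = t_end)
  dir.create(opts$out, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(sweep, file.path(opts$out, "sensitivity.csv"),
                   row.names = FALSE)
  write_run_metadata(file.path(opts$out, "sensitivity.json"), params,
                     scenario = list(name = opts$scenario, minutes = t_end,
                                     targets = targets, factors = factors),
                     solver = list(rtol = 1e-8, atol = 1e-10))
  message("wrote ", file.path(opts$out, "sensitivity.csv"))
}
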
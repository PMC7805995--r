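# Run-report serialization: JSON report, poll-log CSV, trace CSV.

#' Write / read a run report
#'
#' Serializes a `"control_effort"` measurement to a directory: a versioned
#' JSON report (`report.json`, full double precision so it round-trips
#' losslessly), the poll log as CSV (`poll_log.csv`, one row per candidate
#' considered), and the optimal-resolution signal traces as CSV
#' (`traces.csv`, long format: signal, sample index, time, symbol, level).
#'
#' @param object a `"control_effort"`.
#' @param dir output directory (created if missing).
#' @return `write_run_report` returns the directory invisibly;
#'   `read_run_report` returns the report as a list.
#' @export
write_run_report <- function(object, dir) {
  stopifnot(inherits(object, "control_effort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fit <- object$fit
  report <- list(
    schema = "ctrleffort/run-report/1",
    version = object$version,
    timestamp = object$timestamp,
    task = object$scenario$task,
    scenario = object$scenario$scenario,
    kind = object$scenario$kind,
    seed = object$seed,
    T_window = object$T_window,
    params = object$config$params[order(names(object$config$params))],
    signals = lapply(object$specs, function(s)
      list(name = s$name, u_min = s$u_min, u_max = s$u_max, role = s$role)),
    r_init = as.integer(unclass(fit$r_init)),
    r_opt = as.integer(unclass(fit$r_opt)),
    I_uniform_opt = fit$value,
    I_min = fit$I_min,
    delta_I_opt = fit$delta_I_opt,
    rate_uniform = object$rate_uniform,
    rate_min = object$rate_min,
    stages = as.list(fit$stages),
    n_constraint = as.list(fit$n_constraint),
    reference = object$reference[c("t_stop", "reason", "end_q", "end_qd")])
  jsonlite::write_json(report, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  utils::write.csv(fit$poll_log, file.path(dir, "poll_log.csv"),
                   row.names = FALSE)
  if (!is.null(fit$traces)) {
    tr <- do.call(rbind, lapply(fit$traces, function(z)
      data.frame(signal = z$spec$name, k = seq_len(z$m),
                 time = z$sample_times, symbol = z$symbols,
                 level = z$held_values)))
    utils::write.csv(tr, file.path(dir, "traces.csv"), row.names = FALSE)
  }
  invisible(dir)
}

#' @rdname write_run_report
#' @param path path of a `report.json` (or a report directory).
#' @export
read_run_report <- function(path) {
  if (dir.exists(path)) path <- file.path(path, "report.json")
  jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
}

#' Build a scenario from a YAML configuration file
#'
#' Single-file configuration with top-level fields `task`, `scenario`, and
#' optionally `delay`, `noise_sd`, `repeats`, `phase3`, `r_init`
#' (`[n, m]`), plus blocks `plant` and `criterion` with named overrides
#' (see [effort_scenario()]).
#'
#' @param path YAML file path.
#' @return An [effort_scenario()].
#' @export
scenario_from_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  args <- y[intersect(names(y),
                      c("task", "scenario", "delay", "noise_sd", "repeats",
                        "phase3", "r_init"))]
  if (!is.null(args$r_init)) args$r_init <- as.numeric(unlist(args$r_init))
  if (!is.null(y$plant)) args$plant <- y$plant
  if (!is.null(y$criterion)) args$criterion <- y$criterion
  do.call(effort_scenario, args)
}
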
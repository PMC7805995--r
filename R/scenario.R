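# End-to-end scenarios: STIM / SENS / TORQUE.
#
# A scenario wires a plant, a task criterion, the signal codec, and the
# three-phase optimizer together: run the undiscretized reference (and
# extract signal ranges from it where required), build the expensive
# Boolean constraint "simulate with discretization -> criterion", minimize
# the uniform information over resolution vectors, then re-simulate at the
# optimum and report the empirical control effort.

#' Define a discretization scenario
#'
#' STIM discretizes the controller's output to the muscles (range fixed to
#' `[0, 1]`), SENS the proprioceptive sensor signals entering the
#' controller (ranges extracted from the reference run), and TORQUE the
#' command of the ideal torque actuator (fixed `[-20, 20]` N m for
#' pointing, reference-extracted for the periodic task). STIM and SENS use
#' the muscle-driven plant; TORQUE the torque-driven twin.
#'
#' @param task `"pointing"` or `"periodic"`.
#' @param scenario `"STIM"`, `"SENS"`, or `"TORQUE"`.
#' @param delay sensor delay override in s (`NULL` keeps the plant default:
#'   30 ms for the pointing muscle plant, 10 ms periodic muscle, 0 for the
#'   torque plants).
#' @param noise_sd controller output noise override (`NULL` keeps default).
#' @param repeats stochastic repeats averaged per constraint evaluation
#'   (pointing; the periodic plants are deterministic and use one run).
#' @param r_init initial resolution per signal as `c(n, m)`; default
#'   `n = 2^16` levels and one sample per controller tick — the finest
#'   resolution that is physically distinguishable in the loop.
#' @param phase3 run the optimizer's neighborhood phase.
#' @param plant named list of further plant parameter overrides.
#' @param criterion named list of criterion overrides (`radius`,
#'   `threshold` for pointing; `band`, `y_min` for periodic).
#' @return A list with class `"effort_scenario"`.
#' @export
effort_scenario <- function(task = c("pointing", "periodic"),
                            scenario = c("STIM", "SENS", "TORQUE"),
                            delay = NULL, noise_sd = NULL, repeats = 5L,
                            r_init = NULL, phase3 = TRUE,
                            plant = list(), criterion = list()) {
  task <- match.arg(task)
  scenario <- match.arg(scenario)
  kind <- if (scenario == "TORQUE") "torque" else "muscle"
  if (!is.null(delay)) plant$delay <- delay
  if (!is.null(noise_sd)) plant$noise_sd <- noise_sd
  maker <- if (task == "pointing") pointing_plant else periodic_plant
  config <- do.call(maker, c(list(kind = kind), plant))
  structure(list(task = task, scenario = scenario, kind = kind,
                 config = config, repeats = as.integer(repeats),
                 r_init = r_init, phase3 = isTRUE(phase3),
                 criterion_overrides = criterion),
            class = "effort_scenario")
}

#' @export
print.effort_scenario <- function(x, ...) {
  cat(sprintf("<effort_scenario> %s / %s (%s-driven plant)\n",
              x$task, x$scenario, x$kind))
  invisible(x)
}

# reproducible per-candidate seed stream: master seed + hash of r + repeat
candidate_seed <- function(master, r, i) {
  h <- sum((as.numeric(unclass(r)) %% 4096) * (seq_along(unclass(r)) * 977))
  as.integer((as.numeric(master) * 104729 + h * 13 + i * 7919) %% 2147483629)
}

#' Assemble the constraint problem of a scenario
#'
#' Runs the undiscretized reference, verifies that it achieves the task,
#' extracts signal ranges where the scenario requires them, and returns
#' the expensive Boolean constraint callable `P(r)` together with its
#' ingredients. Used by [control_effort()] and directly useful to compare
#' the optimizer against [brute_force_effort()] on the same problem.
#'
#' @param scenario an [effort_scenario()].
#' @param seed master seed; the constraint derives a reproducible seed
#'   stream from it and from each candidate `r`.
#' @return A list with `constraint` (function of `r`), `config` (the plant
#'   configuration, with the torque limit resolved), `specs`, `criterion`,
#'   `reference` (the undiscretized `"sim_result"`), `v_ref`, `run_one`
#'   (function of `r` and repeat index returning a `"sim_result"`), and
#'   `r_init` (the scenario's initial resolution vector).
#' @export
scenario_constraint <- function(scenario, seed = 1L) {
  stopifnot(inherits(scenario, "effort_scenario"))
  seed <- as.integer(seed)
  config <- scenario$config
  task <- scenario$task
  win <- plant_window(config)
  Tw <- win[["t1"]] - win[["t0"]]

  # periodic torque twin: saturation = 1.5 x peak muscle reference torque
  if (task == "periodic" && scenario$kind == "torque" &&
      is.null(config$params$limit)) {
    mref <- simulate_plant(periodic_plant("muscle"), seed = seed)
    config$params$limit <- 1.5 * max(abs(actuator_torque(mref)))
  }

  # noise-free reference for range extraction and reference speed
  cfg0 <- config; cfg0$params$noise_sd <- 0
  reference <- simulate_plant(cfg0, seed = seed)
  if (reference$reason != "completed")
    stop("reference configuration does not achieve the task (",
         reference$reason, " at t = ", reference$t_stop, " s)")

  sig <- plant_signals(config, scenario$scenario)
  specs <- if (scenario$scenario == "SENS" ||
               (scenario$scenario == "TORQUE" && task == "periodic")) {
    extract_reference_ranges(reference, sig)
  } else {
    default_signal_specs(config, scenario$scenario)
  }

  if (task == "pointing") {
    p <- config$params
    crit <- do.call(pointing_criterion, c(
      list(x_goal = p$L * cos(p$q_goal), y_goal = p$L * sin(p$q_goal),
           repeats = scenario$repeats),
      scenario$criterion_overrides))
    v_ref <- NULL
    run_one <- function(r, i)
      simulate_plant(config, scenario$scenario, r = r, specs = specs,
                     seed = candidate_seed(seed, r, i))
    constraint <- function(r)
      pointing_P(lapply(seq_len(crit$repeats), function(i) run_one(r, i)), crit)
    # the reference configuration itself must pass the stochastic criterion
    ref_runs <- lapply(seq_len(crit$repeats), function(i)
      simulate_plant(config, seed = candidate_seed(seed, integer(0), i)))
    if (pointing_P(ref_runs, crit) > 0)
      stop("reference configuration does not achieve the task ",
           "(undiscretized runs fail the pointing criterion)")
  } else {
    v_ref <- estimate_reference_speed(reference)
    crit <- do.call(periodic_criterion, c(
      list(v_ref = v_ref, T = win[["T_total"]]),
      scenario$criterion_overrides))
    config$params$speed_band <- crit$band
    config$params$y_min <- crit$y_min
    run_one <- function(r, i)
      simulate_plant(config, scenario$scenario, r = r, specs = specs,
                     seed = candidate_seed(seed, r, i), v_ref = v_ref)
    constraint <- function(r) periodic_P(run_one(r, 1L), crit)
    ref_check <- simulate_plant(config, seed = seed, v_ref = v_ref)
    if (periodic_P(ref_check, crit) > 0)
      stop("reference configuration does not achieve the task ",
           "(undiscretized run violates its own criterion)")
  }

  r_init <- scenario$r_init
  if (is.null(r_init)) r_init <- c(2^16, round(Tw / config$params$tick))
  r_init_full <- resolution_vector(rep(r_init[1L], length(sig)),
                                   rep(r_init[2L], length(sig)))

  list(constraint = constraint, config = config, specs = specs,
       criterion = crit, reference = reference, v_ref = v_ref,
       run_one = run_one, r_init = r_init_full, window = win, T_window = Tw)
}

#' Measure the control effort of a scenario
#'
#' The package's main fitting function. Assembles the scenario's
#' constraint problem with [scenario_constraint()], then minimizes the
#' uniform information `I(r) = sum_i m_i log2 n_i` over integer resolution
#' vectors subject to the movement succeeding, with [minimize_effort()].
#' The headline result is the empirical control effort `I_min`: the
#' entropy of the symbol sequences actually emitted at the optimal
#' resolution, reported in bits and bits per second of the movement
#' window.
#'
#' @param scenario an [effort_scenario()], or a task name (then `...` is
#'   passed to [effort_scenario()]).
#' @param seed master seed; all stochastic repeats derive their seeds from
#'   it and from the candidate resolution vector, so runs are reproducible.
#' @param ... passed to [effort_scenario()] when `scenario` is a name.
#' @return An object of class `"control_effort"`; see
#'   [summary.control_effort()]. Key fields: `fit` (the `"effort_fit"`),
#'   `I_min` (bit), `rate_min` and `rate_uniform` (bit/s), `specs`,
#'   `reference` (summary of the reference run), `criterion`.
#' @examples
#' \donttest{
#' ce <- control_effort(effort_scenario("pointing", "STIM"), seed = 1)
#' summary(ce)
#' }
#' @export
control_effort <- function(scenario, seed = 1L, ...) {
  if (is.character(scenario)) scenario <- effort_scenario(scenario, ...)
  stopifnot(inherits(scenario, "effort_scenario"))
  seed <- as.integer(seed)
  prob <- scenario_constraint(scenario, seed)
  config <- prob$config
  crit <- prob$criterion
  specs <- prob$specs
  reference <- prob$reference
  v_ref <- prob$v_ref
  run_one <- prob$run_one
  win <- prob$window
  Tw <- prob$T_window

  fit <- minimize_effort(prob$constraint, prob$r_init,
                         phase3 = scenario$phase3, seed = seed,
                         trace_fn = function(r) run_one(r, 1L)$traces)

  structure(list(
    scenario = scenario, config = config, criterion = crit, specs = specs,
    fit = fit,
    I_min = fit$I_min,
    rate_min = bits_per_second(fit$I_min, Tw),
    rate_uniform = bits_per_second(fit$value, Tw),
    rate_stages = fit$stages / Tw,
    window = win, T_window = Tw,
    v_ref = v_ref,
    reference = list(
      t_stop = reference$t_stop, reason = reference$reason,
      end_q = reference$q[length(reference$q)],
      end_qd = reference$qd[length(reference$qd)],
      ranges = lapply(specs, function(s) c(s$u_min, s$u_max))),
    seed = seed,
    version = tryCatch(as.character(utils::packageVersion("ctrleffort")),
                       error = function(e) "0.0.0"),
    timestamp = format(Sys.time(), tz = "UTC")),
    class = "control_effort")
}
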
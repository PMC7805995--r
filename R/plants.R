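# Bundled 1-DOF surrogate plants.
#
# Two closed-loop systems, each in a muscle-driven and a torque-driven
# variant:
#   * pointing: a single-hinge "arm" in the horizontal plane. The muscle
#     variant is actuated by an antagonistic pair of Hill-type muscle-like
#     actuators whose force-length characteristics create stable postural
#     equilibria (the morphological-computation property under study); the
#     torque variant replaces them with an ideal torque source.
#   * periodic: a leg-like oscillator tracking a sinusoidal reference,
#     mapped to forward progress and height of a hip analogue through a
#     compass-gait kinematic map (x' = l cos(phi) |phi'|, y = l cos(phi)).
# Both variants close the loop through a sampled controller (zero-order
# hold between ticks), an optional sensor delay line, and optional
# amplitude/time discretization of selected signals.

plant_defaults_cache <- new.env(parent = emptyenv())

#' Default plant parameters
#'
#' Reads the shipped parameter file (`inst/extdata/plant_defaults.yaml`)
#' and returns the merged parameter list for one plant variant.
#'
#' @param task `"pointing"` or `"periodic"`.
#' @param kind `"muscle"` or `"torque"`.
#' @return Named list of parameters.
#' @export
plant_defaults <- function(task = c("pointing", "periodic"),
                           kind = c("muscle", "torque")) {
  task <- match.arg(task); kind <- match.arg(kind)
  if (is.null(plant_defaults_cache$all)) {
    path <- system.file("extdata", "plant_defaults.yaml", package = "ctrleffort")
    if (path == "") path <- file.path("inst", "extdata", "plant_defaults.yaml")
    plant_defaults_cache$all <- yaml::read_yaml(path)
  }
  d <- plant_defaults_cache$all[[task]]
  c(d$shared, d[[kind]])
}

#' Construct a plant configuration
#'
#' @param kind `"muscle"` (antagonistic Hill-type pair) or `"torque"`
#'   (ideal torque actuator).
#' @param ... named parameter overrides; see the shipped
#'   `plant_defaults.yaml` for names, units, and defaults.
#' @return A list with class `"plant_config"`: `task`, `kind`, `params`.
#' @export
pointing_plant <- function(kind = c("muscle", "torque"), ...) {
  new_plant_config("pointing", match.arg(kind), list(...))
}

#' @rdname pointing_plant
#' @export
periodic_plant <- function(kind = c("muscle", "torque"), ...) {
  new_plant_config("periodic", match.arg(kind), list(...))
}

new_plant_config <- function(task, kind, overrides) {
  p <- plant_defaults(task, kind)
  unknown <- setdiff(names(overrides), names(p))
  if (length(unknown))
    stop("unknown plant parameter(s): ", paste(unknown, collapse = ", "))
  p[names(overrides)] <- overrides
  if (p$dt <= 0) stop("dt must be positive")
  for (tm in c("tick", "delay"))
    if (abs(p[[tm]] / p$dt - round(p[[tm]] / p$dt)) > 1e-9)
      stop("'", tm, "' must be a non-negative integer multiple of dt")
  structure(list(task = task, kind = kind, params = p),
            class = "plant_config")
}

#' @export
print.plant_config <- function(x, ...) {
  cat(sprintf("<plant_config> %s task, %s-driven\n", x$task, x$kind))
  cat("  dt =", x$params$dt, "s, controller tick =", x$params$tick,
      "s, sensor delay =", x$params$delay, "s\n")
  invisible(x)
}

# total simulated duration and the discretization window [t0, t1]
plant_window <- function(config) {
  p <- config$params
  if (config$task == "pointing") c(t0 = 0, t1 = p$T, T_total = p$T)
  else c(t0 = p$t_settle, t1 = p$t_settle + p$T_eval,
         T_total = p$t_settle + p$T_eval)
}

#' Signals of a discretization scenario
#'
#' @param config a [pointing_plant()]/[periodic_plant()] configuration.
#' @param scenario `"STIM"`, `"SENS"`, or `"TORQUE"`.
#' @return Character vector of signal names, in fixed order.
#' @export
plant_signals <- function(config, scenario = c("STIM", "SENS", "TORQUE")) {
  scenario <- match.arg(scenario)
  if (scenario %in% c("STIM", "SENS") && config$kind != "muscle")
    stop(scenario, " requires the muscle-driven plant")
  if (scenario == "TORQUE" && config$kind != "torque")
    stop("TORQUE requires the torque-driven plant")
  ang <- if (config$task == "pointing") "q" else "phi"
  switch(scenario,
         STIM = c("stim_flex", "stim_ext"),
         SENS = paste0(c(ang, paste0(ang, "d")), "_sens"),
         TORQUE = "torque")
}

# --- muscle-like actuator ---------------------------------------------------

fl_bell <- function(lnorm, width) exp(-((lnorm - 1) / width)^2)

fv_hill <- function(vnorm, v_max, curv, ecc) {
  # vnorm: normalized fiber velocity in optimal lengths/s, > 0 lengthening
  if (vnorm < 0) {
    s <- -vnorm
    max(0, (v_max - s) / (v_max + s / curv))
  } else {
    ecc - (ecc - 1) * v_max / (v_max + 7.56 * curv * vnorm)
  }
}

muscle_force <- function(a, lnorm, vnorm, p) {
  act <- a * p$F_max * fl_bell(lnorm, p$fl_width) *
    fv_hill(vnorm, p$v_max, p$fv_curv, p$fv_ecc)
  pas <- p$k_pas * p$F_max * max(0, lnorm - 1)^2
  act + pas
}

#' One step of the muscle-like actuator
#'
#' First-order activation dynamics (exact exponential update of
#' `da/dt = (u - a)/tau`) followed by force generation with a bell-shaped
#' force-length factor (maximum 1 at the optimal fiber length), a Hill-type
#' force-velocity factor (1 at zero velocity, decreasing toward 0 at the
#' maximal shortening velocity, saturating above 1 in lengthening), and a
#' quadratic parallel-elastic term engaged beyond the optimal length.
#'
#' @param activation current activation state in `[0, 1]`.
#' @param stimulation neural stimulation, clamped to `[0, 1]`.
#' @param length fiber length in m.
#' @param velocity fiber lengthening velocity in m/s (negative = shortening).
#' @param params parameter list with `F_max`, `l_opt`, `tau_act`,
#'   `fl_width`, `v_max`, `fv_curv`, `fv_ecc`, `k_pas` (see
#'   [plant_defaults()]).
#' @param dt time step in s.
#' @return List with `activation` (after the step) and `force` (N, using
#'   the updated activation).
#' @export
muscle_actuator_step <- function(activation, stimulation, length, velocity,
                                 params, dt) {
  u <- min(max(stimulation, 0), 1)
  a <- u + (activation - u) * exp(-dt / params$tau_act)
  f <- muscle_force(a, length / params$l_opt, velocity / params$l_opt, params)
  list(activation = a, force = f)
}

#' Sampled PD torque controller
#'
#' `u = kP (phi - phi_ref) + kD (phid - phid_ref)`, saturated at
#' `+/- limit`. The command is applied exactly as computed; the shipped
#' gains are negative so the torque opposes the tracking error.
#'
#' @param phi,phid joint angle (rad) and velocity (rad/s).
#' @param phi_ref,phid_ref reference angle and velocity.
#' @param kP,kD feedback gains (N m/rad, N m s/rad).
#' @param limit saturation torque (N m, positive).
#' @return Torque command in N m.
#' @export
pd_torque_controller <- function(phi, phid, phi_ref, phid_ref, kP, kD, limit) {
  u <- kP * (phi - phi_ref) + kD * (phid - phid_ref)
  pmin(pmax(u, -limit), limit)
}

#' Pure sensor delay line
#'
#' Shifts a sampled stream by `delta_t` seconds; before the delay buffer
#' has filled, the initial value is emitted.
#'
#' @param stream numeric vector sampled every `dt` seconds.
#' @param delta_t delay in seconds (non-negative multiple of `dt`).
#' @param dt sampling interval in seconds.
#' @return The delayed stream, same length as the input.
#' @export
delay_line <- function(stream, delta_t, dt) {
  k <- round(delta_t / dt)
  if (abs(delta_t / dt - k) > 1e-9 || k < 0)
    stop("'delta_t' must be a non-negative integer multiple of dt")
  if (k == 0L || length(stream) == 0L) return(stream)
  c(rep(stream[1L], min(k, length(stream))),
    stream[seq_len(max(0L, length(stream) - k))])
}

# --- closed-loop simulation -------------------------------------------------

# per-signal zero-order-hold discretizer state used inside the loop;
# an environment so that advancing it does not copy the symbol buffers
new_zoh <- function(spec, n, m, t0, Tw) {
  z <- new.env(parent = emptyenv())
  z$spec <- spec; z$n <- as.integer(n); z$m <- as.integer(m)
  z$times <- t0 + (seq_len(m) - 1) * Tw / m
  z$symbols <- integer(m); z$levels <- numeric(m)
  z$next_k <- 1L; z$held <- NA_real_
  z
}

#' Simulate a closed-loop plant run
#'
#' Fixed-step RK4 integration of the closed loop. The controller runs every
#' `tick` seconds and holds its output in between; sensor values entering
#' the controller are read from a delay line. Under a discretization
#' scenario the designated signals additionally pass through an
#' amplitude/time quantizer with its own uniform sample schedule over the
#' movement window and zero-order hold in between. Controller noise, when
#' configured, is additive Gaussian on the controller output, drawn from a
#' stream seeded by `seed`, so identical configurations and seeds yield
#' bit-identical results.
#'
#' For the periodic task the run aborts early (at `t_stop`) once, inside
#' the evaluation window, the sliding-window mean forward speed of the hip
#' analogue leaves the `speed_band` around `v_ref`, or its height falls to
#' `y_min` (a "fall"); the reference speed check is skipped when `v_ref`
#' is `NULL`. A non-finite state aborts any run with reason `"diverged"`.
#'
#' @param config a [pointing_plant()] or [periodic_plant()] configuration.
#' @param scenario `"none"` (no discretization) or one of `"STIM"`,
#'   `"SENS"`, `"TORQUE"`.
#' @param r resolution vector interleaved `(n_1, m_1, ...)`, one pair per
#'   scenario signal; required unless `scenario = "none"`.
#' @param specs list of [signal_spec()] matching the scenario signals;
#'   required for `"SENS"` (and `"TORQUE"` on the periodic task), where
#'   ranges come from a reference run; defaulted for `"STIM"` (`[0, 1]`)
#'   and pointing `"TORQUE"` (`[-20, 20]` N m).
#' @param seed integer seed for the controller noise stream.
#' @param v_ref reference forward speed (m/s) for the periodic abort rule.
#' @return An object of class `"sim_result"`; see Details.
#' @details The result carries the time grid, joint angle/velocity,
#'   activations (muscle), raw and applied command signals, delayed raw
#'   and applied sensor signals, end-effector `x`/`y` (pointing) or hip
#'   analogue `x_hat`/`y_hat` (periodic), the realized
#'   `"discretized_trace"` objects (`traces`), `t_stop` and `reason`
#'   (`"completed"`, `"speed"`, `"fall"`, `"diverged"`), and a saturation
#'   flag `m_saturated` set when a time resolution exceeds the integrator
#'   resolution of the window.
#' @export
simulate_plant <- function(config, scenario = c("none", "STIM", "SENS", "TORQUE"),
                           r = NULL, specs = NULL, seed = 1L, v_ref = NULL) {
  scenario <- match.arg(scenario)
  p <- config$params
  win <- plant_window(config)
  dt <- p$dt
  n_steps <- as.integer(round(win[["T_total"]] / dt))
  tick_steps <- as.integer(round(p$tick / dt))
  delay_steps <- as.integer(round(p$delay / dt))
  task <- config$task; kind <- config$kind
  muscle <- kind == "muscle"

  sig_names <- if (scenario == "none") character(0)
               else plant_signals(config, scenario)
  ns <- length(sig_names)
  if (scenario != "none") {
    if (is.null(r) || length(r) != 2L * ns)
      stop("'r' must supply one (n, m) pair per scenario signal")
    validate_resolution(r)
    if (is.null(specs)) specs <- default_signal_specs(config, scenario)
    if (length(specs) != ns) stop("'specs' must match the scenario signals")
  }

  Tw <- win[["t1"]] - win[["t0"]]
  zoh <- NULL
  m_saturated <- FALSE
  if (ns > 0L) {
    zoh <- lapply(seq_len(ns), function(j) {
      nj <- unclass(r)[2L * j - 1L]; mj <- unclass(r)[2L * j]
      if (mj > Tw / dt) m_saturated <<- TRUE
      new_zoh(specs[[j]], nj, mj, win[["t0"]], Tw)
    })
    names(zoh) <- sig_names
  }

  # pre-drawn controller noise, one row per tick
  n_ticks <- n_steps %/% tick_steps + 1L
  n_cmd <- if (muscle) 2L else 1L
  noise <- matrix(0, n_ticks, n_cmd)
  if (p$noise_sd > 0) {
    rng <- local_rng(seed)
    noise <- matrix(stats::rnorm(n_ticks * n_cmd, 0, p$noise_sd), n_ticks, n_cmd)
    rng()
  }

  # state and trajectory storage
  q0 <- if (task == "pointing") p$q0 else p$phi0
  qd0 <- if (task == "pointing") p$qd0 else p$amp * 2 * pi / p$t_cyc
  np1 <- n_steps + 1L
  Q <- numeric(np1); QD <- numeric(np1)
  A <- if (muscle) matrix(0, np1, 2L) else NULL
  CMD_RAW <- matrix(NA_real_, np1, n_cmd)
  CMD <- matrix(NA_real_, np1, n_cmd)
  SENS_RAW <- matrix(NA_real_, np1, 2L)   # delayed angle, delayed velocity
  SENS_APP <- matrix(NA_real_, np1, 2L)
  XH <- if (task == "periodic") numeric(np1) else NULL

  q <- q0; qd <- qd0; a1 <- 0; a2 <- 0
  Q[1L] <- q; QD[1L] <- qd
  x_hat <- 0
  t_stop <- win[["T_total"]]; reason <- "completed"

  # locals for speed
  arm <- if (muscle) p$gamma * p$l_opt else NA_real_
  omega_ref <- if (task == "periodic") 2 * pi / p$t_cyc else NA_real_
  wspd <- if (task == "periodic") as.integer(round(p$t_cyc / dt)) else NA_integer_
  discretize_cmds <- scenario %in% c("STIM", "TORQUE")
  discretize_sens <- scenario == "SENS"
  u_cmd <- numeric(n_cmd)       # applied commands (held)
  u_raw <- numeric(n_cmd)
  eps <- 1e-9

  # hot path: capture parameters as locals and inline the actuator math
  # (kept algebraically identical to muscle_force()/fv_hill()/fl_bell())
  deriv <- if (muscle) {
    local({
      gam <- p$gamma; qrf <- p$q_ref_flex; qre <- p$q_ref_ext
      Fm <- p$F_max; w2 <- p$fl_width^2; kp_pas <- p$k_pas
      vmx <- p$v_max; crv <- p$fv_curv; ecc <- p$fv_ecc
      dampc <- p$damping; J <- p$J; tau_a <- p$tau_act
      qlo <- p$q_lo; qhi <- p$q_hi; klim <- p$k_lim; arm_ <- arm
      function(q, qd, a1, a2, u1, u2) {
        l1 <- 1 - gam * (q - qrf)
        l2 <- 1 + gam * (q - qre)
        v1 <- -gam * qd
        v2 <- gam * qd
        fv1 <- if (v1 < 0) { s <- -v1; if (s >= vmx) 0 else (vmx - s) / (vmx + s / crv) }
               else ecc - (ecc - 1) * vmx / (vmx + 7.56 * crv * v1)
        fv2 <- if (v2 < 0) { s <- -v2; if (s >= vmx) 0 else (vmx - s) / (vmx + s / crv) }
               else ecc - (ecc - 1) * vmx / (vmx + 7.56 * crv * v2)
        e1 <- l1 - 1; e2 <- l2 - 1
        f1 <- a1 * Fm * exp(-(e1 * e1) / w2) * fv1 +
          (if (e1 > 0) kp_pas * Fm * e1 * e1 else 0)
        f2 <- a2 * Fm * exp(-(e2 * e2) / w2) * fv2 +
          (if (e2 > 0) kp_pas * Fm * e2 * e2 else 0)
        tau <- arm_ * (f1 - f2) - dampc * qd +
          (if (q > qhi) -klim * (q - qhi) else if (q < qlo) klim * (qlo - q) else 0)
        c(qd, tau / J, (u1 - a1) / tau_a, (u2 - a2) / tau_a)
      }
    })
  } else {
    local({
      dampc <- p$damping; J <- p$J
      qlo <- p$q_lo; qhi <- p$q_hi; klim <- p$k_lim
      function(q, qd, u) {
        tau <- u - dampc * qd +
          (if (q > qhi) -klim * (q - qhi) else if (q < qlo) klim * (qlo - q) else 0)
        c(qd, tau / J)
      }
    })
  }

  for (k in seq_len(n_steps)) {
    t <- (k - 1L) * dt

    # delayed sensors
    kd_idx <- max(1L, k - delay_steps)
    s_ang <- Q[kd_idx]; s_vel <- QD[kd_idx]
    SENS_RAW[k, ] <- c(s_ang, s_vel)
    if (discretize_sens) {
      zoh_advance(zoh[[1L]], t, s_ang, eps)
      zoh_advance(zoh[[2L]], t, s_vel, eps)
      in_ang <- if (is.na(zoh[[1L]]$held)) s_ang else zoh[[1L]]$held
      in_vel <- if (is.na(zoh[[2L]]$held)) s_vel else zoh[[2L]]$held
    } else {
      in_ang <- s_ang; in_vel <- s_vel
    }
    SENS_APP[k, ] <- c(in_ang, in_vel)

    # controller tick
    if ((k - 1L) %% tick_steps == 0L) {
      ti <- (k - 1L) %/% tick_steps + 1L
      if (muscle) {
        if (task == "pointing") {
          e <- p$q_goal - in_ang
          ed <- -in_vel
        } else {
          e <- p$amp * sin(omega_ref * t) - in_ang
          ed <- p$amp * omega_ref * cos(omega_ref * t) - in_vel
        }
        u_raw[1L] <- min(max(p$c0 + p$kp * e + p$kd * ed + noise[ti, 1L], 0), 1)
        u_raw[2L] <- min(max(p$c0 - p$kp * e - p$kd * ed + noise[ti, 2L], 0), 1)
      } else {
        if (task == "pointing") {
          ref <- p$q_goal; refd <- 0
        } else {
          ref <- p$amp * sin(omega_ref * t)
          refd <- p$amp * omega_ref * cos(omega_ref * t)
        }
        u_raw[1L] <- pd_torque_controller(in_ang, in_vel, ref, refd,
                                          p$kP, p$kD, p$limit) + noise[ti, 1L]
        u_raw[1L] <- min(max(u_raw[1L], -p$limit), p$limit)
      }
    }
    CMD_RAW[k, ] <- u_raw

    if (discretize_cmds) {
      for (j in seq_len(n_cmd)) {
        zoh_advance(zoh[[j]], t, u_raw[j], eps)
        u_cmd[j] <- if (is.na(zoh[[j]]$held)) u_raw[j] else zoh[[j]]$held
      }
    } else {
      u_cmd <- u_raw
    }
    CMD[k, ] <- u_cmd

    # RK4 step
    if (muscle) {
      k1 <- deriv(q, qd, a1, a2, u_cmd[1L], u_cmd[2L])
      k2 <- deriv(q + dt/2 * k1[1L], qd + dt/2 * k1[2L],
                  a1 + dt/2 * k1[3L], a2 + dt/2 * k1[4L], u_cmd[1L], u_cmd[2L])
      k3 <- deriv(q + dt/2 * k2[1L], qd + dt/2 * k2[2L],
                  a1 + dt/2 * k2[3L], a2 + dt/2 * k2[4L], u_cmd[1L], u_cmd[2L])
      k4 <- deriv(q + dt * k3[1L], qd + dt * k3[2L],
                  a1 + dt * k3[3L], a2 + dt * k3[4L], u_cmd[1L], u_cmd[2L])
      q_new <- q + dt/6 * (k1[1L] + 2*k2[1L] + 2*k3[1L] + k4[1L])
      qd_new <- qd + dt/6 * (k1[2L] + 2*k2[2L] + 2*k3[2L] + k4[2L])
      a1 <- min(max(a1 + dt/6 * (k1[3L] + 2*k2[3L] + 2*k3[3L] + k4[3L]), 0), 1)
      a2 <- min(max(a2 + dt/6 * (k1[4L] + 2*k2[4L] + 2*k3[4L] + k4[4L]), 0), 1)
    } else {
      u <- u_cmd[1L]
      k1 <- deriv(q, qd, u)
      k2 <- deriv(q + dt/2 * k1[1L], qd + dt/2 * k1[2L], u)
      k3 <- deriv(q + dt/2 * k2[1L], qd + dt/2 * k2[2L], u)
      k4 <- deriv(q + dt * k3[1L], qd + dt * k3[2L], u)
      q_new <- q + dt/6 * (k1[1L] + 2*k2[1L] + 2*k3[1L] + k4[1L])
      qd_new <- qd + dt/6 * (k1[2L] + 2*k2[2L] + 2*k3[2L] + k4[2L])
    }

    if (!is.finite(q_new) || !is.finite(qd_new)) {
      t_stop <- t; reason <- "diverged"
      break
    }

    if (task == "periodic") {
      # forward progress of the hip analogue (trapezoid in |phid| l cos phi)
      x_hat <- x_hat + dt / 2 *
        (p$l_leg * cos(q) * abs(qd) + p$l_leg * cos(q_new) * abs(qd_new))
      XH[k + 1L] <- x_hat
    }
    q <- q_new; qd <- qd_new
    Q[k + 1L] <- q; QD[k + 1L] <- qd
    if (muscle) A[k + 1L, ] <- c(a1, a2)

    # abort rules of the periodic task (inside the evaluation window)
    if (task == "periodic") {
      t_new <- k * dt
      if (t_new >= win[["t0"]]) {
        if (p$l_leg * cos(q) <= p$y_min) {
          t_stop <- t_new; reason <- "fall"
          break
        }
        if (!is.null(v_ref) && k > wspd &&
            (k - wspd) * dt >= win[["t0"]]) {
          v_win <- (XH[k + 1L] - XH[k + 1L - wspd]) / (wspd * dt)
          if (abs(v_ref - v_win) / v_ref >= p$speed_band) {
            t_stop <- t_new; reason <- "speed"
            break
          }
        }
      }
    }
  }

  k_stop <- as.integer(round(t_stop / dt)) + 1L
  time <- (seq_len(np1) - 1L) * dt
  traces <- NULL
  if (ns > 0L) {
    traces <- lapply(zoh, function(z) {
      filled <- max(z$next_k - 1L, 1L)
      # samples not reached before an abort repeat the last held value
      if (z$next_k <= z$m) {
        lastlev <- if (is.na(z$held)) {
          quantize_amplitude((z$spec$u_min + z$spec$u_max) / 2, z$spec, z$n)$level
        } else z$held
        lastsym <- if (z$next_k > 1L) z$symbols[z$next_k - 1L] else 1L
        z$symbols[z$next_k:z$m] <- lastsym
        z$levels[z$next_k:z$m] <- lastlev
      }
      new_discretized_trace(z$times - win[["t0"]], z$symbols, z$levels,
                            z$n, z$m, z$spec)
    })
    names(traces) <- sig_names
  }

  structure(list(
    task = task, kind = kind, scenario = scenario,
    time = time, q = Q, qd = QD, activation = A,
    cmd_raw = CMD_RAW, cmd = CMD, sens_raw = SENS_RAW, sens = SENS_APP,
    x = if (task == "pointing") p$L * cos(Q) else NULL,
    y = if (task == "pointing") p$L * sin(Q) else NULL,
    x_hat = XH, y_hat = if (task == "periodic") p$l_leg * cos(Q) else NULL,
    t_stop = t_stop, reason = reason, k_stop = k_stop,
    window = win, dt = dt, seed = seed,
    traces = traces, m_saturated = m_saturated,
    config = config),
    class = "sim_result")
}

zoh_advance <- function(z, t, value, eps) {
  while (z$next_k <= z$m && z$times[z$next_k] <= t + eps) {
    qz <- quantize_amplitude(value, z$spec, z$n)
    z$symbols[z$next_k] <- qz$symbol
    z$levels[z$next_k] <- qz$level
    z$held <- qz$level
    z$next_k <- z$next_k + 1L
  }
  invisible(z)
}

limit_torque <- function(q, q_lo, q_hi, k_lim) {
  if (q > q_hi) -k_lim * (q - q_hi)
  else if (q < q_lo) k_lim * (q_lo - q)
  else 0
}

#' @export
print.sim_result <- function(x, ...) {
  cat(sprintf("<sim_result> %s task, %s-driven, scenario %s\n",
              x$task, x$kind, x$scenario))
  cat(sprintf("  t_stop = %g s (%s)\n", x$t_stop, x$reason))
  if (x$task == "pointing")
    cat(sprintf("  end: q = %.4f rad, qd = %.4f rad/s\n",
                x$q[length(x$q)], x$qd[length(x$qd)]))
  else
    cat(sprintf("  forward distance: %.3f m\n", x$x_hat[x$k_stop]))
  invisible(x)
}

# default signal ranges that do not require a reference run
default_signal_specs <- function(config, scenario) {
  win <- plant_window(config)
  Tw <- win[["t1"]] - win[["t0"]]
  sig <- plant_signals(config, scenario)
  if (scenario == "STIM")
    return(lapply(sig, function(nm) signal_spec(nm, 0, 1, Tw,
                                                "controller-output")))
  if (scenario == "TORQUE" && config$task == "pointing") {
    lim <- 20
    return(list(signal_spec("torque", -lim, lim, Tw, "controller-output")))
  }
  stop(scenario, " signal ranges must be extracted from a reference run")
}

#' Net actuator torque of a muscle-driven run
#'
#' Recomputes the joint torque produced by the antagonistic pair
#' (active + passive, excluding joint damping and limits) from the recorded
#' states of a muscle-driven simulation. Used, e.g., to size the torque
#' twin's saturation at 1.5 times the peak of the muscle reference.
#'
#' @param sim a muscle-driven `"sim_result"`.
#' @return Numeric vector of torques (N m) on the simulation time grid.
#' @export
actuator_torque <- function(sim) {
  if (sim$kind != "muscle") stop("actuator torque is recomputed for muscle runs")
  p <- sim$config$params
  n <- length(sim$q)
  vapply(seq_len(n), function(k) {
    q <- sim$q[k]; qd <- sim$qd[k]
    f1 <- muscle_force(sim$activation[k, 1L], 1 - p$gamma * (q - p$q_ref_flex),
                       -p$gamma * qd, p)
    f2 <- muscle_force(sim$activation[k, 2L], 1 + p$gamma * (q - p$q_ref_ext),
                       p$gamma * qd, p)
    p$gamma * p$l_opt * (f1 - f2)
  }, numeric(1))
}

#' Extract signal ranges from a reference run
#'
#' Sets each signal's amplitude range to the exact minimum and maximum it
#' attained in an undiscretized reference simulation (no padding), over the
#' discretization window. A constant signal yields a degenerate range,
#' which downstream forces single-level quantization.
#'
#' @param reference a `"sim_result"` from an undiscretized run.
#' @param signal_names character vector of signal names (see
#'   [plant_signals()]).
#' @return List of [signal_spec()], one per name.
#' @export
extract_reference_ranges <- function(reference, signal_names) {
  if (reference$scenario != "none")
    stop("ranges must come from an undiscretized reference run")
  if (reference$reason != "completed")
    stop("reference run did not complete; cannot extract ranges")
  win <- reference$window
  Tw <- win[["t1"]] - win[["t0"]]
  rows <- which(reference$time >= win[["t0"]] & reference$time < win[["t1"]])
  ang <- if (reference$task == "pointing") "q" else "phi"
  lapply(signal_names, function(nm) {
    col <- switch(nm,
                  stim_flex = reference$cmd_raw[rows, 1L],
                  stim_ext = reference$cmd_raw[rows, 2L],
                  torque = reference$cmd_raw[rows, 1L],
                  reference$sens_raw[rows, if (nm == paste0(ang, "_sens")) 1L else 2L])
    role <- if (grepl("_sens$", nm)) "controller-input" else "controller-output"
    signal_spec(nm, min(col), max(col), Tw, role)
  })
}
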
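# S3 methods for the fitted objects.

#' @export
print.effort_fit <- function(x, ...) {
  cat("Control-effort pattern search\n")
  cat(sprintf("  signals: %d, r_init max entry: %d\n", x$n_signals,
              max(unclass(x$r_init))))
  pairs <- matrix(unclass(x$r_opt), nrow = 2L)
  cat("  r_opt: ", paste(sprintf("(n=%d, m=%d)", pairs[1L, ], pairs[2L, ]),
                         collapse = " "), "\n")
  cat(sprintf("  I(r_opt) = %.4g bit (uniform), I_min = %.4g bit (empirical)\n",
              x$value, x$I_min))
  cat(sprintf("  delta_I_opt = %.4g bit; constraint evaluations: %s\n",
              x$delta_I_opt,
              paste(names(x$n_constraint), x$n_constraint, sep = "=",
                    collapse = ", ")))
  invisible(x)
}

#' @export
summary.effort_fit <- function(object, ...) {
  structure(list(fit = object), class = "summary.effort_fit")
}

#' @export
print.summary.effort_fit <- function(x, ...) {
  f <- x$fit
  print(f)
  cat("  stage costs [bit]: ",
      paste(sprintf("%s=%.4g", names(f$stages), f$stages), collapse = ", "),
      "\n", sep = "")
  tab <- table(f$poll_log$phase, f$poll_log$outcome)
  cat("  poll outcomes:\n")
  print(tab)
  invisible(x)
}

#' Resolution parameters of a fit
#'
#' @param object an `"effort_fit"` or `"control_effort"`.
#' @param ... unused.
#' @return The optimal resolution vector (named, interleaved `n_i`, `m_i`).
#' @export
coef.effort_fit <- function(object, ...) object$r_opt

#' @rdname coef.effort_fit
#' @export
coef.control_effort <- function(object, ...) object$fit$r_opt

#' Search-trajectory plot
#'
#' Cost of every constraint-evaluated candidate against evaluation index,
#' with the accepted (incumbent) sequence drawn as a step line, on a log
#' scale. Feasible and infeasible candidates are distinguished.
#'
#' @param x an `"effort_fit"`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.effort_fit <- function(x, ...) {
  lg <- x$poll_log[x$poll_log$constraint_called | x$poll_log$accepted, ,
                   drop = FALSE]
  if (nrow(lg) == 0L) {
    warning("empty poll log; nothing to plot")
    return(invisible(x))
  }
  idx <- seq_len(nrow(lg))
  feas <- !is.na(lg$P) & lg$P <= 0
  ylim <- range(pmax(lg$cost, 0.5))
  graphics::plot(idx, pmax(lg$cost, 0.5), log = "y",
                 col = ifelse(feas, "forestgreen", "firebrick"),
                 pch = ifelse(lg$accepted, 19, 1),
                 xlab = "constraint evaluation",
                 ylab = "I(r) [bit, floor 0.5 for display]", ...)
  inc <- cummin(ifelse(lg$accepted, lg$cost, Inf))
  inc[!is.finite(inc)] <- NA
  graphics::lines(idx, pmax(inc, 0.5), type = "s", col = "gray30")
  graphics::legend("topright", bty = "n",
                   legend = c("feasible", "infeasible", "incumbent"),
                   col = c("forestgreen", "firebrick", "gray30"),
                   pch = c(1, 1, NA), lty = c(NA, NA, 1))
  invisible(x)
}

#' @export
print.control_effort <- function(x, ...) {
  cat(sprintf("Control effort: %s task, %s scenario (%s-driven plant)\n",
              x$scenario$task, x$scenario$scenario, x$scenario$kind))
  pairs <- matrix(unclass(x$fit$r_opt), nrow = 2L)
  sig <- vapply(x$specs, `[[`, character(1), "name")
  cat("  optimal resolution:\n")
  for (j in seq_along(sig))
    cat(sprintf("    %-10s n = %d levels, m = %d samples\n",
                sig[j], pairs[1L, j], pairs[2L, j]))
  cat(sprintf("  I(r_opt) uniform:   %8.4g bit  (%.4g bit/s)\n",
              x$fit$value, x$rate_uniform))
  cat(sprintf("  control effort I_min: %6.4g bit  (%.4g bit/s over T = %g s)\n",
              x$I_min, x$rate_min, x$T_window))
  cat(sprintf("  delta_I_opt = %.4g bit\n", x$fit$delta_I_opt))
  invisible(x)
}

#' Summary of a control-effort measurement
#'
#' @param object a `"control_effort"`.
#' @param ... unused.
#' @return The object, invisibly, after printing the scenario, the signal
#'   ranges, stage information values, and evaluation counts.
#' @export
summary.control_effort <- function(object, ...) {
  print(object)
  cat("  signal ranges (from ",
      if (object$scenario$scenario == "STIM") "fixed bounds"
      else if (object$scenario$scenario == "TORQUE" &&
               object$scenario$task == "pointing") "fixed bounds"
      else "reference run", "):\n", sep = "")
  for (s in object$specs)
    cat(sprintf("    %-10s [%.4g, %.4g]\n", s$name, s$u_min, s$u_max))
  cat("  stage rates [bit/s]: ",
      paste(sprintf("%s=%.4g", names(object$rate_stages), object$rate_stages),
            collapse = ", "), "\n", sep = "")
  cat("  constraint evaluations: ",
      paste(names(object$fit$n_constraint), object$fit$n_constraint,
            sep = "=", collapse = ", "), "\n", sep = "")
  if (!is.null(object$v_ref))
    cat(sprintf("  reference speed: %.4g m/s\n", object$v_ref))
  invisible(object)
}

#' @export
plot.control_effort <- function(x, ...) plot(x$fit, ...)

#' Re-simulate the plant at the fitted optimal resolution
#'
#' @param object a `"control_effort"`.
#' @param nsim number of runs.
#' @param seed master seed for the runs (default: the fit's seed).
#' @param ... unused.
#' @return A list of `"sim_result"` runs (length `nsim`).
#' @export
simulate.control_effort <- function(object, nsim = 1, seed = NULL, ...) {
  if (is.null(seed)) seed <- object$seed
  r <- unclass(object$fit$r_opt)
  lapply(seq_len(nsim), function(i)
    simulate_plant(object$config, object$scenario$scenario, r = r,
                   specs = object$specs,
                   seed = candidate_seed(seed, r, i),
                   v_ref = object$v_ref))
}
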
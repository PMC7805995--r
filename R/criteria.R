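# Task performance constraints P(r).
#
# Both tasks use a two-part criterion. Pointing: the averaged end-effector
# position must land inside a circle of radius 2.5 cm around the goal AND
# every averaged joint velocity magnitude must be below 0.15 rad/s, giving
# the Boolean P in {0, 1}. Periodic locomotion: the run must keep the hip
# analogue's sliding-window mean forward speed within a 6% band of the
# reference speed and its height above a floor; a violation stops the
# simulation at t_stop and P = T - t_stop, so feasibility (P <= 0) means
# surviving the whole movement.

#' Pointing performance criterion
#'
#' @param x_goal,y_goal goal position of the end-effector (m).
#' @param radius admissible distance from the goal (m); default 2.5 cm.
#' @param threshold admissible averaged joint speed (rad/s).
#' @param repeats number of stochastic repeats averaged per evaluation.
#' @return A list with class `"pointing_criterion"`.
#' @export
pointing_criterion <- function(x_goal, y_goal, radius = 0.025,
                               threshold = 0.15, repeats = 5L) {
  stopifnot(radius > 0, threshold > 0, repeats >= 1L)
  structure(list(x_goal = x_goal, y_goal = y_goal, radius = radius,
                 threshold = threshold, repeats = as.integer(repeats)),
            class = "pointing_criterion")
}

#' Periodic locomotion performance criterion
#'
#' @param v_ref reference forward speed (m/s), typically from
#'   [estimate_reference_speed()].
#' @param band admissible relative speed deviation (fraction in (0, 1)).
#' @param y_min height floor of the hip analogue (m).
#' @param T full movement duration that must be survived (s).
#' @return A list with class `"periodic_criterion"`.
#' @export
periodic_criterion <- function(v_ref, band = 0.06, y_min = 1.22, T = 6) {
  stopifnot(band > 0, band < 1, T > 0)
  structure(list(v_ref = v_ref, band = band, y_min = y_min, T = T),
            class = "periodic_criterion")
}

#' Pointing performance value
#'
#' Averages the end positions and end velocities over the stochastic
#' repeats, then checks that the mean end-effector position lies strictly
#' inside the goal circle and that the magnitude of every mean joint
#' velocity is strictly below the threshold. Returns the two-valued
#' performance `P`: 0 if both hold, 1 otherwise. A repeat that did not run
#' to completion fails the criterion outright.
#'
#' @param results list of exactly `repeats` pointing `"sim_result"` runs.
#' @param criterion a [pointing_criterion()].
#' @return `P` in `{0, 1}` (feasible iff 0).
#' @export
pointing_P <- function(results, criterion) {
  if (length(results) != criterion$repeats)
    stop("expected exactly ", criterion$repeats, " simulation runs, got ",
         length(results))
  if (any(vapply(results, function(s) s$reason != "completed", logical(1))))
    return(1)
  n <- length(results[[1L]]$q)
  x_end <- mean(vapply(results, function(s) s$x[n], numeric(1)))
  y_end <- mean(vapply(results, function(s) s$y[n], numeric(1)))
  qd_end <- mean(vapply(results, function(s) s$qd[n], numeric(1)))
  in_circle <- (criterion$x_goal - x_end)^2 + (criterion$y_goal - y_end)^2 <
    criterion$radius^2
  slow <- abs(qd_end) < criterion$threshold
  if (in_circle && slow) 0 else 1
}

#' Periodic performance value
#'
#' The time missing to the desired duration: `P = T - t_stop`. The abort
#' itself (speed band, height floor) is applied during simulation by
#' [simulate_plant()]; a run that survived the whole movement has
#' `t_stop = T` and `P = 0`.
#'
#' @param result a periodic `"sim_result"`.
#' @param criterion a [periodic_criterion()].
#' @return `P` in seconds (feasible iff `P <= 0`).
#' @export
periodic_P <- function(result, criterion) {
  criterion$T - result$t_stop
}

#' Estimate the reference forward speed
#'
#' Ordinary least-squares slope of the hip analogue's forward position
#' against time over the evaluation window of an undiscretized reference
#' run.
#'
#' @param reference a periodic `"sim_result"`, or a data frame / list with
#'   numeric `time` and `x` components.
#' @return Speed in m/s.
#' @export
estimate_reference_speed <- function(reference) {
  if (inherits(reference, "sim_result")) {
    win <- reference$window
    rows <- which(reference$time >= win[["t0"]] &
                    reference$time <= win[["t1"]])
    tt <- reference$time[rows]; xx <- reference$x_hat[rows]
  } else {
    tt <- reference$time; xx <- reference$x
  }
  if (length(tt) < 2L) stop("need at least two samples to fit a speed")
  unname(stats::coef(stats::lm(xx ~ tt))[2L])
}
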
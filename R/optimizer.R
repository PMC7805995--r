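#' Constraint-outcome cache
#'
#' Memoizes performance-constraint evaluations keyed on the integer
#' resolution vector, so that no candidate is simulated twice — including
#' across optimizer phases and across optimizer/oracle comparisons.
#' Stochastic constraints are cached too: the same candidate always maps to
#' the same (averaged) outcome, which guarantees descent consistency.
#'
#' @return An environment usable as a cache.
#' @export
new_effort_cache <- function() new.env(parent = emptyenv())

r_key <- function(r) paste(unclass(r), collapse = ",")

# log of every candidate considered; records are collected in an
# environment and bound into a data frame at the end of a phase/run
new_poll_log <- function() {
  e <- new.env(parent = emptyenv())
  e$rows <- list()
  e$n_constraint <- 0L
  e
}

log_row <- function(log, phase, r, cost, outcome, P, constraint_called,
                    accepted) {
  log$rows[[length(log$rows) + 1L]] <- list(
    phase = phase, candidate = r_key(r), cost = cost, outcome = outcome,
    P = P, constraint_called = constraint_called, accepted = accepted)
  if (constraint_called) log$n_constraint <- log$n_constraint + 1L
  length(log$rows)
}

poll_log_df <- function(log) {
  rows <- log$rows
  if (length(rows) == 0L)
    return(data.frame(phase = character(), candidate = character(),
                      cost = numeric(), outcome = character(), P = numeric(),
                      constraint_called = logical(), accepted = logical(),
                      stringsAsFactors = FALSE))
  data.frame(
    phase = vapply(rows, `[[`, character(1), "phase"),
    candidate = vapply(rows, `[[`, character(1), "candidate"),
    cost = vapply(rows, `[[`, numeric(1), "cost"),
    outcome = vapply(rows, `[[`, character(1), "outcome"),
    P = vapply(rows, `[[`, numeric(1), "P"),
    constraint_called = vapply(rows, `[[`, logical(1), "constraint_called"),
    accepted = vapply(rows, `[[`, logical(1), "accepted"),
    stringsAsFactors = FALSE)
}

#' Generate a poll candidate
#'
#' Pattern-search polling step: the candidate is
#' `r_test = r - mesh * d` elementwise. Non-integer entries are rounded to
#' the nearest integer with ties toward the smaller value (the search
#' direction is downward, and the cheap-first cost test filters over-eager
#' candidates safely), then clamped at 1. Entries with `d = 0` are
#' untouched.
#'
#' @param r current resolution vector (integer entries).
#' @param mesh positive mesh size vector, same length as `r`.
#' @param d direction vector, same length as `r`.
#' @return The candidate as a plain integer-valued numeric vector.
#' @examples
#' poll_candidate(c(8, 8), c(2, 2), c(1, 1)) # (6, 6)
#' poll_candidate(c(6, 6), c(2, 2), c(1, -0.5)) # (4, 7)
#' @export
poll_candidate <- function(r, mesh, d) {
  if (any(mesh <= 0)) stop("mesh entries must be positive")
  cand <- unclass(r) - mesh * d
  cand <- pmax(1, ceiling(cand - 0.5)) # nearest integer, ties downward
  cand[d == 0] <- unclass(r)[d == 0]
  as.numeric(cand)
}

#' Evaluate a poll candidate (cheap cost first)
#'
#' The cost `I(r)` is computed first; the expensive constraint is invoked
#' only if the candidate is strictly cheaper than the incumbent and its
#' outcome is not already cached. A constraint callable that throws is
#' recorded as infeasible (a crashed simulation is a failed movement).
#'
#' @param candidate resolution vector to evaluate.
#' @param incumbent_cost cost of the current best feasible point.
#' @param constraint function of `r` returning the performance value `P`;
#'   feasible iff `P <= 0`.
#' @param cache a [new_effort_cache()].
#' @param cost cost function of `r` (default [info_uniform()]).
#' @param log internal poll log (optional).
#' @param phase label recorded in the log.
#' @return List with `cost`, `feasible` (NA when skipped by cost), `P`,
#'   `outcome` (`"evaluated"`, `"cached"`, or `"skipped-by-cost"`), and the
#'   log row index.
#' @export
evaluate_candidate <- function(candidate, incumbent_cost, constraint, cache,
                               cost = info_uniform, log = NULL,
                               phase = "manual") {
  if (is.null(log)) log <- new_poll_log()
  cst <- cost(candidate)
  key <- r_key(candidate)
  if (cst >= incumbent_cost) {
    i <- log_row(log, phase, candidate, cst, "skipped-by-cost", NA_real_,
                 FALSE, FALSE)
    return(list(cost = cst, feasible = NA, P = NA_real_,
                outcome = "skipped-by-cost", row = i))
  }
  if (!is.null(cache[[key]])) {
    P <- cache[[key]]
    i <- log_row(log, phase, candidate, cst, "cached", P, FALSE, FALSE)
    return(list(cost = cst, feasible = P <= 0, P = P, outcome = "cached",
                row = i))
  }
  P <- tryCatch(as.numeric(constraint(candidate)),
                error = function(e) Inf) # crashed simulation = failed movement
  if (!is.finite(P) && !is.infinite(P)) P <- Inf
  cache[[key]] <- P
  i <- log_row(log, phase, candidate, cst, "evaluated", P, TRUE, FALSE)
  list(cost = cst, feasible = P <= 0, P = P, outcome = "evaluated", row = i)
}

mark_accepted <- function(log, row) log$rows[[row]]$accepted <- TRUE

#' Phase 1: parallel bisection on all resolution entries
#'
#' Rapid initial sweep treating all signals equally. The pattern contains
#' the single all-ones direction; the mesh starts at `(r_init - 1)/2`
#' elementwise, doubles after a successful poll (feasible and cheaper) and
#' halves otherwise, terminating once every mesh entry is below 1. This is
#' a parallel bisection toward the feasibility border, costing only a few
#' constraint evaluations even for many signals.
#'
#' @param r_init initial resolution vector; must be feasible.
#' @inheritParams evaluate_candidate
#' @return List with `r` (incumbent after the phase), `cost`, `log`
#'   (data frame), `n_constraint` (constraint evaluations used), `cache`.
#' @export
phase1_bisection <- function(r_init, constraint, cache = NULL, cost = info_uniform,
                             log = NULL) {
  validate_resolution(r_init)
  if (is.null(cache)) cache <- new_effort_cache()
  own_log <- is.null(log)
  if (own_log) log <- new_poll_log()
  n0 <- log$n_constraint

  ev0 <- evaluate_candidate(unclass(r_init), Inf, constraint, cache,
                            cost = cost, log = log, phase = "phase1")
  if (!isTRUE(ev0$feasible))
    stop("initial guess must satisfy the performance constraint")
  mark_accepted(log, ev0$row)
  r <- as.numeric(unclass(r_init))
  inc_cost <- ev0$cost
  mesh <- (r - 1) / 2
  ones <- rep(1, length(r))

  while (!all(mesh < 1)) {
    cand <- poll_candidate(r, mesh, ones)
    ev <- evaluate_candidate(cand, inc_cost, constraint, cache, cost = cost,
                             log = log, phase = "phase1")
    if (isTRUE(ev$feasible) && ev$cost < inc_cost) {
      r <- cand
      inc_cost <- ev$cost
      mark_accepted(log, ev$row)
      mesh <- mesh * 2
    } else {
      mesh <- mesh * 0.5
    }
  }
  list(r = r, cost = inc_cost,
       log = if (own_log) poll_log_df(log) else log,
       n_constraint = log$n_constraint - n0, cache = cache)
}

# augmented direction vectors: the entry of the most recent successful
# polling direction receives -0.5 in every vector except its own unit
# vector, which becomes a bare +0.5 (the "go back" combinations)
augmented_direction <- function(l, s, len) {
  d <- numeric(len)
  if (l == s) {
    d[s] <- 0.5
  } else {
    d[l] <- 1
    d[s] <- -0.5
  }
  d
}

#' Phase 2: coordinate pattern search
#'
#' Polls the `2 N_u` unit directions in fixed index order with
#' first-improvement acceptance (the cheapest-to-evaluate order, minimizing
#' expensive constraint calls). Because the cost is monotone in every
#' entry, only downward polls can improve. After a fully unsuccessful base
#' sweep, an augmented set of directions built from the most recent
#' successful direction allows one parameter to step back by half a mesh,
#' escaping shallow local minima. The mesh (re-initialized to
#' `max(1, r/4)`) doubles on success and halves after a failed full sweep;
#' the phase ends when all mesh entries are below 1 and a full sweep
#' (base + augmented) fails.
#'
#' @param r feasible starting resolution vector.
#' @inheritParams phase1_bisection
#' @param max_sweeps safety bound on the number of sweeps.
#' @return Same shape as [phase1_bisection()].
#' @export
phase2_pattern <- function(r, constraint, cache = NULL, cost = info_uniform,
                           log = NULL, max_sweeps = 1000L) {
  if (is.null(cache)) cache <- new_effort_cache()
  own_log <- is.null(log)
  if (own_log) log <- new_poll_log()
  n0 <- log$n_constraint

  r <- as.numeric(unclass(r))
  len <- length(r)
  inc_cost <- cost(r)
  mesh <- pmax(1, r / 4)
  last_dir <- NULL

  for (sweep in seq_len(max_sweeps)) {
    success <- FALSE
    for (l in seq_len(len)) {           # base sweep: unit vectors e_l
      d <- numeric(len); d[l] <- 1
      cand <- poll_candidate(r, mesh, d)
      ev <- evaluate_candidate(cand, inc_cost, constraint, cache, cost = cost,
                               log = log, phase = "phase2")
      if (isTRUE(ev$feasible) && ev$cost < inc_cost) {
        r <- cand; inc_cost <- ev$cost; last_dir <- l
        mark_accepted(log, ev$row)
        mesh <- mesh * 2
        success <- TRUE
        break
      }
    }
    if (!success && !is.null(last_dir)) { # augmented sweep
      for (l in seq_len(len)) {
        d <- augmented_direction(l, last_dir, len)
        cand <- poll_candidate(r, mesh, d)
        ev <- evaluate_candidate(cand, inc_cost, constraint, cache, cost = cost,
                                 log = log, phase = "phase2")
        if (isTRUE(ev$feasible) && ev$cost < inc_cost) {
          r <- cand; inc_cost <- ev$cost; last_dir <- l
          mark_accepted(log, ev$row)
          mesh <- mesh * 2
          success <- TRUE
          break
        }
      }
    }
    if (!success) {
      if (all(mesh < 1)) break
      mesh <- mesh * 0.5
    }
  }
  list(r = r, cost = inc_cost,
       log = if (own_log) poll_log_df(log) else log,
       n_constraint = log$n_constraint - n0, cache = cache)
}

#' Phase 3: local neighborhood sweep and discreteness error
#'
#' Systematic scan of the local neighborhood of the incumbent: all
#' directions with 1, 2, or 3 simultaneous unit decrements are polled with
#' the mesh fixed at ones. Any feasible strictly cheaper point restarts the
#' sweep. On termination the discreteness error is computed as the largest
#' cost drop achievable by decrementing a single entry,
#' `delta_I_opt = max_l I(r_opt) - I(r_opt - e_l)`, excluding entries
#' already at 1.
#'
#' @inheritParams phase2_pattern
#' @param max_restarts safety bound on accepted improvements.
#' @return As [phase1_bisection()], plus `delta_I_opt`.
#' @export
phase3_neighborhood <- function(r, constraint, cache = NULL,
                                cost = info_uniform, log = NULL,
                                max_restarts = 10000L) {
  if (is.null(cache)) cache <- new_effort_cache()
  own_log <- is.null(log)
  if (own_log) log <- new_poll_log()
  n0 <- log$n_constraint

  r <- as.numeric(unclass(r))
  len <- length(r)
  inc_cost <- cost(r)
  k_max <- min(3L, len)
  combos <- do.call(c, lapply(seq_len(k_max), function(k)
    utils::combn(len, k, simplify = FALSE)))

  for (restart in seq_len(max_restarts)) {
    improved <- FALSE
    for (combo in combos) {
      d <- numeric(len); d[combo] <- 1
      cand <- poll_candidate(r, rep(1, len), d)
      if (all(cand == r)) next  # fully clamped at the domain boundary
      ev <- evaluate_candidate(cand, inc_cost, constraint, cache, cost = cost,
                               log = log, phase = "phase3")
      if (isTRUE(ev$feasible) && ev$cost < inc_cost) {
        r <- cand; inc_cost <- ev$cost
        mark_accepted(log, ev$row)
        improved <- TRUE
        break
      }
    }
    if (!improved) break
  }
  list(r = r, cost = inc_cost, delta_I_opt = delta_info(r, cost),
       log = if (own_log) poll_log_df(log) else log,
       n_constraint = log$n_constraint - n0, cache = cache)
}

#' Discreteness error of an optimum
#'
#' `delta_I_opt = max_l [ I(r) - I(r - e_l) ]` over single-entry unit
#' decrements that stay in the admissible set (entries already at 1 are
#' excluded). Zero when every entry is 1.
#'
#' @param r resolution vector.
#' @param cost cost function (default [info_uniform()]).
#' @return Non-negative error bound in bit.
#' @export
delta_info <- function(r, cost = info_uniform) {
  r <- as.numeric(unclass(r))
  drops <- vapply(seq_along(r), function(l) {
    if (r[l] <= 1) return(NA_real_)
    dec <- r; dec[l] <- dec[l] - 1
    cost(r) - cost(dec)
  }, numeric(1))
  if (all(is.na(drops))) 0 else max(drops, na.rm = TRUE)
}

#' Minimize control effort by three-phase pattern search
#'
#' Solves `min I(r) subject to P(r) <= 0` over integer resolution vectors
#' for a cheap monotone cost and an expensive Boolean constraint: phase 1
#' bisects all entries in parallel toward the feasibility border, phase 2
#' refines entries individually with an adaptive mesh, and phase 3 scans
#' the local neighborhood with up to three simultaneous unit decrements and
#' computes the discreteness error. A shared cache guarantees that no
#' candidate is simulated twice. The constraint callable owns any
#' stochastic averaging and its seed stream; the optimizer treats it as
#' deterministic.
#'
#' @param constraint function of `r` returning `P(r)`; feasible iff
#'   `P(r) <= 0`. May throw; a throwing candidate is treated as infeasible.
#' @param r_init feasible initial resolution vector (high resolutions).
#' @param cost cost function of `r` (default [info_uniform()]).
#' @param phase3 logical; run the (potentially expensive) neighborhood
#'   phase. Skipping it leaves the phase-2 incumbent as the optimum, with
#'   the discreteness error still computed there.
#' @param seed integer recorded with the result (the optimizer itself is
#'   deterministic; the constraint owns its randomness).
#' @param trace_fn optional function of `r` returning the list of
#'   `"discretized_trace"` objects realized by the system at `r`; used to
#'   compute the empirical control effort at the optimum.
#' @param max_sweeps,max_restarts safety bounds for phases 2 and 3.
#' @return An object of class `"effort_fit"`: list with `r_opt`, `value`
#'   (uniform-assumption information at the optimum, bit), `I_min`
#'   (empirical information, bit; `NA` without `trace_fn`), `delta_I_opt`,
#'   `stages` (cost after initialization and each phase), `n_constraint`
#'   (constraint evaluations per phase), `poll_log`, `traces`, `r_init`,
#'   `seed`.
#' @examples
#' # feasible iff n >= 3 and m >= 5 for the single signal
#' con <- separable_constraint(c(3, 5))
#' fit <- minimize_effort(con, resolution_vector(64, 64))
#' coef(fit) # (3, 5)
#' @export
minimize_effort <- function(constraint, r_init, cost = info_uniform,
                            phase3 = TRUE, seed = NA_integer_,
                            trace_fn = NULL, max_sweeps = 1000L,
                            max_restarts = 10000L) {
  validate_resolution(r_init)
  cache <- new_effort_cache()
  log <- new_poll_log()

  p1 <- phase1_bisection(r_init, constraint, cache, cost = cost, log = log)
  n1 <- p1$n_constraint
  p2 <- phase2_pattern(p1$r, constraint, cache, cost = cost, log = log,
                       max_sweeps = max_sweeps)
  n2 <- p2$n_constraint
  if (phase3) {
    p3 <- phase3_neighborhood(p2$r, constraint, cache, cost = cost, log = log,
                              max_restarts = max_restarts)
    n3 <- p3$n_constraint
    r_opt <- p3$r
    delta <- p3$delta_I_opt
  } else {
    n3 <- 0L
    r_opt <- p2$r
    delta <- delta_info(p2$r, cost)
  }

  nu <- length(r_opt) / 2L
  r_opt_rv <- resolution_vector(r_opt[seq(1, length(r_opt), 2)],
                                r_opt[seq(2, length(r_opt), 2)])
  traces <- if (!is.null(trace_fn)) trace_fn(r_opt) else NULL
  structure(list(
    r_opt = r_opt_rv,
    value = cost(r_opt),
    I_min = if (is.null(traces)) NA_real_ else info_empirical(traces),
    delta_I_opt = delta,
    stages = c(I0 = cost(as.numeric(unclass(r_init))), I1 = p1$cost,
               I2 = p2$cost, I3 = cost(r_opt)),
    n_constraint = c(phase1 = n1, phase2 = n2, phase3 = n3),
    poll_log = poll_log_df(log),
    traces = traces,
    r_init = r_init,
    seed = seed,
    n_signals = nu,
    phase3 = phase3,
    cache = cache),
    class = "effort_fit")
}
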
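#' Synthetic monotone constraint problems
#'
#' Constraint factories with the structure the control-effort problem
#' assumes: feasibility is monotone in the resolution (finer resolutions
#' never break a working movement), with a clear border below which the
#' movement fails. `separable_constraint` is feasible iff every entry of
#' `r` is at least its threshold (its constrained optimum is known in
#' closed form). `weighted_sum_constraint` couples entries: feasible iff
#' `sum(w * r) >= c0`, returned as `P(r) = c0 - sum(w * r)`.
#'
#' @param thresholds positive integer vector, one per resolution entry,
#'   interleaved `(n_1, m_1, ...)`.
#' @param w positive weights, one per resolution entry.
#' @param c0 required weighted sum.
#' @return A function of `r` returning `P(r)` (feasible iff `P <= 0`).
#' @examples
#' P <- separable_constraint(c(3, 5))
#' P(c(3, 5)) # 0
#' P(c(2, 9)) # 1
#' @export
separable_constraint <- function(thresholds) {
  force(thresholds)
  function(r) as.numeric(!all(unclass(r) >= thresholds))
}

#' @rdname separable_constraint
#' @export
weighted_sum_constraint <- function(w, c0) {
  force(w); force(c0)
  function(r) c0 - sum(w * unclass(r))
}

# exact optimum of the separable problem: cost sum m_i log2 n_i is
# minimized at the threshold corner (entries with n* = 1 contribute 0)
separable_optimum <- function(thresholds) {
  n <- thresholds[seq(1, length(thresholds), 2)]
  m <- thresholds[seq(2, length(thresholds), 2)]
  list(r = thresholds, value = sum(m * log2(n)))
}

#' Generate the synthetic test-problem bundle
#'
#' Reproducible fixtures for optimizer and codec testing: a family of
#' separable monotone constraint problems with known optima, a family of
#' coupled weighted-sum problems, a small set of analytic signal time
#' series in the package CSV format, and one deliberately infeasible
#' problem whose initial guess violates the constraint (to exercise the
#' optimizer's error path). The same seed always produces an identical
#' bundle.
#'
#' @param seed integer seed.
#' @param n_separable,n_weighted number of problems of each family.
#' @param signals admissible signal counts for the separable family.
#' @param max_threshold largest threshold drawn.
#' @param dir optional directory; when given, the manifest (JSON) and the
#'   signal series (CSV) are also written there.
#' @return List with `separable` (each: `thresholds`, `r_init`,
#'   `constraint`, `optimum`), `weighted` (each: `w`, `c0`, `r_init`,
#'   `constraint`), `signals` (data frame), `infeasible_start`, `seed`.
#' @export
generate_fixtures <- function(seed = 1L, n_separable = 100L, n_weighted = 50L,
                              signals = 1:3, max_threshold = 16L, dir = NULL) {
  stopifnot(max_threshold >= 1L)
  rng <- local_rng(seed)
  on.exit(rng())

  separable <- lapply(seq_len(n_separable), function(i) {
    nu <- sample(signals, 1L)
    thr <- sample.int(max_threshold, 2L * nu, replace = TRUE)
    list(thresholds = thr,
         r_init = rep(64, 2L * nu),
         constraint = separable_constraint(thr),
         optimum = separable_optimum(thr))
  })

  weighted <- lapply(seq_len(n_weighted), function(i) {
    nu <- 2L
    box <- 16L
    w <- round(stats::runif(2L * nu, 0.5, 2), 3)
    # draw the border so that (a) the search start (the box corner) is
    # feasible and (b) the degenerate n = 1 corners are NOT feasible inside
    # the box, i.e. amplitude information is genuinely required
    w_n <- w[c(1L, 3L)]; w_m <- w[c(2L, 4L)]
    lo <- sum(w_n) + box * sum(w_m)
    hi <- box * sum(w)
    c0 <- round(lo + stats::runif(1, 0.2, 0.8) * (hi - lo), 3)
    list(w = w, c0 = c0, box = box,
         r_init = rep(box, 2L * nu),
         constraint = weighted_sum_constraint(w, c0))
  })

  tt <- seq(0, 1, by = 0.01)
  sig <- data.frame(time = tt,
                    ramp = tt,
                    sine = sin(2 * pi * tt),
                    noisy = sin(2 * pi * tt) + stats::rnorm(length(tt), 0, 0.05))

  bundle <- list(separable = separable, weighted = weighted, signals = sig,
                 infeasible_start = list(constraint = function(r) 1,
                                         r_init = rep(64, 2L)),
                 seed = as.integer(seed))

  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    manifest <- list(
      seed = as.integer(seed),
      separable = lapply(separable, function(p)
        list(thresholds = p$thresholds, r_init = p$r_init,
             optimum_r = p$optimum$r, optimum_value = p$optimum$value)),
      weighted = lapply(weighted, function(p)
        list(w = p$w, c0 = p$c0, r_init = p$r_init)))
    jsonlite::write_json(manifest, file.path(dir, "fixtures_manifest.json"),
                         auto_unbox = TRUE, digits = NA)
    write_signal_csv(sig, file.path(dir, "fixture_signals.csv"))
  }
  bundle
}

# seed the RNG locally; returns a restore function
local_rng <- function(seed) {
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  set.seed(seed)
  function() {
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }
}
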
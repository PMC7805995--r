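#' Brute-force control-effort oracle
#'
#' Exhaustive reference method for small problems, used as an independent
#' check of the pattern-search optimizer: enumerates the whole grid of
#' resolution vectors in increasing-cost order and returns the first
#' feasible point, which is the global constrained minimum. Constraint
#' outcomes are memoized in the same cache format as the optimizer, so the
#' two can share evaluations.
#'
#' @param constraint function of `r` returning `P(r)`; feasible iff
#'   `P(r) <= 0`.
#' @param upper integer vector of per-entry upper bounds (interleaved
#'   `(n_1, m_1, ...)`); the lower bound of every entry is `lower`.
#' @param lower per-entry lower bound (default 1).
#' @param cost cost function of `r` (default [info_uniform()]).
#' @param cache optional [new_effort_cache()] shared with other searches.
#' @param cap maximum admissible grid size.
#' @return List with `r` (argmin), `value`, `n_constraint` (constraint
#'   evaluations spent), and `grid_size`.
#' @examples
#' P <- separable_constraint(c(3, 5))
#' brute_force_effort(P, upper = c(9, 9))$r # (3, 5)
#' @export
brute_force_effort <- function(constraint, upper, lower = 1L,
                               cost = info_uniform, cache = NULL, cap = 1e6) {
  upper <- as.integer(upper)
  if (length(upper) %% 2L != 0L || any(upper < lower))
    stop("'upper' must be an even-length vector of bounds >= 'lower'")
  size <- prod(upper - lower + 1)
  if (size > cap)
    stop("grid of ", format(size, big.mark = ","),
         " points exceeds the cap; shrink the bounds")
  if (is.null(cache)) cache <- new_effort_cache()

  grid <- as.matrix(expand.grid(lapply(upper, function(u) lower:u),
                                KEEP.OUT.ATTRS = FALSE))
  ncol_n <- seq(1L, ncol(grid), by = 2L)
  ncol_m <- seq(2L, ncol(grid), by = 2L)
  # vectorized uniform cost over the grid; falls back to `cost` row-wise
  # only if a non-default cost is supplied
  if (identical(cost, info_uniform)) {
    costs <- rowSums(grid[, ncol_m, drop = FALSE] *
                       log2(grid[, ncol_n, drop = FALSE]))
  } else {
    costs <- apply(grid, 1L, cost)
  }
  ord <- order(costs)  # stable: ties resolved by enumeration order

  n_evals <- 0L
  for (i in ord) {
    r <- as.numeric(grid[i, ])
    key <- r_key(r)
    P <- cache[[key]]
    if (is.null(P)) {
      P <- tryCatch(as.numeric(constraint(r)), error = function(e) Inf)
      cache[[key]] <- P
      n_evals <- n_evals + 1L
    }
    if (P <= 0)
      return(list(r = r, value = costs[i], n_constraint = n_evals,
                  grid_size = size))
  }
  stop("no feasible point in bounds")
}
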
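#' Resolution vector
#'
#' The optimization variable of the control-effort problem: for each of the
#' `N_u` control signals, an amplitude resolution `n_i` (number of
#' distinguishable levels) and a time resolution `m_i` (number of
#' sample-and-hold updates during the movement). Entries are positive
#' integers; the vector interleaves them as `(n_1, m_1, ..., n_Nu, m_Nu)`.
#'
#' @param n integer vector of amplitude level counts, one per signal.
#' @param m integer vector of sample counts, one per signal (same length).
#' @return An integer vector of length `2 * length(n)` with class
#'   `"resolution_vector"`, interleaved `(n_1, m_1, n_2, m_2, ...)`.
#' @examples
#' resolution_vector(n = c(4, 8), m = c(3, 2))
#' @export
resolution_vector <- function(n, m) {
  if (length(n) != length(m) || length(n) < 1L)
    stop("'n' and 'm' must be non-empty vectors of equal length")
  r <- as.integer(rbind(n, m))
  names(r) <- paste0(rep(c("n", "m"), length(n)), rep(seq_along(n), each = 2L))
  validate_resolution(r)
  structure(r, class = "resolution_vector")
}

validate_resolution <- function(r) {
  rr <- unclass(r)
  if (length(rr) < 2L || length(rr) %% 2L != 0L)
    stop("a resolution vector must have an even, positive length (pairs n_i, m_i)")
  if (any(!is.finite(rr)) || any(rr < 1) || any(rr != floor(rr)))
    stop("all resolution entries must be integers >= 1")
  invisible(r)
}

#' @export
print.resolution_vector <- function(x, ...) {
  nu <- length(x) / 2L
  cat("Resolution vector (", nu, ifelse(nu == 1L, " signal", " signals"),
      "):\n", sep = "")
  pairs <- matrix(unclass(x), nrow = 2L)
  cat(paste0("  signal ", seq_len(nu), ": n = ", pairs[1L, ],
             ", m = ", pairs[2L, ]), sep = "\n")
  cat("Uniform information:", format(info_uniform(x)), "bit\n")
  invisible(x)
}

# amplitude (odd) and time (even) entries of an interleaved vector
r_levels  <- function(r) unclass(r)[seq(1L, length(r), by = 2L)]
r_samples <- function(r) unclass(r)[seq(2L, length(r), by = 2L)]

#' Signal specification
#'
#' Metadata for one control signal: its name, amplitude range, the duration
#' of the movement window over which it is discretized, and whether it is a
#' controller output (actuator command) or controller input (sensor value).
#' A degenerate range `u_min == u_max` is allowed for constant signals and
#' forces single-level quantization.
#'
#' @param name signal identifier.
#' @param u_min,u_max amplitude bounds in signal units (`u_min <= u_max`).
#' @param T movement duration in seconds (must be positive).
#' @param role `"controller-output"` or `"controller-input"`.
#' @return A list with class `"signal_spec"`.
#' @export
signal_spec <- function(name, u_min, u_max, T,
                        role = c("controller-output", "controller-input")) {
  role <- match.arg(role)
  if (!is.finite(u_min) || !is.finite(u_max) || u_min > u_max)
    stop("signal range must be finite with u_min <= u_max")
  if (!is.finite(T) || T <= 0) stop("duration T must be positive")
  structure(list(name = as.character(name), u_min = u_min, u_max = u_max,
                 T = T, role = role),
            class = "signal_spec")
}

#' @export
print.signal_spec <- function(x, ...) {
  cat(sprintf("Signal '%s' (%s): range [%g, %g], T = %g s\n",
              x$name, x$role, x$u_min, x$u_max, x$T))
  invisible(x)
}

#' Quantize a value to one of n amplitude levels
#'
#' Levels span the signal range inclusively with `n - 1` equal gaps:
#' `u_j = u_min + (j - 1) (u_max - u_min)/(n - 1)`. The value is clamped to
#' the range, then assigned to the nearest level, ties broken toward the
#' larger level. With `n = 1` (or a degenerate range) the single level is
#' the midpoint of the range.
#'
#' @param value numeric vector of signal values (finite).
#' @param spec a [signal_spec()].
#' @param n number of amplitude levels (integer >= 1).
#' @return A list with integer `symbol` (level index in `1..n`) and numeric
#'   `level` (the reconstructed amplitude), each the length of `value`.
#' @examples
#' s <- signal_spec("u", 0, 1, T = 1)
#' quantize_amplitude(0.30, s, n = 3) # symbol 2, level 0.5
#' @export
quantize_amplitude <- function(value, spec, n) {
  if (any(!is.finite(value)))
    stop("non-finite signal value: corrupt simulation output")
  n <- as.integer(n)
  if (is.na(n) || n < 1L) stop("'n' must be an integer >= 1")
  if (n == 1L || spec$u_max == spec$u_min) {
    mid <- (spec$u_min + spec$u_max) / 2
    return(list(symbol = rep(1L, length(value)),
                level  = rep(mid, length(value))))
  }
  step <- (spec$u_max - spec$u_min) / (n - 1L)
  v <- pmin(pmax(value, spec$u_min), spec$u_max)
  # nearest level, ties toward the larger level
  j <- floor((v - spec$u_min) / step + 0.5) + 1L
  j <- pmin(pmax(as.integer(j), 1L), n)
  list(symbol = j, level = spec$u_min + (j - 1L) * step)
}

#' Discretize a continuous signal in amplitude and time
#'
#' Samples the signal at `m` uniformly spaced instants
#' `t_k = (k - 1) T / m` starting at `t = 0`, quantizes each sample to `n`
#' amplitude levels, and reconstructs the signal by zero-order hold: each
#' level is held until the next sample instant.
#'
#' @param sampler a function of time returning the signal value at any
#'   `t` in `[0, T]`.
#' @param spec a [signal_spec()].
#' @param n amplitude level count (>= 1).
#' @param m sample count (>= 1).
#' @return A `"discretized_trace"`: list with `sample_times`, integer
#'   `symbols` in `1..n`, `held_values`, and `n`, `m`, `spec`.
#' @examples
#' s <- signal_spec("ramp", 0, 1, T = 1)
#' tr <- discretize_trace(function(t) t, s, n = 2, m = 2)
#' tr$symbols # 1, 2
#' @export
discretize_trace <- function(sampler, spec, n, m) {
  m <- as.integer(m)
  if (is.na(m) || m < 1L) stop("'m' must be an integer >= 1")
  tk <- (seq_len(m) - 1L) * spec$T / m
  vals <- vapply(tk, function(t) as.numeric(sampler(t)[[1L]]), numeric(1))
  q <- quantize_amplitude(vals, spec, n)
  new_discretized_trace(tk, q$symbol, q$level, as.integer(n), m, spec)
}

new_discretized_trace <- function(sample_times, symbols, held_values, n, m,
                                  spec) {
  structure(list(sample_times = sample_times, symbols = as.integer(symbols),
                 held_values = held_values, n = n, m = m, spec = spec),
            class = "discretized_trace")
}

#' @export
print.discretized_trace <- function(x, ...) {
  cat(sprintf("Discretized trace of '%s': n = %d levels, m = %d samples\n",
              x$spec$name, x$n, x$m))
  cat("Per-sample entropy:",
      format(info_empirical(x) / x$m, digits = 4), "bit\n")
  invisible(x)
}

#' Zero-order-hold reconstruction of a discretized trace
#'
#' @param trace a [discretize_trace()] result.
#' @param t numeric vector of times in `[0, T]`.
#' @return The held level at each `t`.
#' @export
trace_value <- function(trace, t) {
  idx <- findInterval(t, trace$sample_times)
  trace$held_values[pmax(idx, 1L)]
}

#' Symbol histogram of a discretized trace
#'
#' Counts how often each of the `n` amplitude levels was emitted and the
#' corresponding empirical probabilities `p_j = count_j / m`.
#'
#' @param trace a `"discretized_trace"`.
#' @return List with integer `counts` (length `n`) and numeric `probs`.
#' @export
symbol_histogram <- function(trace) {
  if (any(trace$symbols < 1L | trace$symbols > trace$n))
    stop("trace contains symbols outside 1..n: inconsistent with its resolution")
  counts <- tabulate(trace$symbols, nbins = trace$n)
  list(counts = counts, probs = counts / trace$m)
}

#' Information content under the uniform-occupancy assumption
#'
#' The optimization cost function: assuming every amplitude level is
#' equally likely (`p_ji = 1/n_i`), the information carried by all signals
#' is `I(r) = sum_i m_i log2(n_i)` bits. Side-effect free and linear in the
#' number of signals.
#'
#' @param r a [resolution_vector()] or a plain even-length integer vector
#'   interleaved `(n_1, m_1, ...)`.
#' @return Information in bit.
#' @examples
#' info_uniform(resolution_vector(n = 2, m = 4)) # 4 bit
#' @export
info_uniform <- function(r) {
  validate_resolution(r)
  sum(r_samples(r) * log2(r_levels(r)))
}

#' Empirical information content of discretized traces
#'
#' The control effort at a given resolution as actually realized by the
#' system: for each signal, the per-sample Shannon entropy
#' `H_i = -sum_j p_ji log2 p_ji` of the emitted symbol frequencies
#' (convention `0 log2 0 = 0`), weighted by the number of samples:
#' `I = sum_i m_i H_i`. Bounded above by [info_uniform()] at the same
#' resolution, with equality iff the symbol occupancy is uniform.
#'
#' @param traces a `"discretized_trace"` or a list of them (one per signal).
#' @return Information in bit.
#' @export
info_empirical <- function(traces) {
  if (inherits(traces, "discretized_trace")) traces <- list(traces)
  total <- 0
  for (tr in traces) {
    p <- symbol_histogram(tr)$probs
    p <- p[p > 0]
    total <- total + tr$m * (-sum(p * log2(p)))
  }
  total
}

#' Information rate
#'
#' Converts total information over a movement of duration `T` into a rate.
#'
#' @param I information in bit.
#' @param T duration in seconds (> 0).
#' @return Rate in bit/s.
#' @export
bits_per_second <- function(I, T) {
  if (!is.finite(T) || T <= 0) stop("duration T must be positive")
  I / T
}

#' Read / write signal time series as CSV
#'
#' Wide format: a `time` column in seconds followed by one column per
#' signal. Values are written with full double precision so that a
#' write/read cycle reproduces the numbers exactly.
#'
#' @param data a data frame whose first column is `time`.
#' @param path file path.
#' @return `read_signal_csv` returns the data frame; `write_signal_csv`
#'   returns `path` invisibly.
#' @export
write_signal_csv <- function(data, path) {
  stopifnot(is.data.frame(data), names(data)[1L] == "time")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(names(data), collapse = ","), con)
  body <- do.call(cbind, lapply(data, function(col) sprintf("%.17g", col)))
  writeLines(apply(body, 1L, paste, collapse = ","), con)
  invisible(path)
}

#' @rdname write_signal_csv
#' @export
read_signal_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (names(df)[1L] != "time") stop("signal CSV must start with a 'time' column")
  df
}
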
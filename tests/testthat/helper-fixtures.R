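# shared helpers: hand-built traces and stub simulation results

unit_spec <- function(name = "u", T = 1) signal_spec(name, 0, 1, T)

# a trace directly from a symbol sequence (levels on the uniform grid)
make_trace <- function(symbols, n, spec = unit_spec()) {
  m <- length(symbols)
  lev <- if (n == 1L) rep((spec$u_min + spec$u_max) / 2, m)
         else spec$u_min + (symbols - 1) * (spec$u_max - spec$u_min) / (n - 1)
  ctrleffort:::new_discretized_trace((seq_len(m) - 1) * spec$T / m,
                                     symbols, lev, as.integer(n),
                                     as.integer(m), spec)
}

# minimal pointing run stub for criterion arithmetic
pointing_stub <- function(x, y, qd, reason = "completed") {
  structure(list(q = 0, qd = qd, x = x, y = y, reason = reason),
            class = "sim_result")
}

# exact optimum of a separable problem by per-signal enumeration
# (independent of both the optimizer and brute_force_effort's ordering)
separable_enum_optimum <- function(thresholds, upper = 17L) {
  n_thr <- thresholds[seq(1, length(thresholds), 2)]
  m_thr <- thresholds[seq(2, length(thresholds), 2)]
  total <- 0
  for (i in seq_along(n_thr)) {
    best <- Inf
    for (n in seq_len(upper)) for (m in seq_len(upper))
      if (n >= n_thr[i] && m >= m_thr[i]) best <- min(best, m * log2(n))
    total <- total + best
  }
  total
}

# small, fast pointing STIM scenario for harness-level tests
fast_stim_scenario <- function(...) {
  effort_scenario("pointing", "STIM", r_init = c(8, 2), ...)
}
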
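test_that("amplitude quantization maps to the nearest inclusive level, ties upward", {
  s <- unit_spec()
  # midpoint of two levels ties to the larger one
  expect_identical(quantize_amplitude(0.5, s, 2)$symbol, 2L)
  expect_equal(quantize_amplitude(0.5, s, 2)$level, 1.0)
  # nearest of {0, 0.5, 1}
  expect_identical(quantize_amplitude(0.30, s, 3)$symbol, 2L)
  expect_equal(quantize_amplitude(0.30, s, 3)$level, 0.5)
  # out-of-range values are clamped before quantization
  expect_identical(quantize_amplitude(7.3, s, 5)$symbol, 5L)
  expect_equal(quantize_amplitude(7.3, s, 5)$level, 1.0)
  expect_identical(quantize_amplitude(-2, s, 5)$symbol, 1L)
  # a single level is the midpoint of the range
  expect_equal(quantize_amplitude(0.9, s, 1)$level, 0.5)
  # a degenerate range forces single-level behaviour for any n
  sdeg <- signal_spec("c", 0.3, 0.3, T = 1)
  expect_identical(quantize_amplitude(99, sdeg, 7)$symbol, 1L)
  expect_equal(quantize_amplitude(99, sdeg, 7)$level, 0.3)
  expect_error(quantize_amplitude(NaN, s, 3), "corrupt")
})

test_that("quantized levels never leave the signal range", {
  set.seed(11)
  for (i in 1:50) {
    lo <- runif(1, -5, 5); hi <- lo + runif(1, 0, 10)
    s <- signal_spec("u", lo, hi, T = 1)
    n <- sample(1:12, 1)
    v <- runif(20, lo - 3, hi + 3)
    q <- quantize_amplitude(v, s, n)
    expect_true(all(q$level >= lo - 1e-12 & q$level <= hi + 1e-12))
    expect_true(all(q$symbol >= 1L & q$symbol <= n))
  }
})

test_that("trace discretization samples uniformly from t = 0 with zero-order hold", {
  s <- unit_spec()
  # constant signal at n = 1 collapses to the range midpoint
  tr <- discretize_trace(function(t) 0.4, s, n = 1, m = 1)
  expect_equal(tr$held_values, 0.5)
  expect_equal(tr$sample_times, 0)
  # ramp sampled at t = 0 and T/2
  tr2 <- discretize_trace(function(t) t, s, n = 2, m = 2)
  expect_identical(tr2$symbols, c(1L, 2L))
  expect_equal(tr2$held_values, c(0, 1))
  expect_equal(trace_value(tr2, c(0, 0.49, 0.5, 0.99)), c(0, 0, 1, 1))
  # fine-resolution limit: reconstruction within one quantization step
  tr3 <- discretize_trace(function(t) sin(2 * pi * t) / 2 + 0.5, s,
                          n = 2^20, m = 1000)
  tt <- tr3$sample_times
  expect_lt(max(abs(tr3$held_values - (sin(2 * pi * tt) / 2 + 0.5))),
            1 / (2^20 - 1))
})

test_that("re-discretizing a held reconstruction is idempotent", {
  set.seed(7)
  s <- unit_spec()
  for (i in 1:25) {
    n <- sample(2:9, 1); m <- sample(1:40, 1)
    f <- approxfun(seq(0, 1, length.out = 12), runif(12), rule = 2)
    tr <- discretize_trace(f, s, n, m)
    tr2 <- discretize_trace(function(t) trace_value(tr, t), s, n, m)
    expect_identical(tr2$symbols, tr$symbols)
  }
})

test_that("uniform information is sum(m log2 n), additive and monotone", {
  expect_identical(info_uniform(resolution_vector(1, 1)), 0)
  expect_identical(info_uniform(resolution_vector(2, 4)), 4)
  expect_identical(info_uniform(resolution_vector(c(4, 8), c(3, 2))), 12)
  set.seed(3)
  for (i in 1:25) {
    nu <- sample(1:4, 1)
    n <- sample(1:20, nu, replace = TRUE); m <- sample(1:20, nu, replace = TRUE)
    r <- resolution_vector(n, m)
    # additivity over signals
    expect_equal(info_uniform(r),
                 sum(vapply(seq_len(nu), function(j)
                   info_uniform(resolution_vector(n[j], m[j])), numeric(1))))
    # strictly increasing in each n (m > 0) and each m (n >= 2)
    j <- sample(nu, 1)
    expect_gt(info_uniform(resolution_vector(n + (seq_len(nu) == j), m)),
              info_uniform(r) - 1e-15)
    if (n[j] >= 2)
      expect_gt(info_uniform(resolution_vector(n, m + (seq_len(nu) == j))),
                info_uniform(r))
  }
  expect_error(info_uniform(c(0, 3)), "integers >= 1")
  expect_error(info_uniform(c(2, 3, 4)), "even")
})

test_that("empirical information is m-weighted symbol entropy, bounded by the uniform value", {
  # degenerate occupancy carries no information
  expect_equal(info_empirical(make_trace(rep(2L, 8), n = 4)), 0)
  # uniform occupancy attains the maximum
  expect_equal(info_empirical(make_trace(rep(1:4, 2), n = 4)), 16)
  # m = 4 symbols (1,1,2,3) over n = 3 bins: H = 1.5 bit/sample
  expect_equal(info_empirical(make_trace(c(1L, 1L, 2L, 3L), n = 3)), 6)
  # several signals add
  expect_equal(info_empirical(list(make_trace(c(1L, 2L), n = 2),
                                   make_trace(rep(1L, 3), n = 5))), 2)
  expect_error(info_empirical(make_trace(c(1L, 4L), n = 3)), "outside")
})

test_that("empirical information never exceeds the uniform assumption", {
  set.seed(21)
  for (i in 1:50) {
    n <- sample(1:8, 1); m <- sample(1:60, 1)
    tr <- make_trace(sample.int(n, m, replace = TRUE), n)
    expect_lte(info_empirical(tr), info_uniform(resolution_vector(n, m)) + 1e-9)
  }
})

test_that("information rate divides by the movement duration", {
  expect_equal(bits_per_second(10, 5), 2)
  expect_equal(bits_per_second(0, 3.7), 0)
  expect_equal(bits_per_second(337.5, 1), 337.5)
  expect_error(bits_per_second(1, 0), "positive")
})

test_that("signal CSV writer/reader round-trips exactly", {
  df <- data.frame(time = seq(0, 1, by = 0.1),
                   a = sin(seq(0, 1, by = 0.1) * 3) / 7,
                   b = rnorm(11))
  path <- tempfile(fileext = ".csv")
  write_signal_csv(df, path)
  back <- read_signal_csv(path)
  expect_identical(back$time, df$time)
  expect_identical(back$a, df$a)
  expect_identical(back$b, df$b)
  unlink(path)
})
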
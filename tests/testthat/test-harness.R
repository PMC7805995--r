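test_that("brute force enumerates in increasing cost order and finds the constrained minimum", {
  bf <- brute_force_effort(separable_constraint(c(3, 5)), upper = c(9, 9))
  expect_equal(bf$r, c(3, 5))
  expect_equal(bf$value, 5 * log2(3))
  expect_equal(brute_force_effort(function(r) 0, upper = c(6, 6))$value, 0)
  expect_error(brute_force_effort(function(r) 1, upper = c(3, 3)),
               "no feasible point")
  expect_error(brute_force_effort(function(r) 0, upper = c(200, 200, 200, 200)),
               "cap")
  # shared cache: a pre-warmed cache removes those evaluations
  cache <- new_effort_cache()
  con <- separable_constraint(c(2, 2))
  b1 <- brute_force_effort(con, upper = c(4, 4), cache = cache)
  b2 <- brute_force_effort(con, upper = c(4, 4), cache = cache)
  expect_identical(b2$n_constraint, 0L)
  expect_equal(b1$r, b2$r)
})

test_that("fixture bundles are reproducible and carry their known optima", {
  a <- generate_fixtures(seed = 7, n_separable = 10, n_weighted = 3)
  b <- generate_fixtures(seed = 7, n_separable = 10, n_weighted = 3)
  expect_identical(lapply(a$separable, `[[`, "thresholds"),
                   lapply(b$separable, `[[`, "thresholds"))
  expect_identical(a$signals, b$signals)
  # manifested optimum agrees with direct enumeration
  for (p in a$separable[1:3]) {
    if (prod(rep(17, length(p$thresholds))) <= 1e6) {
      bf <- brute_force_effort(p$constraint,
                               upper = rep(17, length(p$thresholds)))
      expect_equal(bf$value, p$optimum$value)
    }
    expect_equal(separable_enum_optimum(p$thresholds), p$optimum$value)
  }
  # the bundle includes a problem whose initial guess violates the constraint
  expect_error(minimize_effort(a$infeasible_start$constraint,
                               a$infeasible_start$r_init),
               "initial guess")
  # writing to disk round-trips through the manifest
  dir <- tempfile()
  generate_fixtures(seed = 7, n_separable = 3, n_weighted = 2, dir = dir)
  man <- jsonlite::read_json(file.path(dir, "fixtures_manifest.json"),
                             simplifyVector = FALSE)
  expect_equal(man$seed, 7)
  expect_length(man$separable, 3L)
  unlink(dir, recursive = TRUE)
})

test_that("a scenario measurement returns a feasible optimum below the initial cost", {
  ce <- control_effort(fast_stim_scenario(), seed = 1)
  expect_s3_class(ce, "control_effort")
  fit <- ce$fit
  r_opt <- unclass(fit$r_opt)
  # returned point is feasible under the scenario's own constraint
  prob <- scenario_constraint(fast_stim_scenario(), seed = 1)
  expect_lte(prob$constraint(r_opt), 0)
  expect_lte(fit$value, info_uniform(fit$r_init))
  expect_gte(fit$delta_I_opt, 0)
  expect_gte(ce$I_min, 0)
  # empirical information can never exceed the uniform assumption
  expect_lte(ce$I_min, fit$value + 1e-9)
  expect_equal(ce$rate_min, ce$I_min / 1)
  # every constraint evaluation appears exactly once in the poll log
  expect_identical(sum(fit$poll_log$constraint_called),
                   as.integer(sum(fit$n_constraint)))
  expect_false(any(duplicated(
    fit$poll_log$candidate[fit$poll_log$constraint_called])))
})

test_that("an unachievable task is rejected at the reference stage", {
  sc <- effort_scenario("pointing", "STIM", criterion = list(radius = 1e-5))
  expect_error(control_effort(sc, seed = 1),
               "reference configuration does not achieve the task")
})

test_that("the optimizer agrees with brute force on the bundled separable fixtures", {
  fx <- generate_fixtures(seed = 12, n_separable = 8, n_weighted = 0,
                          signals = 1:2, max_threshold = 6)
  for (p in fx$separable) {
    fit <- minimize_effort(p$constraint, p$r_init)
    bf <- brute_force_effort(p$constraint, upper = rep(8, length(p$thresholds)))
    expect_equal(fit$value, bf$value)
  }
})

test_that("run reports serialize losslessly and scenarios load from YAML", {
  ce <- control_effort(fast_stim_scenario(), seed = 2)
  dir <- tempfile()
  write_run_report(ce, dir)
  rep1 <- read_run_report(dir)
  expect_identical(rep1$schema, "ctrleffort/run-report/1")
  # integer-valued doubles come back as integers; values are preserved
  expect_equal(as.numeric(rep1$I_min), ce$I_min)
  expect_equal(as.numeric(rep1$I_uniform_opt), ce$fit$value)
  expect_equal(as.numeric(rep1$rate_min), ce$rate_min)
  expect_equal(as.numeric(rep1$delta_I_opt), ce$fit$delta_I_opt)
  expect_equal(unlist(rep1$r_opt), unname(unclass(ce$fit$r_opt)))
  # a write/read/write cycle is a fixed point
  log_back <- utils::read.csv(file.path(dir, "poll_log.csv"),
                              stringsAsFactors = FALSE)
  expect_identical(nrow(log_back), nrow(ce$fit$poll_log))
  expect_identical(log_back$candidate, ce$fit$poll_log$candidate)
  unlink(dir, recursive = TRUE)

  yml <- tempfile(fileext = ".yaml")
  writeLines(c("task: pointing", "scenario: STIM", "repeats: 3",
               "r_init: [8, 4]", "phase3: false",
               "plant:", "  noise_sd: 0.0", "criterion:", "  radius: 0.03"),
             yml)
  sc <- scenario_from_yaml(yml)
  expect_identical(sc$task, "pointing")
  expect_identical(sc$scenario, "STIM")
  expect_identical(sc$repeats, 3L)
  expect_false(sc$phase3)
  expect_equal(sc$config$params$noise_sd, 0)
  expect_equal(sc$criterion_overrides$radius, 0.03)
  unlink(yml)
})

test_that("re-simulating a fitted scenario reproduces the optimal traces", {
  ce <- control_effort(fast_stim_scenario(), seed = 1)
  sims <- simulate(ce, nsim = 1)
  expect_identical(sims[[1]]$reason, "completed")
  expect_identical(lapply(sims[[1]]$traces, `[[`, "symbols"),
                   lapply(ce$fit$traces, `[[`, "symbols"))
  expect_equal(info_empirical(sims[[1]]$traces), ce$I_min)
})
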
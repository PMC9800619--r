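test_that("objective vanishes at the generating parameters", {
  p <- default_params()
  obs <- generate_observations(p, noise_sd = 0, n_replicates = 1, seed = 1)
  expect_lt(calibration_objective(p, obs), 1e-10)
})

test_that("objective increases when a sensitive parameter is perturbed", {
  p <- default_params()
  obs <- generate_observations(p, noise_sd = 0, n_replicates = 1, seed = 1)
  base <- calibration_objective(p, obs)
  for (nm in sensitive_param_names()) {
    expect_gt(calibration_objective(scale_parameter(p, nm, 10), obs), base)
  }
})

test_that("empty observation sets give a vacuous zero with a warning", {
  p <- default_params()
  obs <- generate_observations(p, noise_sd = 0, n_replicates = 1, seed = 1)
  empty <- obs[0, ]
  expect_warning(val <- calibration_objective(p, empty), "Empty")
  expect_equal(val, 0)
})

test_that("unknown observables are rejected", {
  p <- default_params()
  obs <- generate_observations(p, noise_sd = 0, n_replicates = 1, seed = 1)
  obs$observable[1] <- "Ki67"
  expect_error(calibration_objective(p, obs), "unknown")
})

test_that("fit recovers the truth when it is among the starts", {
  p <- default_params()
  obs <- generate_observations(p, noise_sd = 0, n_replicates = 1, seed = 1)
  fit <- fit_colitis(obs, free = c("gammaI17RMIR", "kMIRp65"),
                     n_starts = 2, seed = 1, include_init = TRUE)
  expect_lt(fit$objective_value, 1e-8)
  expect_equal(fit$best_params$gammaI17RMIR, p$gammaI17RMIR, tolerance = 0.05)
  expect_equal(fit$best_params$kMIRp65, p$kMIRp65, tolerance = 0.05)
})

test_that("fits are deterministic and improve monotonically in starts", {
  p <- default_params()
  obs <- generate_observations(p, noise_sd = 0.1, n_replicates = 3, seed = 2)
  f1 <- fit_colitis(obs, free = "gammaI17RMIR", n_starts = 2, seed = 5)
  f2 <- fit_colitis(obs, free = "gammaI17RMIR", n_starts = 2, seed = 5)
  expect_identical(unclass(f1$best_params), unclass(f2$best_params))
  expect_equal(f1$starts, f2$starts)
  f4 <- fit_colitis(obs, free = "gammaI17RMIR", n_starts = 4, seed = 5)
  expect_lte(f4$objective_value, f1$objective_value)
  # the longer run extends the shorter run's start list
  expect_equal(f4$starts$objective[1:2], f1$starts$objective)
})

test_that("tidy and glance summarize a fit", {
  p <- default_params()
  obs <- generate_observations(p, noise_sd = 0, n_replicates = 1, seed = 1)
  fit <- fit_colitis(obs, free = "kMIRpST", n_starts = 1, seed = 1,
                     include_init = TRUE)
  td <- tidy(fit)
  expect_named(td, c("parameter", "estimate", "lower", "upper"))
  expect_equal(td$parameter, "kMIRpST")
  gl <- glance(fit)
  expect_equal(gl$n_starts, 2)
  expect_equal(gl$n_free, 1)
  path <- withr::local_tempfile(fileext = ".json")
  write_fit(fit, path)
  expect_true(jsonlite::validate(paste(readLines(path), collapse = "")))
})

test_that("recovery report flags parameters outside twofold agreement", {
  p <- default_params()
  rep0 <- parameter_recovery_report(p, p)
  expect_true(all(rep0$ratio == 1))
  expect_false(any(rep0$flagged))
  p2 <- scale_parameter(p, "kMIRp65", 2.0)
  rep2 <- parameter_recovery_report(p, p2, names = mir31_coupling_names())
  expect_equal(rep2$ratio[rep2$parameter == "kMIRp65"], 2)
  expect_false(rep2$flagged[rep2$parameter == "kMIRp65"])  # boundary included
  p3 <- scale_parameter(p, "kMIRp65", 2.6)
  rep3 <- parameter_recovery_report(p, p3)
  expect_true(rep3$flagged[rep3$parameter == "kMIRp65"])
})

test_that("a model calibrated to the reference waveforms adapts", {
  obs <- reference_observations(default_protocol())
  fit <- fit_colitis(obs, free = c("kMIRp65", "kDamage"), n_starts = 1,
                     seed = 3, include_init = TRUE,
                     control = list(iter.max = 60, eval.max = 120,
                                    rel.tol = 1e-6))
  traj <- simulate_colitis(fit$best_params, default_protocol(),
                           times = coarse_times())
  obs_fit <- observables(traj)
  for (o in c("MIR31", "pP65", "pSTAT3")) {
    s <- obs_fit[obs_fit$observable == o, ]
    b <- s$value[1]
    at13 <- s$value[which.min(abs(s$time - 13))]
    expect_lte(abs(at13 - b), 0.15 * (max(s$value) - b))
  }
  n <- obs_fit[obs_fit$observable == "N", ]
  expect_lt(min(n$value), n$value[1])
  expect_gt(n$value[which.min(abs(n$time - 13))], 0.9 * n$value[1])
})
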
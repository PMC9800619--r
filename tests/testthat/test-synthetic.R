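test_that("noiseless observations equal the model observables exactly", {
  p <- default_params()
  tp <- c(0, 1, 3, 5, 6, 8, 10, 13)
  obs <- generate_observations(p, default_protocol(), timepoints = tp,
                               n_replicates = 2, noise_sd = 0, seed = 1)
  traj <- simulate_colitis(p, default_protocol(), times = tp)
  model <- observables(traj)
  for (o in c("MIR31", "pP65", "pSTAT3", "N")) {
    got <- obs_series(obs, o)
    want <- model[model$observable == o, ]
    # both normalized by the max over the same time points
    expect_equal(got$value[got$replicate == 1],
                 want$value / max(want$value), tolerance = 1e-10)
  }
})

test_that("observation sets are deterministic given the seed", {
  p <- default_params()
  a <- generate_observations(p, seed = 7)
  b <- generate_observations(p, seed = 7)
  c <- generate_observations(p, seed = 8)
  expect_identical(as.data.frame(a), as.data.frame(b))
  expect_false(identical(as.data.frame(a), as.data.frame(c)))
})

test_that("replicate noise has the configured coefficient of variation", {
  p <- default_params()
  obs <- generate_observations(p, timepoints = 5, n_replicates = 1000,
                               noise_sd = 0.1, seed = 3)
  cv <- obs |>
    dplyr::summarise(cv = stats::sd(value) / mean(value), .by = "observable")
  expect_true(all(cv$cv > 0.09 & cv$cv < 0.11))
})

test_that("replicate means converge to the noiseless values", {
  p <- default_params()
  tp <- c(0, 5, 10)
  big <- generate_observations(p, timepoints = tp, n_replicates = 10000,
                               noise_sd = 0.1, seed = 5)
  noiseless <- generate_observations(p, timepoints = tp, n_replicates = 1,
                                     noise_sd = 0, seed = 1)
  means <- big |>
    dplyr::summarise(m = mean(value), .by = c("observable", "time_days"))
  joined <- dplyr::inner_join(means, as.data.frame(noiseless),
                              by = c("observable", "time_days"))
  expect_true(all(abs(joined$m - joined$value) <=
                    0.01 * pmax(joined$value, 0.05)))
})

test_that("each observable's replicate-mean maximum is one", {
  obs <- generate_observations(default_params(), n_replicates = 4,
                               noise_sd = 0.15, seed = 2)
  norm <- obs |>
    dplyr::summarise(m = mean(value), .by = c("observable", "time_days")) |>
    dplyr::summarise(mx = max(m), .by = "observable")
  expect_equal(norm$mx, rep(1, 4))
})

test_that("reference waveforms carry the qualitative experimental anchors", {
  wf <- reference_waveforms(dose_protocol(3.5))
  for (o in c("MIR31", "pP65", "pSTAT3")) {
    s <- wf[wf$observable == o, ]
    expect_equal(s$time[which.max(s$value)], 5)           # peak at withdrawal
  }
  mir <- wf[wf$observable == "MIR31", ]
  expect_lt(abs(mir$value[nrow(mir)] - mir$value[1]) / mir$value[1], 0.05)
  n <- wf[wf$observable == "N", ]
  expect_equal(n$time[which.min(n$value)], 5)
  expect_true(all(diff(n$value[n$time <= 5]) <= 1e-12))
  expect_true(all(diff(n$value[n$time >= 5]) >= -1e-12))
  expect_gt(n$value[nrow(n)], 0.99)
})

test_that("observation sets round-trip through CSV with metadata", {
  p <- default_params()
  obs <- generate_observations(p, n_replicates = 3, noise_sd = 0.1, seed = 4)
  path <- withr::local_tempfile(fileext = ".csv")
  write_observations(obs, path)
  back <- read_observations(path)
  expect_equal(as.data.frame(back), as.data.frame(obs), tolerance = 1e-12)
  expect_equal(attr(back, "noise_sd"), 0.1)
  expect_equal(attr(back, "seed"), 4)
  expect_equal(attr(back, "protocol")$dss_conc, 3.5)
})

test_that("generation rejects invalid inputs", {
  p <- default_params()
  expect_error(generate_observations(p, timepoints = c(0, 20)), "horizon")
  expect_error(generate_observations(p, n_replicates = 0), "n_replicates")
  expect_error(generate_observations(p, noise_sd = -0.1), "noise_sd")
})
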
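test_that("knockout model has no MIR31 production and MIR31 stays at zero", {
  p <- default_params()
  rhs <- build_model(p, "KO")
  y <- baseline_state(p, "KO")
  expect_equal(unname(y["MIR31"]), 0)
  dy <- rhs(0, y, 3.5)
  expect_equal(dy[9], 0)  # d[MIR31]/dt
  traj <- ko_traj()
  expect_true(all(traj$MIR31 == 0))
})

test_that("wild type with all MIR31 couplings zeroed reproduces the knockout", {
  p0 <- default_params()
  p <- do.call(colitis_params,
               stats::setNames(as.list(rep(0, 6)), mir31_coupling_names()))
  times <- coarse_times()
  wt0 <- simulate_colitis(p, default_protocol(), "WT", times = times)
  ko <- simulate_colitis(p0, default_protocol(), "KO", times = times)
  for (sp in setdiff(names(wt0), c("time", "MIR31"))) {
    expect_equal(wt0[[sp]], ko[[sp]], tolerance = 1e-6)
  }
  expect_true(all(abs(wt0$MIR31) < 1e-6))
})

test_that("untreated simulation stays flat at the baseline steady state", {
  p <- default_params()
  traj <- simulate_colitis(p, dose_protocol(dss_conc = 0),
                           times = coarse_times())
  for (sp in setdiff(names(traj), "time")) {
    rng <- range(traj[[sp]])
    expect_lt(diff(rng), 1e-5 * max(rng[2], 1))
  }
})

test_that("states remain non-negative under random parameter perturbations", {
  p0 <- default_params()
  rate_names <- grep("^(k|d|gamma)", names(p0), value = TRUE)
  set.seed(99)
  for (i in 1:5) {
    jitter <- stats::setNames(
      as.list(unlist(p0[rate_names]) * exp(stats::runif(length(rate_names),
                                                        log(0.5), log(2)))),
      rate_names)
    p <- do.call(colitis_params, jitter)
    traj <- simulate_colitis(p, default_protocol(), "WT",
                             times = seq(0, 15, 0.1))
    expect_true(all(as.matrix(traj[, -1]) >= 0))
  }
})

test_that("adaptive simulation matches an independent fixed-step integrator", {
  p <- default_params()
  prot <- default_protocol()
  rhs <- build_model(p, "WT")
  f <- function(t, y) rhs(t, y, dss_input(t, prot))
  y0 <- baseline_state(p, "WT")
  times <- seq(0, 15, by = 0.002)
  ref <- rk4_integrate(f, as.numeric(y0), times)
  keep <- seq(1, length(times), by = 500)  # compare every day
  traj <- simulate_colitis(p, prot, "WT", times = times[keep], y0 = y0)
  sim <- as.matrix(tibble::as_tibble(traj)[, -1])
  scale <- pmax(abs(ref[keep, ]), 1e-3)
  expect_lt(max(abs(sim - ref[keep, ]) / scale), 1e-5)
})

test_that("solution is converged with respect to the output grid", {
  p <- default_params()
  fine <- simulate_colitis(p, default_protocol(), times = seq(0, 15, 0.01))
  coarse <- simulate_colitis(p, default_protocol(), times = seq(0, 15, 0.02))
  idx <- match(coarse$time, fine$time)
  m_f <- as.matrix(tibble::as_tibble(fine)[idx, -1])
  m_c <- as.matrix(tibble::as_tibble(coarse)[, -1])
  expect_lt(max(abs(m_f - m_c) / pmax(abs(m_f), 1e-3)), 1e-6)
})

test_that("observables normalize to their own maxima", {
  obs <- observables(wt_traj())
  for (o in unique(obs$observable)) {
    expect_equal(max(obs_series(obs, o)$value), 1)
  }
  flat <- simulate_colitis(default_params(), dose_protocol(dss_conc = 0),
                           times = coarse_times())
  obs_flat <- observables(flat)
  expect_true(all(abs(obs_flat$value - 1) < 1e-5))
})

test_that("cross-genotype normalization uses the reference maxima", {
  obs_ko <- observables(ko_traj(), norm_ref = wt_traj())
  expect_gt(max(obs_series(obs_ko, "pP65")$value), 1)
  expect_gt(max(obs_series(obs_ko, "pSTAT3")$value), 1)
})

test_that("trajectory exports tidy long format", {
  long <- trajectory_long(wt_traj())
  expect_named(long, c("time_days", "species", "value", "genotype", "dss_conc"))
  expect_setequal(unique(long$species), setdiff(names(wt_traj()), "time"))
  expect_true(all(long$genotype == "WT"))
  expect_true(all(long$dss_conc == 3.5))
})

test_that("simulation rejects grids outside the protocol horizon", {
  expect_error(
    simulate_colitis(default_params(), default_protocol(), times = c(0, 16)),
    "horizon")
})
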
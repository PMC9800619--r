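test_that("binding weights are mass-action in strength and target level", {
  p <- default_params()
  st <- c(Gp130 = 0, IL17RA = 0, Axin1 = 0, Lats12 = 0)
  expect_equal(binding_weights(st, p),
               c(w0 = p$w0, w1 = 0, w2 = 0, w3 = 0, w4 = 0))
  p2 <- colitis_params(gammaI17RMIR = 2)
  st2 <- c(Gp130 = 1, IL17RA = 3, Axin1 = 1, Lats12 = 1)
  expect_equal(unname(binding_weights(st2, p2)["w2"]), 6)
  # bilinearity: doubling gamma and halving the target leaves w unchanged
  p4 <- colitis_params(gammaI17RMIR = 4)
  st3 <- st2; st3["IL17RA"] <- 1.5
  expect_equal(binding_weights(st3, p4)[["w2"]],
               binding_weights(st2, p2)[["w2"]])
  expect_error(binding_weights(c(st2, -1), p), "non-negative")
})

make_traj <- function(df) {
  structure(tibble::as_tibble(df),
            class = c("colitis_trajectory", class(tibble::tibble())))
}

test_that("binding probabilities normalize hand-computed weights", {
  # equal weights across all five channels -> 0.2 each
  p <- colitis_params(w0 = 2, gammaGpMIR = 2, gammaI17RMIR = 2,
                      gammaAxiMIR = 2, gammaLatMIR = 2)
  tr <- make_traj(list(time = 0, Gp130 = 1, IL17RA = 1, Axin1 = 1,
                       Lats12 = 1, MIR31 = 1))
  pr <- binding_probabilities(tr, p)
  expect_equal(unlist(pr[1, c("p0", "p1", "p2", "p3", "p4")]),
               c(p0 = 0.2, p1 = 0.2, p2 = 0.2, p3 = 0.2, p4 = 0.2))
  # weights (1, 2, 3, 4, 0) -> probabilities (0.1, 0.2, 0.3, 0.4, 0)
  p2 <- colitis_params(w0 = 1, gammaGpMIR = 2, gammaI17RMIR = 3,
                       gammaAxiMIR = 4, gammaLatMIR = 5)
  tr2 <- make_traj(list(time = 0, Gp130 = 1, IL17RA = 1, Axin1 = 1,
                        Lats12 = 0, MIR31 = 1))
  pr2 <- binding_probabilities(tr2, p2)
  expect_equal(unlist(pr2[1, c("p0", "p1", "p2", "p3", "p4")]),
               c(p0 = 0.1, p1 = 0.2, p2 = 0.3, p3 = 0.4, p4 = 0),
               tolerance = 1e-12)
})

test_that("probabilities sum to one and strengths conserve MIR31 pointwise", {
  p <- default_params()
  traj <- wt_traj()
  pr <- binding_probabilities(traj, p)
  sums <- pr$p0 + pr$p1 + pr$p2 + pr$p3 + pr$p4
  expect_lt(max(abs(sums - 1)), 1e-9)
  expect_true(all(as.matrix(pr[, c("p0", "p1", "p2", "p3", "p4")]) >= 0))
  fs <- action_strengths(traj, pr)
  expect_lt(max(abs(fs$F0 + fs$F1 + fs$F2 - traj$MIR31)), 1e-9)
})

test_that("action strengths follow the probability split arithmetically", {
  pr <- tibble::tibble(time = c(0, 1), p0 = c(0.4, 0.4),
                       p_inh = c(0.6, 0.6), p_reg = c(0, 0))
  tr <- make_traj(list(time = c(0, 1), MIR31 = c(2, 0)))
  fs <- action_strengths(tr, pr)
  expect_equal(fs$F1, c(1.2, 0))
  expect_equal(fs$F0, c(0.8, 0))
  expect_error(action_strengths(tr, dplyr::mutate(pr, time = c(0, 2))),
               "grids differ")
})

test_that("intersection finder locates constructed crossings", {
  t <- seq(0, 15, by = 0.01)
  # difference changes sign at exactly 2.5 and 9.0
  diff_curve <- -(t - 2.5) * (t - 9.0) / 50
  p_reg <- rep(0.5, length(t))
  p_inh <- p_reg + diff_curve
  res <- find_intersections(p_inh, p_reg, t)
  expect_equal(res$D1, 2.5, tolerance = 0.01)
  expect_equal(res$D2, 9.0, tolerance = 0.01)

  none <- find_intersections(p_reg - 0.1, p_reg, t)
  expect_true(is.na(none$D1) && is.na(none$D2))
  expect_length(none$crossings, 0)

  expect_warning(res3 <- find_intersections(0.5 + 0.1 * sin(2 * t), p_reg, t),
                 "More than two")
  expect_gt(length(res3$crossings), 2)
})

test_that("at the healthy baseline MIR31 mainly promotes regeneration", {
  p <- default_params()
  pr <- binding_probabilities(wt_traj(), p)
  expect_gt(pr$p_reg[1], pr$p_inh[1])
})

test_that("bisection recovers an analytically known onset", {
  got <- mir31colitis:::bisect_threshold(function(x) x > 1.234, 0, 5,
                                         tol = 0.001, "none")
  expect_equal(got, 1.234, tolerance = 0.001)
  expect_warning(
    na <- mir31colitis:::bisect_threshold(function(x) FALSE, 0, 5, 0.01,
                                          "impossible"),
    "impossible")
  expect_true(is.na(na))
})

test_that("threshold finders bracket their decision boundary", {
  p <- default_params()
  prot <- default_protocol()
  dstar <- threshold_no_intersection(p, prot, tol = 0.02)
  below <- competition_profile(p, dose_protocol(dstar - 0.05, horizon = 15))
  above <- competition_profile(p, dose_protocol(dstar + 0.05, horizon = 15))
  expect_true(is.na(below$D1))
  expect_false(is.na(above$D1))

  # degenerate receptors: inhibition can never dominate
  pdeg <- colitis_params(gammaGpMIR = 0, gammaI17RMIR = 0)
  expect_warning(sw <- threshold_function_switch(pdeg, prot, tol = 0.1),
                 "never dominates")
  expect_true(is.na(sw))
})

test_that("dose sweep reproduces the concentration-dependence trends", {
  p <- default_params()
  sweep <- dss_sweep(p, conc_grid = c(0, 1, 2, 3, 3.5))
  expect_false(any(sweep$failed))
  # no DSS: no intersections, cell number and MIR31 stay at baseline
  at0 <- sweep[sweep$dss_conc == 0, ]
  expect_true(is.na(at0$D1) && is.na(at0$D2))
  base <- baseline_state(p, "WT")
  expect_equal(at0$min_N, unname(base["N"]), tolerance = 1e-4)
  expect_equal(at0$peak_MIR31, unname(base["MIR31"]), tolerance = 1e-3)
  # inflammation and MIR31 induction grow with dose, cell damage deepens
  expect_true(all(diff(sweep$peak_MIR31) >= -1e-9))
  expect_true(all(diff(sweep$peak_IL1b) >= -1e-9))
  expect_true(all(diff(sweep$min_N) <= 1e-9))
  # action strengths grow with dose while the regeneration probability at the
  # F2 peak declines (strength and probability move in opposite directions);
  # the probability decline is monotone up to a sub-1% numerical ripple
  expect_true(all(diff(sweep$max_F1) >= -1e-9))
  expect_true(all(diff(sweep$max_F2) >= -1e-9))
  expect_true(all(diff(sweep$p_reg_at_f2max) <= 0.01))
  expect_lt(sweep$p_reg_at_f2max[nrow(sweep)], sweep$p_reg_at_f2max[1] - 0.1)
})
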
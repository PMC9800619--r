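#' Binding weights of MIR31 across its targets
#'
#' Mass-action-style propensities for MIR31's allocation: `w_i = gamma_i *
#' [Target_i]` for the four targets (Gp130, IL17RA, Axin1, Lats1/2, in that
#' order), plus the constant resting-state weight `w0`.
#'
#' @param state Named species state vector (or one-row trajectory slice).
#' @param params A [colitis_params()].
#' @return Named numeric vector `c(w0, w1, w2, w3, w4)`.
#' @export
binding_weights <- function(state, params) {
  stopifnot(inherits(params, "colitis_params"))
  if (any(state < 0)) stop("State must be non-negative.", call. = FALSE)
  c(w0 = params$w0,
    w1 = params$gammaGpMIR * state[["Gp130"]],
    w2 = params$gammaI17RMIR * state[["IL17RA"]],
    w3 = params$gammaAxiMIR * state[["Axin1"]],
    w4 = params$gammaLatMIR * state[["Lats12"]])
}

#' Time-resolved MIR31 binding probabilities
#'
#' Normalizes the binding weights pointwise along a trajectory:
#' `p_i(t) = w_i(t) / sum_j w_j(t)`.  `p1 + p2` is the probability that MIR31
#' acts to inhibit inflammation (receptor targets), `p3 + p4` that it acts to
#' promote regeneration (WNT/Hippo targets), and `p0` the resting share.
#'
#' @param traj A wild-type `colitis_trajectory`.
#' @param params A [colitis_params()].
#' @return Tibble with columns `time`, `p0`..`p4`, `p_inh` (= p1 + p2) and
#'   `p_reg` (= p3 + p4); rows sum to one exactly.
#' @export
binding_probabilities <- function(traj, params) {
  stopifnot(inherits(traj, "colitis_trajectory"),
            inherits(params, "colitis_params"))
  w <- tibble::tibble(
    w0 = params$w0,
    w1 = params$gammaGpMIR * traj$Gp130,
    w2 = params$gammaI17RMIR * traj$IL17RA,
    w3 = params$gammaAxiMIR * traj$Axin1,
    w4 = params$gammaLatMIR * traj$Lats12
  )
  tot <- rowSums(w)
  if (any(tot <= 0)) {
    stop("All binding weights are zero at some time point; probabilities undefined.",
         call. = FALSE)
  }
  p <- w / tot
  names(p) <- c("p0", "p1", "p2", "p3", "p4")
  dplyr::bind_cols(tibble::tibble(time = traj$time), tibble::as_tibble(p)) |>
    dplyr::mutate(p_inh = .data$p1 + .data$p2, p_reg = .data$p3 + .data$p4)
}

#' MIR31 action strengths
#'
#' Apportions the MIR31 concentration by binding probability:
#' `F0 = [MIR31] * p0` (resting), `F1 = [MIR31] * (p1 + p2)` (inflammation
#' inhibition), `F2 = [MIR31] * (p3 + p4)` (regeneration promotion).  Their
#' sum `F = F0 + F1 + F2` equals the MIR31 concentration pointwise.
#'
#' @param traj A `colitis_trajectory`.
#' @param probs Binding probabilities from [binding_probabilities()] on the
#'   same time grid.
#' @return Tibble with columns `time`, `F0`, `F1`, `F2`, `F_total`.
#' @export
action_strengths <- function(traj, probs) {
  stopifnot(inherits(traj, "colitis_trajectory"))
  if (!isTRUE(all.equal(traj$time, probs$time))) {
    stop("Trajectory and probability grids differ.", call. = FALSE)
  }
  M <- traj$MIR31
  tibble::tibble(
    time = traj$time,
    F0 = M * probs$p0,
    F1 = M * probs$p_inh,
    F2 = M * probs$p_reg,
    F_total = M
  )
}

#' Intersection times of the two probability curves
#'
#' Locates sign changes of `p_inh - p_reg` along the grid by linear
#' interpolation.  `D1` is the first crossing, `D2` the last; when the curves
#' never cross both are `NA` (a valid outcome: at low DSS the regeneration
#' probability dominates throughout).  More than two crossings are reported
#' with a warning.
#'
#' @param p_inh,p_reg Aligned numeric series in `[0, 1]`.
#' @param time Time grid (days).
#' @return A list with elements `D1`, `D2` (days or `NA`) and `crossings`
#'   (all crossing times).
#' @export
find_intersections <- function(p_inh, p_reg, time) {
  stopifnot(length(p_inh) == length(p_reg), length(p_inh) == length(time))
  d <- p_inh - p_reg
  s <- sign(d)
  # treat exact zeros as crossings at the grid point
  idx <- which(s[-1] * s[-length(s)] < 0)
  crossings <- time[idx] + (time[idx + 1] - time[idx]) * d[idx] /
    (d[idx] - d[idx + 1])
  zeros <- time[s == 0 & dplyr::lag(s, default = 1) != 0]
  crossings <- sort(unique(c(crossings, zeros)))
  if (length(crossings) == 0) {
    return(list(D1 = NA_real_, D2 = NA_real_, crossings = numeric(0)))
  }
  if (length(crossings) > 2) {
    warning("More than two probability-curve crossings (", length(crossings),
            "); reporting first and last.", call. = FALSE)
  }
  list(D1 = crossings[1],
       D2 = if (length(crossings) >= 2) crossings[length(crossings)] else NA_real_,
       crossings = crossings)
}

#' Full competition profile of a simulation
#'
#' Bundles binding probabilities, action strengths and intersection times for
#' one protocol into a single object.
#'
#' @param params A [colitis_params()].
#' @param protocol A [dose_protocol()].
#' @param traj Optional precomputed wild-type trajectory.
#' @return A `competition_profile` list: `probabilities`, `strengths`,
#'   `D1`, `D2`, `f_max_time` (time of maximal total action strength),
#'   `protocol`.
#' @export
competition_profile <- function(params, protocol = dose_protocol(),
                                traj = NULL) {
  stopifnot(inherits(params, "colitis_params"))
  traj <- traj %||% simulate_colitis(params, protocol, "WT")
  probs <- binding_probabilities(traj, params)
  strengths <- action_strengths(traj, probs)
  cross <- find_intersections(probs$p_inh, probs$p_reg, probs$time)
  i_fmax <- which.max(strengths$F_total)
  i_f1max <- which.max(strengths$F1)
  i_f2max <- which.max(strengths$F2)
  structure(
    list(probabilities = probs, strengths = strengths,
         D1 = cross$D1, D2 = cross$D2, crossings = cross$crossings,
         f_max_time = strengths$time[i_fmax],
         p_inh_at_fmax = probs$p_inh[i_fmax],
         p_reg_at_fmax = probs$p_reg[i_fmax],
         f1_max = strengths$F1[i_f1max], f1_max_time = strengths$time[i_f1max],
         f2_max = strengths$F2[i_f2max], f2_max_time = strengths$time[i_f2max],
         p_inh_at_f1max = probs$p_inh[i_f1max],
         p_reg_at_f2max = probs$p_reg[i_f2max],
         protocol = protocol),
    class = "competition_profile"
  )
}

#' @export
print.competition_profile <- function(x, ...) {
  cat(sprintf(
    "<competition_profile> %.2f%% DSS: D1 = %s, D2 = %s, F max at day %.2f\n",
    x$protocol$dss_conc,
    ifelse(is.na(x$D1), "none", sprintf("%.2f d", x$D1)),
    ifelse(is.na(x$D2), "none", sprintf("%.2f d", x$D2)),
    x$f_max_time))
  invisible(x)
}

#' Sweep the DSS concentration
#'
#' Runs one full simulation plus competition evaluation per concentration and
#' summarizes each: peak MIR31 and IL1b, minimum N, intersections D1/D2,
#' maximal action strengths and the probability split at the F-max time.
#' Per-concentration failures are recorded and the sweep continues.
#'
#' @param params A [colitis_params()].
#' @param conc_grid Increasing DSS concentrations (% wt/vol); default 0 to 4
#'   in steps of 0.05.
#' @param protocol Template protocol supplying timing and washout; its
#'   `dss_conc` is replaced per grid point.
#' @return A `dss_sweep` tibble: one row per concentration with columns
#'   `dss_conc`, `peak_MIR31`, `peak_IL1b`, `min_N`, `D1`, `D2`, `max_F1`,
#'   `max_F2`, `f_max_time`, `p_inh_at_fmax`, `p_reg_at_fmax`, `failed`.
#' @export
dss_sweep <- function(params, conc_grid = seq(0, 4, by = 0.05),
                      protocol = dose_protocol()) {
  stopifnot(inherits(params, "colitis_params"))
  if (any(conc_grid < 0) || is.unsorted(conc_grid, strictly = TRUE)) {
    stop("`conc_grid` must be non-negative and strictly increasing.",
         call. = FALSE)
  }
  y0 <- baseline_state(params, "WT")
  rows <- purrr::map(conc_grid, function(conc) {
    res <- tryCatch({
      prot <- dose_protocol(conc, protocol$t_on, protocol$t_off,
                            protocol$washout_rate, protocol$horizon)
      traj <- simulate_colitis(params, prot, "WT", y0 = y0)
      prof <- competition_profile(params, prot, traj = traj)
      tibble::tibble(
        dss_conc = conc,
        peak_MIR31 = max(traj$MIR31),
        peak_IL1b = max(traj$IL1b),
        min_N = min(traj$N),
        D1 = prof$D1, D2 = prof$D2,
        max_F1 = prof$f1_max,
        max_F2 = prof$f2_max,
        f_max_time = prof$f_max_time,
        p_inh_at_fmax = prof$p_inh_at_fmax,
        p_reg_at_fmax = prof$p_reg_at_fmax,
        p_inh_at_f1max = prof$p_inh_at_f1max,
        p_reg_at_f2max = prof$p_reg_at_f2max,
        failed = FALSE
      )
    }, error = function(e) {
      tibble::tibble(dss_conc = conc, peak_MIR31 = NA_real_,
                     peak_IL1b = NA_real_, min_N = NA_real_, D1 = NA_real_,
                     D2 = NA_real_, max_F1 = NA_real_, max_F2 = NA_real_,
                     f_max_time = NA_real_, p_inh_at_fmax = NA_real_,
                     p_reg_at_fmax = NA_real_, p_inh_at_f1max = NA_real_,
                     p_reg_at_f2max = NA_real_, failed = TRUE)
    })
    res
  })
  out <- dplyr::bind_rows(rows)
  structure(out, class = c("dss_sweep", class(out)), params = params,
            protocol = protocol)
}

#' Lowest DSS concentration at which the probability curves intersect
#'
#' Bisects the DSS concentration on `[lower, upper]` for the smallest value
#' at which [find_intersections()] detects a crossing of the
#' inflammation-inhibition and regeneration-promotion probabilities.  Below
#' this threshold the regeneration probability dominates throughout and MIR31
#' acts chiefly as a regeneration promoter.
#'
#' @param params A [colitis_params()].
#' @param protocol Template protocol (timing/washout).
#' @param lower,upper Bracketing concentrations (% wt/vol), default `[0, 5]`.
#' @param tol Bisection tolerance (% wt/vol), default 0.01.
#' @return Threshold concentration (% wt/vol), or `NA` with a warning when no
#'   crossing exists anywhere on the bracket.
#' @export
threshold_no_intersection <- function(params, protocol = dose_protocol(),
                                      lower = 0, upper = 5, tol = 0.01) {
  has_crossing <- function(conc) {
    if (conc == 0) return(FALSE)
    prot <- dose_protocol(conc, protocol$t_on, protocol$t_off,
                          protocol$washout_rate, protocol$horizon)
    prof <- competition_profile(params, prot)
    !is.na(prof$D1)
  }
  bisect_threshold(has_crossing, lower, upper, tol,
                   "No probability-curve crossing at any concentration on the bracket.")
}

#' DSS concentration at which MIR31's major function switches
#'
#' Bisects for the smallest concentration above which the dominant role of
#' MIR31 — measured where its action is strongest — becomes inflammation
#' inhibition rather than regeneration promotion.  Two operationalizations of
#' "where its action is strongest" are available:
#'
#' * `"f1_f2_peaks"` (default): compare the inflammation-inhibition
#'   probability at the time its action strength `F1` peaks against the
#'   regeneration-promotion probability at the time `F2` peaks — the two
#'   maximal-action-strength working points of the dose-response analysis.
#' * `"total_f_max"`: compare both probabilities at the single time of
#'   maximal total action strength `F`.
#'
#' @inheritParams threshold_no_intersection
#' @param criterion Switch criterion, see Details.
#' @return Threshold concentration (% wt/vol), or `NA` with a warning.
#' @export
threshold_function_switch <- function(params, protocol = dose_protocol(),
                                      lower = 0, upper = 5, tol = 0.01,
                                      criterion = c("f1_f2_peaks",
                                                    "total_f_max")) {
  criterion <- match.arg(criterion)
  switched <- function(conc) {
    if (conc == 0) return(FALSE)
    prot <- dose_protocol(conc, protocol$t_on, protocol$t_off,
                          protocol$washout_rate, protocol$horizon)
    prof <- competition_profile(params, prot)
    if (criterion == "f1_f2_peaks") {
      prof$p_inh_at_f1max > prof$p_reg_at_f2max
    } else {
      prof$p_inh_at_fmax > prof$p_reg_at_fmax
    }
  }
  bisect_threshold(switched, lower, upper, tol,
                   "Inhibition never dominates at the maximal action strength on the bracket.")
}

# bisection for the smallest x in [lower, upper] with predicate(x) TRUE,
# assuming the predicate is monotone (FALSE below threshold, TRUE above)
bisect_threshold <- function(predicate, lower, upper, tol, none_msg) {
  if (!predicate(upper)) {
    warning(none_msg, call. = FALSE)
    return(NA_real_)
  }
  if (predicate(lower)) return(lower)
  lo <- lower; hi <- upper
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (predicate(mid)) hi <- mid else lo <- mid
  }
  (lo + hi) / 2
}

#' Export a competition profile to CSV
#'
#' @param profile A [competition_profile()].
#' @param path Output CSV path (probabilities and strengths, long format).
#' @return `path`, invisibly.
#' @export
write_competition <- function(profile, path) {
  stopifnot(inherits(profile, "competition_profile"))
  dplyr::left_join(profile$probabilities, profile$strengths, by = "time") |>
    readr::write_csv(path)
  invisible(path)
}
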
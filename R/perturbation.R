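#' Change ratio of the proliferative cell number
#'
#' The sensitivity measure of the scaling analysis:
#' `delta(t) = |N_lambda(t) - N(t)| / N(t)`, the pointwise relative shift in
#' the proliferative cell number between a perturbed and the reference
#' trajectory.
#'
#' @param base Reference `colitis_trajectory` (unperturbed wild type).
#' @param perturbed Perturbed trajectory on the same time grid.
#' @return Tibble with columns `time` and `delta`.
#' @export
change_ratio <- function(base, perturbed) {
  stopifnot(inherits(base, "colitis_trajectory"),
            inherits(perturbed, "colitis_trajectory"))
  if (!isTRUE(all.equal(base$time, perturbed$time))) {
    stop("Trajectories must share the same time grid.", call. = FALSE)
  }
  if (any(base$N <= 0)) {
    stop("Reference proliferative cell number must be > 0 everywhere.",
         call. = FALSE)
  }
  tibble::tibble(time = base$time,
                 delta = abs(perturbed$N - base$N) / base$N)
}

#' One-at-a-time parameter-scaling sensitivity scan
#'
#' For each parameter in `names` and each scaling factor in `lam_grid`, the
#' wild-type model is re-simulated with that single parameter multiplied by
#' lambda and the change ratio `delta(t)` of the proliferative cell number is
#' recorded over the full grid.  Perturbed runs start from the unperturbed
#' wild-type baseline steady state: the scaling emulates an acute intervention
#' on a healthy animal at day 0.
#'
#' Per-cell simulation failures are recorded (`failed = TRUE`, `delta = NA`)
#' and the scan continues.
#'
#' @param params Calibrated [colitis_params()].
#' @param names Parameters to scan (default: the six MIR31 couplings).
#' @param lam_grid Scaling factors; default 25 points log-uniform on
#'   `[0.01, 100]`.
#' @param protocol A [dose_protocol()].
#' @param eval_time Day at which the headline `delta` is reported (default 5,
#'   the end of treatment).
#' @param times Simulation grid (defaults to 0.01-day spacing).
#' @return A `sensitivity_scan` tibble with columns `parameter`, `lambda`,
#'   `time`, `delta`, `failed`; attribute `eval_time`; the per-cell value at
#'   `eval_time` is in attribute `summary` (tibble `parameter`, `lambda`,
#'   `delta_eval`).
#' @export
sensitivity_scan <- function(params, names = mir31_coupling_names(),
                             lam_grid = 10^seq(-2, 2, length.out = 25),
                             protocol = dose_protocol(), eval_time = 5,
                             times = NULL) {
  stopifnot(inherits(params, "colitis_params"))
  if (any(lam_grid <= 0)) stop("`lam_grid` must be positive.", call. = FALSE)
  if (is.null(times)) times <- seq(0, protocol$horizon, by = 0.01)
  if (!any(abs(times - eval_time) < 1e-9)) {
    times <- sort(unique(c(times, eval_time)))
  }

  y0 <- baseline_state(params, "WT")
  base <- simulate_colitis(params, protocol, "WT", times = times, y0 = y0)

  cells <- tidyr::expand_grid(parameter = names, lambda = lam_grid)
  rows <- purrr::pmap(cells, function(parameter, lambda) {
    pert <- tryCatch(
      simulate_colitis(scale_parameter(params, parameter, lambda),
                       protocol, "WT", times = times, y0 = y0),
      error = function(e) NULL
    )
    if (is.null(pert)) {
      tibble::tibble(parameter = parameter, lambda = lambda,
                     time = times, delta = NA_real_, failed = TRUE)
    } else {
      cr <- change_ratio(base, pert)
      tibble::tibble(parameter = parameter, lambda = lambda,
                     time = cr$time, delta = cr$delta, failed = FALSE)
    }
  })
  scan <- dplyr::bind_rows(rows)

  summary <- scan |>
    dplyr::filter(abs(.data$time - eval_time) < 1e-9) |>
    dplyr::transmute(parameter = .data$parameter, lambda = .data$lambda,
                     delta_eval = .data$delta)

  structure(scan,
            class = c("sensitivity_scan", class(scan)),
            eval_time = eval_time, summary = summary,
            base = base, params = params, protocol = protocol)
}

#' Headline sensitivity summary at the evaluation time
#'
#' @param scan A [sensitivity_scan()] result.
#' @return Tibble `parameter`, `lambda`, `delta_eval`.
#' @export
sensitivity_summary <- function(scan) {
  stopifnot(inherits(scan, "sensitivity_scan"))
  attr(scan, "summary")
}

#' Wild-type versus MIR31-knockout comparison
#'
#' Simulates both genotypes under the same protocol (each from its own
#' untreated steady state), normalizes the observables to the wild-type
#' maxima, and summarizes the knockout phenotype: peak p-p65 and p-STAT3,
#' minimum proliferative cell number, and the time N takes to recover to
#' `recovery_frac` of its baseline after its minimum.
#'
#' @param params Calibrated [colitis_params()].
#' @param protocol A [dose_protocol()].
#' @param recovery_frac Recovery threshold as a fraction of baseline N
#'   (default 0.9).
#' @param times Simulation grid.
#' @return A list of class `ko_comparison`: `observables` (long tibble over
#'   both genotypes, WT-normalized), `metrics` (tibble `genotype`,
#'   `peak_pP65`, `peak_pSTAT3`, `min_N`, `recovery_time`), and the two
#'   trajectories `wt`, `ko`.
#' @export
ko_comparison <- function(params, protocol = dose_protocol(),
                          recovery_frac = 0.9, times = NULL) {
  stopifnot(inherits(params, "colitis_params"))
  wt <- simulate_colitis(params, protocol, "WT", times = times)
  ko <- simulate_colitis(params, protocol, "KO", times = times)

  # normalize both genotypes to the wild-type maxima; a species that is
  # identically zero in the wild type (degenerate zero-coupling model) is
  # reported unscaled rather than failing normalization
  maxima <- purrr::map_dbl(c(MIR31 = "MIR31", pP65 = "pP65",
                             pSTAT3 = "pSTAT3", N = "N"), ~ max(wt[[.x]]))
  norm_obs <- function(traj, genotype) {
    purrr::map_dfr(names(maxima), function(o) {
      tibble::tibble(
        time = traj$time, observable = o,
        value = if (maxima[[o]] > 0) traj[[o]] / maxima[[o]] else traj[[o]],
        genotype = genotype
      )
    })
  }
  obs <- dplyr::bind_rows(norm_obs(wt, "WT"), norm_obs(ko, "KO"))

  metric_row <- function(traj, genotype) {
    baseN <- traj$N[1]
    i_min <- which.min(traj$N)
    after <- traj[traj$time >= traj$time[i_min], ]
    rec <- after$time[after$N >= recovery_frac * baseN][1]
    tibble::tibble(
      genotype = genotype,
      peak_pP65 = max(traj$pP65),
      peak_pSTAT3 = max(traj$pSTAT3),
      min_N = min(traj$N),
      baseline_N = baseN,
      recovery_time = rec %||% NA_real_
    )
  }
  metrics <- dplyr::bind_rows(metric_row(wt, "WT"), metric_row(ko, "KO"))

  structure(list(observables = obs, metrics = metrics, wt = wt, ko = ko),
            class = "ko_comparison")
}

#' @export
print.ko_comparison <- function(x, ...) {
  cat("<ko_comparison>\n")
  print(x$metrics)
  invisible(x)
}

#' Export a sensitivity scan to long-format CSV
#'
#' @param scan A [sensitivity_scan()] result.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_sensitivity <- function(scan, path) {
  stopifnot(inherits(scan, "sensitivity_scan"))
  tibble::as_tibble(scan) |>
    dplyr::transmute(parameter = .data$parameter, lambda = .data$lambda,
                     time_days = .data$time, delta = .data$delta) |>
    readr::write_csv(path)
  invisible(path)
}
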
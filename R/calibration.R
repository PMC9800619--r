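#' Calibration loss for a candidate parameter set
#'
#' Simulates the wild-type model under `protocol`, evaluates the four
#' observables at the observation time points, normalizes model and data with
#' the same convention (each observable divided by the maximum of its
#' replicate means across time points), and returns the sum over observables
#' and time points of squared deviations between the normalized model curve
#' and the normalized replicate means.  Observables are equally weighted:
#' after max-normalization all four live on a comparable scale.
#'
#' Integration failures do not propagate: they return a large penalty value
#' (`1e6`) with attribute `failed = TRUE` so multi-start optimization can
#' continue.
#'
#' @param params Candidate [colitis_params()].
#' @param obs An `observation_set` (see [generate_observations()]).
#' @param protocol A [dose_protocol()]; defaults to the protocol recorded in
#'   `obs`, if any.
#' @return Scalar loss (non-negative).
#' @export
calibration_objective <- function(params, obs, protocol = NULL) {
  stopifnot(inherits(params, "colitis_params"),
            inherits(obs, "observation_set"))
  protocol <- protocol %||% attr(obs, "protocol") %||% dose_protocol()
  if (nrow(obs) == 0) {
    warning("Empty observation set: objective is vacuously 0.", call. = FALSE)
    return(0)
  }
  known <- c("MIR31", "pP65", "pSTAT3", "N")
  bad <- setdiff(unique(obs$observable), known)
  if (length(bad)) {
    stop("Observation set contains observable(s) unknown to the model: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }

  means <- obs |>
    dplyr::summarise(data_mean = mean(.data$value),
                     .by = c("observable", "time_days"))
  objective_core(params, means, protocol)
}

# hot path shared by calibration_objective() and fit_colitis(): `means` is the
# pre-aggregated tibble of replicate means (observable, time_days, data_mean)
objective_core <- function(params, means, protocol) {
  tp <- sort(unique(means$time_days))
  traj <- tryCatch(
    simulate_colitis(params, protocol, genotype = "WT", times = tp),
    error = function(e) NULL
  )
  if (is.null(traj)) {
    return(structure(1e6, failed = TRUE))
  }
  loss <- 0
  for (o in unique(means$observable)) {
    mod <- traj[[o]][match(means$time_days[means$observable == o], traj$time)]
    mx <- max(traj[[o]])
    if (mx <= 0) return(structure(1e6, failed = TRUE))
    loss <- loss + sum((mod / mx - means$data_mean[means$observable == o])^2)
  }
  loss
}

#' Fit model parameters by bounded multi-start optimization
#'
#' Reproduces the calibration procedure: starting points for the free
#' parameters are drawn log-uniformly within their bounds (seeded, so the fit
#' is deterministic), each start is refined by bounded quasi-Newton
#' least-squares minimization of [calibration_objective()] in log-parameter
#' space, and the best converged start wins.
#'
#' Only the parameters named in `free` are estimated; all others are fixed at
#' their values in `init`.  By default the six MIR31 coupling parameters are
#' free — the quantities the knockout and sensitivity analyses depend on.
#'
#' @param obs An `observation_set`.
#' @param free Character vector of parameter names to estimate.
#' @param init Fixed values for the non-free parameters (default
#'   [colitis_params()]).
#' @param bounds Tibble with columns `parameter`, `lower`, `upper`
#'   (default [param_bounds()] restricted to `free`).
#' @param n_starts Number of random starts (>= 1).
#' @param seed Integer seed for start sampling.
#' @param protocol Dosing protocol (defaults to the one recorded in `obs`).
#' @param include_init If `TRUE`, `init`'s own values are used as one
#'   additional start.
#' @param control Passed to [stats::nlminb()] (e.g. `iter.max`).
#' @return A `colitis_fit` object: list with `best_params`
#'   (`colitis_params`), `objective_value`, `n_starts`, `starts` (per-start
#'   tibble: start id, seed-drawn initial values, converged flag, objective),
#'   `bounds`, `free`, `seed`.
#' @export
fit_colitis <- function(obs, free = mir31_coupling_names(),
                        init = colitis_params(), bounds = NULL,
                        n_starts = 10, seed = 1L, protocol = NULL,
                        include_init = FALSE,
                        control = list(iter.max = 150, eval.max = 300,
                                       rel.tol = 1e-7)) {
  stopifnot(inherits(obs, "observation_set"), n_starts >= 1)
  protocol <- protocol %||% attr(obs, "protocol") %||% dose_protocol()
  bounds <- bounds %||% param_bounds(init, names = free)
  bounds <- bounds[match(free, bounds$parameter), ]
  if (anyNA(bounds$lower) || any(!is.finite(c(bounds$lower, bounds$upper)))) {
    stop("Bounds must be finite for every free parameter.", call. = FALSE)
  }

  make_params <- function(theta_log) {
    vals <- as.list(exp(theta_log))
    names(vals) <- free
    p <- init
    p[free] <- vals
    validate_params(p)
  }
  means <- tibble::as_tibble(obs) |>
    dplyr::summarise(data_mean = mean(.data$value),
                     .by = c("observable", "time_days"))
  obj_log <- function(theta_log) {
    as.numeric(objective_core(make_params(theta_log), means, protocol))
  }

  lo <- log(bounds$lower); hi <- log(bounds$upper)
  # one contiguous block of draws per start, so a longer run extends the
  # shorter run's start list (monotone improvement in n_starts)
  starts_mat <- withr::with_seed(seed, {
    do.call(rbind, purrr::map(seq_len(n_starts), function(i) {
      stats::runif(length(free), lo, hi)
    }))
  })
  if (include_init) {
    theta0 <- pmin(pmax(log(unlist(init[free])), lo), hi)
    starts_mat <- rbind(starts_mat, theta0)
  }

  runs <- purrr::map(seq_len(nrow(starts_mat)), function(i) {
    res <- tryCatch(
      stats::nlminb(starts_mat[i, ], obj_log, lower = lo, upper = hi,
                    control = control),
      error = function(e) NULL
    )
    if (is.null(res)) {
      list(objective = Inf, converged = FALSE, par = starts_mat[i, ])
    } else {
      list(objective = res$objective, converged = res$convergence == 0,
           par = res$par)
    }
  })

  objectives <- purrr::map_dbl(runs, "objective")
  best <- which.min(objectives)
  starts_tbl <- tibble::tibble(
    start = seq_along(runs),
    objective = objectives,
    converged = purrr::map_lgl(runs, "converged")
  )

  structure(
    list(
      best_params = make_params(runs[[best]]$par),
      objective_value = objectives[best],
      n_starts = nrow(starts_mat),
      starts = starts_tbl,
      bounds = bounds,
      free = free,
      seed = seed,
      protocol = protocol
    ),
    class = "colitis_fit"
  )
}

#' Per-parameter recovery report
#'
#' Compares a fitted parameter set against the ground truth used to generate
#' the data: returns fitted/truth ratios and log2 ratios, flagging parameters
#' whose ratio falls outside `[0.5, 2]`.
#'
#' @param truth,fitted `colitis_params` objects with the same schema.
#' @param names Optional subset of parameters to report (default: all).
#' @return Tibble with columns `parameter`, `truth`, `fitted`, `ratio`,
#'   `log2_ratio`, `flagged`.
#' @export
parameter_recovery_report <- function(truth, fitted, names = NULL) {
  stopifnot(inherits(truth, "colitis_params"),
            inherits(fitted, "colitis_params"))
  if (!identical(sort(base::names(truth)), sort(base::names(fitted)))) {
    stop("Parameter schemas differ between `truth` and `fitted`.",
         call. = FALSE)
  }
  nm <- names %||% base::names(truth)
  unknown <- setdiff(nm, base::names(truth))
  if (length(unknown)) {
    stop("Unknown parameter(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  tibble::tibble(
    parameter = nm,
    truth = purrr::map_dbl(nm, ~ truth[[.x]]),
    fitted = purrr::map_dbl(nm, ~ fitted[[.x]])
  ) |>
    dplyr::mutate(
      ratio = .data$fitted / .data$truth,
      log2_ratio = log2(.data$ratio),
      flagged = .data$ratio < 0.5 | .data$ratio > 2
    )
}

#' @export
print.colitis_fit <- function(x, ...) {
  cat(sprintf(
    "<colitis_fit> %d free parameter(s), %d start(s), best objective %.4g\n",
    length(x$free), x$n_starts, x$objective_value))
  invisible(x)
}

#' Tidy and glance methods for calibration results
#'
#' `tidy()` returns one row per free parameter (estimate and bounds);
#' `glance()` returns a one-row model summary.
#'
#' @param x A `colitis_fit`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.colitis_fit <- function(x, ...) {
  tibble::tibble(
    parameter = x$free,
    estimate = purrr::map_dbl(x$free, ~ x$best_params[[.x]]),
    lower = x$bounds$lower,
    upper = x$bounds$upper
  )
}

#' @rdname tidy.colitis_fit
#' @export
glance.colitis_fit <- function(x, ...) {
  tibble::tibble(
    objective = x$objective_value,
    n_starts = x$n_starts,
    n_converged = sum(x$starts$converged),
    n_free = length(x$free),
    seed = x$seed
  )
}

#' Serialize a calibration result to JSON
#'
#' @param fit A `colitis_fit`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_fit <- function(fit, path) {
  stopifnot(inherits(fit, "colitis_fit"))
  out <- list(
    best_params = as.list(unclass(fit$best_params)),
    objective_value = fit$objective_value,
    n_starts = fit$n_starts,
    seed = fit$seed,
    free = fit$free,
    bounds = as.list(fit$bounds),
    starts = as.list(fit$starts)
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
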
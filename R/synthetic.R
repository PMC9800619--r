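#' Generate synthetic replicate observations
#'
#' Emulates the structure of the quantified mouse time-course measurements:
#' the wild-type model is simulated, the four observables (MIR31, p-p65,
#' p-STAT3, N) are evaluated at the requested time points, multiplicative
#' Gaussian noise `value * (1 + eps)` with `eps ~ N(0, noise_sd^2)` (truncated
#' at zero) is applied per replicate, and each observable is normalized by the
#' maximum of its replicate means across time points — the same convention as
#' the published summary bars.  Deterministic given `seed`.
#'
#' @param params Ground-truth [colitis_params()].
#' @param protocol A [dose_protocol()].
#' @param timepoints Observation days within `[0, horizon]`; the default grid
#'   `{0, 1, 3, 5, 6, 8, 10, 13}` brackets treatment, withdrawal and recovery.
#' @param n_replicates Replicates per time point (default 3, as in the
#'   experimental panels; the MIR31 panel used 4).
#' @param noise_sd Replicate coefficient of variation (default 0.1).
#' @param seed Integer seed.
#' @return An `observation_set` tibble with columns `observable`, `time_days`,
#'   `replicate`, `value`, and metadata attributes (`n_replicates`,
#'   `noise_sd`, `seed`, `normalization`, `protocol`).
#' @export
generate_observations <- function(params, protocol = dose_protocol(),
                                  timepoints = c(0, 1, 3, 5, 6, 8, 10, 13),
                                  n_replicates = 3, noise_sd = 0.1,
                                  seed = 1L) {
  stopifnot(inherits(params, "colitis_params"),
            inherits(protocol, "dose_protocol"))
  if (any(timepoints < 0) || any(timepoints > protocol$horizon)) {
    stop("`timepoints` must lie within [0, horizon].", call. = FALSE)
  }
  if (n_replicates < 1) stop("`n_replicates` must be >= 1.", call. = FALSE)
  if (noise_sd < 0) stop("`noise_sd` must be >= 0.", call. = FALSE)
  timepoints <- sort(unique(timepoints))

  traj <- simulate_colitis(params, protocol, genotype = "WT",
                           times = timepoints)
  truth <- tibble::as_tibble(traj)[, c("time", "MIR31", "pP65", "pSTAT3", "N")] |>
    tidyr::pivot_longer(-"time", names_to = "observable",
                        values_to = "truth") |>
    dplyr::rename(time_days = "time")

  obs <- withr::with_seed(seed, {
    tidyr::expand_grid(truth, replicate = seq_len(n_replicates)) |>
      dplyr::mutate(
        value = pmax(0, .data$truth * (1 + stats::rnorm(dplyr::n(), 0, noise_sd)))
      )
  })

  # normalize each observable by the max over time points of its replicate mean
  norm <- obs |>
    dplyr::summarise(mean_value = mean(.data$value),
                     .by = c("observable", "time_days")) |>
    dplyr::summarise(max_mean = max(.data$mean_value), .by = "observable")
  obs <- obs |>
    dplyr::left_join(norm, by = "observable") |>
    dplyr::transmute(
      observable = .data$observable,
      time_days = .data$time_days,
      replicate = .data$replicate,
      value = .data$value / .data$max_mean
    ) |>
    dplyr::arrange(.data$observable, .data$time_days, .data$replicate)

  structure(obs,
            class = c("observation_set", class(obs)),
            n_replicates = n_replicates, noise_sd = noise_sd, seed = seed,
            normalization = "max of replicate means per observable",
            protocol = protocol)
}

#' Noiseless reference waveforms of the four observables
#'
#' Parametric target curves carrying the qualitative anchors of the quantified
#' experimental panels under a given protocol: MIR31, p-p65 and p-STAT3 rise
#' from baseline, peak at the end of treatment and relax back to baseline
#' (adaptation); the proliferative cell count N falls monotonically during
#' treatment, reaches its minimum at withdrawal, and recovers by the horizon.
#' These curves serve as calibration targets when no measurements are
#' available.
#'
#' Each adaptation curve is `base + amp * g(t)` with `g` a smooth rise on
#' `[t_on, t_off]` (peaking at 1 at `t_off`) and an exponential relaxation
#' afterwards; N is `1 - depth * g_N(t)` with the mirrored shape.  Amplitudes
#' scale with the Hill-saturated DSS concentration so low doses produce
#' proportionally flat curves.
#'
#' @param protocol A [dose_protocol()].
#' @param times Evaluation grid (defaults to 0.01-day spacing).
#' @return Tibble with columns `time`, `observable`, `value` (normalized to
#'   the curve maximum).
#' @export
reference_waveforms <- function(protocol = dose_protocol(), times = NULL) {
  stopifnot(inherits(protocol, "dose_protocol"))
  if (is.null(times)) times <- seq(0, protocol$horizon, by = 0.01)
  t_on <- protocol$t_on; t_off <- protocol$t_off
  dur <- t_off - t_on
  # dose scaling saturating at high % wt/vol
  dose <- protocol$dss_conc^2 / (2.5^2 + protocol$dss_conc^2)

  rise <- function(t, tau) {
    # smooth 0 -> 1 ramp on [t_on, t_off], exponential relaxation after
    g <- numeric(length(t))
    up <- t >= t_on & t <= t_off
    g[up] <- (1 - exp(-(t[up] - t_on) / tau)) / (1 - exp(-dur / tau))
    g[t > t_off] <- exp(-(t[t > t_off] - t_off) / 1.5)
    g
  }

  curves <- list(
    MIR31  = function(t) 0.05 + 0.95 * dose * rise(t, tau = 2.5),
    pP65   = function(t) 0.10 + 0.90 * dose * rise(t, tau = 1.5),
    pSTAT3 = function(t) 0.10 + 0.90 * dose * rise(t, tau = 2.0),
    N      = function(t) 1 - 0.45 * dose * rise(t, tau = 3.0)
  )
  purrr::imap_dfr(curves, function(f, nm) {
    v <- f(times)
    tibble::tibble(time = times, observable = nm, value = v / max(v))
  })
}

#' Convert reference waveforms into an observation set
#'
#' Samples [reference_waveforms()] at discrete time points and formats the
#' result as a noiseless `observation_set`, so the calibration machinery can
#' fit the model to the published curve shapes directly.
#'
#' @inheritParams generate_observations
#' @return An `observation_set` tibble (single noiseless replicate).
#' @export
reference_observations <- function(protocol = dose_protocol(),
                                   timepoints = c(0, 1, 3, 5, 6, 8, 10, 13)) {
  wf <- reference_waveforms(protocol, times = timepoints)
  obs <- wf |>
    dplyr::transmute(observable = .data$observable,
                     time_days = .data$time,
                     replicate = 1L,
                     value = .data$value) |>
    dplyr::arrange(.data$observable, .data$time_days)
  # renormalize to the max over the sampled time points
  obs <- obs |>
    dplyr::mutate(value = .data$value / max(.data$value), .by = "observable")
  structure(obs,
            class = c("observation_set", class(obs)),
            n_replicates = 1L, noise_sd = 0, seed = NA_integer_,
            normalization = "max of replicate means per observable",
            protocol = protocol)
}

#' Read and write observation sets
#'
#' Observation sets round-trip through a tidy CSV (columns `observable`,
#' `time_days`, `replicate`, `value`) with a JSON sidecar (`<path>.json`)
#' holding the generation metadata.
#'
#' @param obs An `observation_set`.
#' @param path CSV file path.
#' @return `write_observations()` returns `path` invisibly;
#'   `read_observations()` returns an `observation_set`.
#' @export
write_observations <- function(obs, path) {
  stopifnot(inherits(obs, "observation_set"))
  readr::write_csv(tibble::as_tibble(obs), path)
  prot <- attr(obs, "protocol")
  meta <- list(
    n_replicates = attr(obs, "n_replicates"),
    noise_sd = attr(obs, "noise_sd"),
    seed = attr(obs, "seed"),
    normalization = attr(obs, "normalization"),
    protocol = prot[c("dss_conc", "t_on", "t_off", "washout_rate", "horizon")]
  )
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_observations
#' @export
read_observations <- function(path) {
  obs <- readr::read_csv(path, show_col_types = FALSE,
                         col_types = readr::cols(
                           observable = readr::col_character(),
                           time_days = readr::col_double(),
                           replicate = readr::col_integer(),
                           value = readr::col_double()
                         ))
  meta_path <- paste0(path, ".json")
  meta <- if (file.exists(meta_path)) jsonlite::read_json(meta_path) else list()
  prot <- meta$protocol
  structure(obs,
            class = c("observation_set", class(obs)),
            n_replicates = meta$n_replicates %||% NA_integer_,
            noise_sd = meta$noise_sd %||% NA_real_,
            seed = meta$seed %||% NA_integer_,
            normalization = meta$normalization %||% NA_character_,
            protocol = if (!is.null(prot)) {
              dose_protocol(prot$dss_conc, prot$t_on, prot$t_off,
                            prot$washout_rate, prot$horizon)
            } else NULL)
}
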
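#' Assemble a run configuration
#'
#' A configuration bundles everything a reproducible analysis run needs: the
#' dosing protocol, the model parameterization and genotype, the stages to
#' execute, the output directory and the global seed.  All randomness in a run
#' flows from the single seed.
#'
#' @param protocol A [dose_protocol()].
#' @param params A [colitis_params()], or a path to a parameter YAML file.
#' @param genotype `"WT"` or `"KO"` (used by the `simulate` stage).
#' @param stages Character vector drawn from `"simulate"`, `"generate-data"`,
#'   `"fit"`, `"ko"`, `"sensitivity"`, `"competition"`, `"sweep"`,
#'   `"landmarks"` (the one-run table of intersection times, dose thresholds
#'   and the maximal-action-strength time).
#' @param out_dir Output directory for artifacts.
#' @param seed Global integer seed.
#' @param n_starts Multi-start count for the `fit` stage.
#' @param lam_grid Scaling factors for the `sensitivity` stage.
#' @param conc_grid Concentrations for the `sweep` stage.
#' @return A `run_config` list.
#' @export
colitis_config <- function(protocol = dose_protocol(),
                           params = colitis_params(),
                           genotype = "WT",
                           stages = "simulate",
                           out_dir = tempfile("colitis_run_"),
                           seed = 1L,
                           n_starts = 10,
                           lam_grid = 10^seq(-2, 2, length.out = 25),
                           conc_grid = seq(0, 4, by = 0.05)) {
  if (is.character(params)) params <- read_params(params)
  structure(
    list(protocol = protocol, params = params, genotype = genotype,
         stages = stages, out_dir = out_dir, seed = as.integer(seed),
         n_starts = n_starts, lam_grid = lam_grid, conc_grid = conc_grid),
    class = "run_config"
  )
}

#' Validate a run configuration
#'
#' Checks every configuration invariant and returns the violations as a
#' character vector of messages (empty when the configuration is valid); it
#' never throws.
#'
#' @param config A [colitis_config()] (or plain list with the same fields).
#' @return Character vector of violation messages; `character(0)` if valid.
#' @export
validate_config <- function(config) {
  v <- character(0)
  p <- config$protocol
  if (!inherits(p, "dose_protocol")) {
    pl <- tryCatch(
      do.call(dose_protocol, p[c("dss_conc", "t_on", "t_off",
                                 "washout_rate", "horizon")]),
      error = function(e) conditionMessage(e))
    if (is.character(pl)) v <- c(v, paste0("protocol: ", pl)) else p <- pl
  }
  if (inherits(p, "dose_protocol")) {
    if (p$dss_conc < 0) v <- c(v, "protocol$dss_conc: must be >= 0")
    if (!(p$t_on < p$t_off)) v <- c(v, "protocol$t_off: requires t_on < t_off")
    if (p$t_off > p$horizon) v <- c(v, "protocol$t_off: must be <= horizon")
  }
  if (!inherits(config$params, "colitis_params")) {
    v <- c(v, "params: not a colitis_params object")
  }
  known <- c("simulate", "generate-data", "fit", "ko", "sensitivity",
             "competition", "sweep", "landmarks")
  bad <- setdiff(config$stages, known)
  if (length(bad)) {
    v <- c(v, paste0("stages: unknown stage(s) ", paste(bad, collapse = ", ")))
  }
  if (!config$genotype %in% c("WT", "KO")) {
    v <- c(v, "genotype: must be 'WT' or 'KO'")
  }
  if (!is.numeric(config$seed) || length(config$seed) != 1 ||
      is.na(config$seed)) {
    v <- c(v, "seed: must be a single integer")
  }
  v
}

#' Execute a configured analysis run
#'
#' Runs the requested stages in dependency order and writes plain CSV/JSON
#' artifacts plus a `manifest.json` recording the inputs, parameters, seed and
#' package version, so every artifact is reproducible from its manifest.
#' Identical configurations produce identical artifacts.
#'
#' @param config A validated [colitis_config()].
#' @return Invisibly, the manifest as a list (also written to
#'   `out_dir/manifest.json`).
#' @export
run_colitis <- function(config) {
  violations <- validate_config(config)
  if (length(violations)) {
    stop("Invalid configuration:\n  ",
         paste(violations, collapse = "\n  "), call. = FALSE)
  }
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  artifacts <- character(0)
  add <- function(name) artifacts <<- c(artifacts, name)
  out <- function(name) file.path(config$out_dir, name)
  # independent seed substreams per stage so stages reproduce in isolation
  stage_seed <- function(offset) (config$seed * 1000L + offset) %% .Machine$integer.max

  obs <- NULL
  if ("simulate" %in% config$stages || "competition" %in% config$stages) {
    traj <- simulate_colitis(config$params, config$protocol, config$genotype)
    readr::write_csv(trajectory_long(traj), out("trajectory.csv"))
    add("trajectory.csv")
  }
  if ("generate-data" %in% config$stages || "fit" %in% config$stages) {
    obs <- generate_observations(config$params, config$protocol,
                                 seed = stage_seed(1L))
    write_observations(obs, out("observations.csv"))
    add("observations.csv")
  }
  if ("fit" %in% config$stages) {
    fit <- fit_colitis(obs, n_starts = config$n_starts,
                       seed = stage_seed(2L), protocol = config$protocol)
    write_fit(fit, out("fit.json"))
    add("fit.json")
  }
  if ("ko" %in% config$stages) {
    koc <- ko_comparison(config$params, config$protocol)
    readr::write_csv(koc$metrics, out("ko_metrics.csv"))
    readr::write_csv(koc$observables, out("ko_observables.csv"))
    add("ko_metrics.csv"); add("ko_observables.csv")
  }
  if ("sensitivity" %in% config$stages) {
    scan <- sensitivity_scan(config$params, lam_grid = config$lam_grid,
                             protocol = config$protocol)
    write_sensitivity(scan, out("sensitivity.csv"))
    readr::write_csv(sensitivity_summary(scan), out("sensitivity_day5.csv"))
    add("sensitivity.csv"); add("sensitivity_day5.csv")
  }
  if ("competition" %in% config$stages) {
    prof <- competition_profile(config$params, config$protocol)
    write_competition(prof, out("competition.csv"))
    jsonlite::write_json(
      list(D1 = prof$D1, D2 = prof$D2, f_max_time = prof$f_max_time,
           p_inh_at_fmax = prof$p_inh_at_fmax,
           p_reg_at_fmax = prof$p_reg_at_fmax),
      out("competition_summary.json"), auto_unbox = TRUE, digits = NA)
    add("competition.csv"); add("competition_summary.json")
  }
  if ("landmarks" %in% config$stages) {
    prof <- competition_profile(config$params, config$protocol)
    landmarks <- tibble::tibble(
      quantity = c("D1_days", "D2_days", "no_intersection_threshold_pct",
                   "function_switch_threshold_pct", "f_max_time_days"),
      value = c(prof$D1, prof$D2,
                threshold_no_intersection(config$params, config$protocol),
                threshold_function_switch(config$params, config$protocol),
                prof$f_max_time)
    )
    readr::write_csv(landmarks, out("landmarks.csv"))
    add("landmarks.csv")
  }
  if ("sweep" %in% config$stages) {
    sweep <- dss_sweep(config$params, config$conc_grid, config$protocol)
    readr::write_csv(tibble::as_tibble(sweep), out("dss_sweep.csv"))
    add("dss_sweep.csv")
  }

  manifest <- list(
    package = "mir31colitis",
    version = as.character(utils::packageVersion("mir31colitis")),
    seed = config$seed,
    genotype = config$genotype,
    stages = config$stages,
    protocol = config$protocol[c("dss_conc", "t_on", "t_off",
                                 "washout_rate", "horizon")],
    params = as.list(unclass(config$params)),
    artifacts = artifacts
  )
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(manifest)
}
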
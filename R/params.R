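#' Model parameter set
#'
#' Constructs the full parameter set of the colitis network model.  The
#' defaults are the package's calibrated wild-type parameterization: they were
#' chosen within typical biological ranges and adjusted against the reference
#' waveforms (see [reference_waveforms()]) so that the simulated MIR31, p-p65,
#' p-STAT3 and proliferative-cell dynamics reproduce the published adaptation
#' behaviour under the standard 3.5% / 5-day protocol.  Any subset can be
#' overridden by name.
#'
#' Naming convention: `k*` are maximal production/activation rates (per day),
#' `l*` half-saturation constants (a.u.), `d*` first-order degradation rates
#' (per day), `gamma*` the four MIR31 inhibition strengths (dimensionless
#' multipliers on MIR31 inside the repressive Hill factor), `kMIRp65` /
#' `kMIRpST` the MIR31 induction rates, `w0` the resting-state binding weight
#' of the competition analysis, and `n` the shared Hill coefficient.
#'
#' @param ... Named parameter overrides, e.g. `colitis_params(gammaI17RMIR = 2)`.
#' @return An object of class `colitis_params`: a named list of scalars.
#' @examples
#' p <- colitis_params()
#' p$gammaI17RMIR
#' tidy(p)
#' @export
colitis_params <- function(...) {
  p <- default_param_values()
  dots <- list(...)
  if (length(dots)) {
    if (is.null(names(dots)) || any(names(dots) == "")) {
      stop("All parameter overrides must be named.", call. = FALSE)
    }
    unknown <- setdiff(names(dots), names(p))
    if (length(unknown)) {
      stop("Unknown parameter(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
    p[names(dots)] <- dots
  }
  validate_params(structure(p, class = "colitis_params"))
}

default_param_values <- function() {
  list(
    # shared Hill coefficient
    n = 2,
    # DSS -> cytokines (immune-cell release lumped into the forcing)
    kTD = 3.784,  lTD = 1.892, dTNF = 2,
    kI1D = 0.559, lI1D = 1.892, kI1P65 = 2.162, lI1P65 = 0.7, dIL1 = 1.5,
    kI6D = 1.135, lI6D = 1.892, kI6P65 = 1.2,   lI6P65 = 0.7, dIL6 = 1.5,
    # NF-kB module: TNFa and the IL17/IL17RA feedback activate p65
    kP650 = 0.1, kP65TNF = 1.432, lP65TNF = 0.8,
    kP65IL17 = 4.032, lP65IL17 = 1.021, lP65I17R = 0.7798, dP65 = 2.155,
    # STAT3 module: IL6 acting through Gp130, plus a weak IL1b route
    kST0 = 0.08, kSTIL6 = 1.374, lSTIL6 = 0.7, lSTGp = 0.5379,
    kSTIL1 = 0.1432, lSTIL1 = 0.7, dST = 0.8,
    # IL17 secretion downstream of p-STAT3
    kIL17ST = 2, lIL17ST = 0.7, dIL17 = 1.621,
    # MIR31 induction by p-p65 and p-STAT3
    kMIRp65 = 2.532, lMIRp65 = 0.8, kMIRpST = 0.488, lMIRpST = 0.8,
    dMIR = 4.5,
    # MIR31 targets: basal (MIR31-insensitive) + repressible synthesis
    kGp0 = 0.28,     kGp = 0.12,    lGpMIR = 1,   dGp = 0.4,
    kI17R0 = 0.03975, kI17R = 0.715, lI17RMIR = 1, dI17R = 0.7548,
    kAxi0 = 0.039,   kAxi = 1.261,  lAxiMIR = 1,  dAxi = 1.3,
    kLat0 = 0.0075,  kLat = 0.2425, lLatMIR = 1,  dLat = 0.25,
    # MIR31 inhibition strengths
    gammaGpMIR = 3.2, gammaI17RMIR = 2.007,
    gammaAxiMIR = 8,  gammaLatMIR = 2.5,
    # WNT / Hippo transducers
    kBcat = 2, lBcatAxi = 0.5, dBcat = 1,
    kYap = 2,  lYapLat = 0.5,  dYap = 1,
    # proliferative epithelial cells
    kProlif = 0.9365, lNBcat = 0.2, lNYap = 0.2,
    kDamage = 2.224, lNIL1 = 1.396,
    Nmax = 1.2, Nbase = 1, dN = 0.3759,
    # resting-state binding weight of the competition analysis
    w0 = 2
  )
}

validate_params <- function(p) {
  vals <- unlist(p)
  if (any(!is.finite(vals))) {
    stop("All parameters must be finite numbers.", call. = FALSE)
  }
  # basal activities and the MIR31 couplings may be exactly zero (the
  # knockout is the six-coupling zero limit of the wild type)
  allow_zero <- c("kP650", "kST0", mir31_coupling_names())
  bad <- names(vals)[vals <= 0 & !names(vals) %in% allow_zero]
  if (length(bad)) {
    stop("Parameters must be strictly positive: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  if (any(unlist(p[allow_zero]) < 0)) {
    stop("Basal rates kP650 and kST0 must be >= 0.", call. = FALSE)
  }
  if (p$n < 1) stop("Hill coefficient `n` must be >= 1.", call. = FALSE)
  p
}

#' MIR31 coupling parameter names
#'
#' The six parameters that couple MIR31 to the rest of the network: the four
#' inhibition strengths on its targets and the two induction rates.  These are
#' the parameters scanned in the sensitivity analysis; the knockout model is
#' equivalent to setting all six to zero.
#'
#' @return Character vector of parameter names.
#' @export
mir31_coupling_names <- function() {
  c("gammaGpMIR", "gammaI17RMIR", "gammaAxiMIR", "gammaLatMIR",
    "kMIRp65", "kMIRpST")
}

#' The three couplings with strong influence on the proliferative cell count
#' (MIR31 repression of IL17RA and the two MIR31 induction rates).
#' @rdname mir31_coupling_names
#' @export
sensitive_param_names <- function() {
  c("gammaI17RMIR", "kMIRp65", "kMIRpST")
}

#' Scale one parameter by a multiplicative factor
#'
#' The elementary move of the sensitivity analysis: returns a copy of `params`
#' with parameter `name` multiplied by `lam`, all others untouched.
#'
#' @param params A [colitis_params()] object.
#' @param name Parameter name to scale.
#' @param lam Positive scaling factor.
#' @return A new `colitis_params` object.
#' @export
scale_parameter <- function(params, name, lam) {
  stopifnot(inherits(params, "colitis_params"))
  if (!is.character(name) || length(name) != 1 || !name %in% names(params)) {
    stop("Unknown parameter name: ", name, call. = FALSE)
  }
  if (!is.numeric(lam) || length(lam) != 1 || !is.finite(lam) || lam <= 0) {
    stop("`lam` must be a single positive number.", call. = FALSE)
  }
  params[[name]] <- params[[name]] * lam
  validate_params(params)
}

#' Default calibration bounds per parameter
#'
#' Bounds reflect typical biological ranges by parameter type: rate-like
#' parameters (`k*`, `d*`) in `[1e-3, 1e2]` per day, half-saturations (`l*`)
#' in `[1e-2, 1e1]` a.u., inhibition strengths (`gamma*`) in `[1e-2, 1e2]`.
#'
#' @param params A `colitis_params` object (used for names and point values).
#' @param names Optional subset of parameter names.
#' @return A tibble with columns `parameter`, `value`, `lower`, `upper`.
#' @export
param_bounds <- function(params = colitis_params(), names = NULL) {
  stopifnot(inherits(params, "colitis_params"))
  nm <- names %||% base::names(params)
  unknown <- setdiff(nm, base::names(params))
  if (length(unknown)) {
    stop("Unknown parameter(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  lower <- purrr::map_dbl(nm, function(x) {
    if (grepl("^gamma", x)) 1e-2
    else if (grepl("^l", x)) 1e-2
    else if (x %in% c("n")) 1
    else if (x %in% c("Nmax", "Nbase", "w0")) 1e-2
    else 1e-3
  })
  upper <- purrr::map_dbl(nm, function(x) {
    if (grepl("^gamma", x)) 1e2
    else if (grepl("^l", x)) 1e1
    else if (x %in% c("n")) 4
    else if (x %in% c("Nmax", "Nbase", "w0")) 1e1
    else 1e2
  })
  tibble::tibble(
    parameter = nm,
    value = purrr::map_dbl(nm, ~ params[[.x]]),
    lower = lower,
    upper = upper
  )
}

#' @export
print.colitis_params <- function(x, ...) {
  cat(sprintf("<colitis_params> %d parameters (n = %g)\n", length(x), x$n))
  cat("MIR31 couplings: ",
      paste(sprintf("%s = %.3g", mir31_coupling_names(),
                    unlist(x[mir31_coupling_names()])), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Tidy a parameter set into a tibble
#'
#' @param x A `colitis_params` object.
#' @param ... Unused.
#' @return Tibble with columns `parameter`, `value`, `unit`, `lower`, `upper`
#'   (bounds from [param_bounds()]).
#' @export
tidy.colitis_params <- function(x, ...) {
  b <- param_bounds(x)
  b$unit <- purrr::map_chr(b$parameter, param_unit)
  b[, c("parameter", "value", "unit", "lower", "upper")]
}

param_unit <- function(name) {
  if (name == "n") "dimensionless"
  else if (grepl("^gamma", name)) "dimensionless"
  else if (grepl("^l", name)) "a.u."
  else if (name %in% c("Nmax", "Nbase", "w0")) "a.u."
  else "per day"
}

#' Read and write parameter files
#'
#' Parameters round-trip through a flat YAML file with one entry per
#' parameter, each carrying `value`, `unit`, `lower` and `upper` fields so
#' that externally tabulated parameter values can be dropped in verbatim.
#'
#' @param params A `colitis_params` object.
#' @param path File path.
#' @return `write_params()` returns `path` invisibly; `read_params()` returns
#'   a `colitis_params` object.
#' @export
write_params <- function(params, path) {
  stopifnot(inherits(params, "colitis_params"))
  td <- tidy.colitis_params(params)
  entries <- purrr::pmap(td, function(parameter, value, unit, lower, upper) {
    list(value = value, unit = unit, lower = lower, upper = upper)
  })
  names(entries) <- td$parameter
  yaml::write_yaml(entries, path)
  invisible(path)
}

#' @rdname write_params
#' @export
read_params <- function(path) {
  raw <- yaml::read_yaml(path)
  vals <- purrr::map(raw, function(x) if (is.list(x)) x$value else x)
  do.call(colitis_params, vals)
}
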
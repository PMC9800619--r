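species_names <- function() {
  c("TNFa", "IL1b", "IL6", "IL17", "pP65", "pSTAT3",
    "Gp130", "IL17RA", "MIR31", "Axin1", "Lats12",
    "bCatenin", "Yap", "N")
}

#' Build the ODE right-hand side for a genotype
#'
#' Assembles the 14-species network as a function `f(t, y, dss)` returning the
#' state derivative.  The wild-type (`"WT"`) model contains four processes:
#' DSS-induced cytokine production (TNFa, IL1b, IL6, with p-p65 feeding back
#' on IL1b/IL6 and the IL17--IL17RA loop on p-p65), MIR31 induction by p-p65
#' and p-STAT3, MIR31 repression of its four targets (Gp130, IL17RA, Axin1,
#' Lats1/2), and WNT/Hippo-driven epithelial regeneration (Axin1 -| b-catenin,
#' Lats1/2 -| Yap, both driving proliferation).  In the knockout (`"KO"`)
#' model MIR31 production and all MIR31-dependent repression terms are
#' removed; regeneration proceeds by intrinsic proliferation only.
#'
#' Every species carries first-order degradation; inhibitory edges enter as
#' repressive Hill factors multiplying the affected production term.
#'
#' @param params A [colitis_params()] object.
#' @param genotype `"WT"` or `"KO"`.
#' @return A function `f(t, y, dss)` mapping time, named state vector and the
#'   effective DSS concentration to the derivative vector.
#' @export
build_model <- function(params, genotype = c("WT", "KO")) {
  stopifnot(inherits(params, "colitis_params"))
  genotype <- match.arg(genotype)
  # unpack parameters into this closure's frame once; the right-hand side is
  # called thousands of times per integration and list access dominates
  for (nm in names(params)) assign(nm, params[[nm]])
  wt <- genotype == "WT"

  function(t, y, dss) {
    y <- unname(pmax(y, 0))
    T_ <- y[1]; I1 <- y[2]; I6 <- y[3]; I17 <- y[4]
    P <- y[5]; S <- y[6]; G <- y[7]; R <- y[8]; M <- y[9]
    A <- y[10]; L <- y[11]; B <- y[12]; Yp <- y[13]; N <- y[14]

    dT  <- kTD * h_act(dss, lTD, n) - dTNF * T_
    dI1 <- kI1D * h_act(dss, lI1D, n) +
      kI1P65 * h_act(P, lI1P65, n) - dIL1 * I1
    dI6 <- kI6D * h_act(dss, lI6D, n) +
      kI6P65 * h_act(P, lI6P65, n) - dIL6 * I6
    dI17 <- kIL17ST * h_act(S, lIL17ST, n) - dIL17 * I17
    dP <- kP650 + kP65TNF * h_act(T_, lP65TNF, n) +
      kP65IL17 * h_act(I17, lP65IL17, n) * h_act(R, lP65I17R, n) -
      dP65 * P
    dS <- kST0 +
      kSTIL6 * h_act(I6, lSTIL6, n) * h_act(G, lSTGp, n) +
      kSTIL1 * h_act(I1, lSTIL1, n) - dST * S

    if (wt) {
      dM <- kMIRp65 * h_act(P, lMIRp65, n) +
        kMIRpST * h_act(S, lMIRpST, n) - dMIR * M
      repGp  <- h_rep(gammaGpMIR * M, lGpMIR, n)
      repR   <- h_rep(gammaI17RMIR * M, lI17RMIR, n)
      repAxi <- h_rep(gammaAxiMIR * M, lAxiMIR, n)
      repLat <- h_rep(gammaLatMIR * M, lLatMIR, n)
    } else {
      dM <- 0
      repGp <- repR <- repAxi <- repLat <- 1
    }

    dG <- kGp0 + kGp * repGp - dGp * G
    dR <- kI17R0 + kI17R * repR - dI17R * R
    dA <- kAxi0 + kAxi * repAxi - dAxi * A
    dL <- kLat0 + kLat * repLat - dLat * L
    dB <- kBcat * h_rep(A, lBcatAxi, n) - dBcat * B
    dY <- kYap * h_rep(L, lYapLat, n) - dYap * Yp
    dNcell <- kProlif * h_act(B, lNBcat, n) * h_act(Yp, lNYap, n) *
      (1 - N / Nmax) -
      kDamage * h_act(I1, lNIL1, n) * N -
      dN * (N - Nbase)

    c(dT, dI1, dI6, dI17, dP, dS, dG, dR, dM, dA, dL, dB, dY, dNcell)
  }
}

#' Untreated baseline steady state
#'
#' Integrates the DSS-free system from unit concentrations (MIR31 starting at
#' zero in the knockout) until the maximum relative derivative falls below
#' `tol`, capped at `t_max` days.  This homeostatic state is the initial
#' condition of every simulation: day-0 animals are untreated.
#'
#' @param params A [colitis_params()] object.
#' @param genotype `"WT"` or `"KO"`.
#' @param tol Convergence tolerance on `max(|dy| / max(|y|, 1))` (per day).
#' @param t_max Maximum equilibration time in days.
#' @return Named state vector at steady state.
#' @export
baseline_state <- function(params, genotype = "WT", tol = 1e-8, t_max = 500) {
  rhs <- build_model(params, genotype)
  y <- rep(1, 14)
  if (genotype == "KO") y[9] <- 0
  f <- function(t, y, parms) list(rhs(t, y, 0))
  converged <- function(y) max(abs(rhs(0, y, 0)) / pmax(abs(y), 1)) < tol
  # in the knockout, MIR31 is pinned at zero and excluded from the Newton solve
  free <- if (genotype == "KO") setdiff(1:14, 9) else 1:14

  newton_polish <- function(y) {
    for (it in 1:30) {
      fy <- rhs(0, y, 0)[free]
      if (max(abs(fy) / pmax(abs(y[free]), 1)) < tol) return(y)
      J <- matrix(0, length(free), length(free))
      for (j in seq_along(free)) {
        h <- max(1e-7, 1e-7 * abs(y[free[j]]))
        yp <- y; yp[free[j]] <- yp[free[j]] + h
        J[, j] <- (rhs(0, yp, 0)[free] - fy) / h
      }
      step <- tryCatch(solve(J, -fy), error = function(e) NULL)
      if (is.null(step)) return(y)
      ynew <- y
      ynew[free] <- y[free] + step
      if (any(ynew < 0) || any(!is.finite(ynew))) return(y)
      y <- ynew
    }
    y
  }

  elapsed <- 0
  repeat {
    # short relaxation toward the attractor, then Newton to machine-level rest
    chunk <- min(25, t_max - elapsed)
    sol <- deSolve::lsoda(y, c(0, chunk), f, parms = NULL,
                          rtol = 1e-6, atol = 1e-8)
    y <- pmax(sol[nrow(sol), -1], 0)
    elapsed <- elapsed + chunk
    y <- newton_polish(y)
    if (converged(y)) break
    if (elapsed >= t_max) {
      stop("Baseline steady state did not converge within ", t_max, " days.",
           call. = FALSE)
    }
  }
  stats::setNames(pmax(unname(y), 0), species_names())
}

#' Simulate the colitis model
#'
#' Integrates the network ODEs for one genotype under a dosing protocol and
#' returns the trajectory as a tibble (one row per time point, one column per
#' species).  Integration is split at the protocol's switch points so the
#' discontinuous forcing never crosses an adaptive step.  Initial conditions
#' default to the genotype's untreated steady state ([baseline_state()]).
#'
#' States that dip below `-1e-9` abort with an error; values in `[-1e-9, 0)`
#' are clamped to zero with a warning.
#'
#' @param params A [colitis_params()] object.
#' @param protocol A [dose_protocol()]; default 3.5% wt/vol for days 0--5.
#' @param genotype `"WT"` or `"KO"`.
#' @param times Output time grid (days) within `[0, horizon]`; defaults to
#'   0.01-day spacing, the resolution used by the downstream analyses.
#' @param y0 Optional named initial state (bypasses the steady-state solve).
#' @param rtol,atol Solver tolerances passed to [deSolve::lsoda()].
#' @return A `colitis_trajectory` tibble with columns `time` and the 14
#'   species; attributes `genotype`, `protocol` and `params`.
#' @examples
#' \donttest{
#' traj <- simulate_colitis(colitis_params(), dose_protocol(3.5))
#' observables(traj)
#' }
#' @export
simulate_colitis <- function(params, protocol = dose_protocol(),
                             genotype = c("WT", "KO"), times = NULL,
                             y0 = NULL, rtol = 1e-8, atol = 1e-10) {
  stopifnot(inherits(params, "colitis_params"),
            inherits(protocol, "dose_protocol"))
  genotype <- match.arg(genotype)
  if (is.null(times)) times <- seq(0, protocol$horizon, by = 0.01)
  if (any(times < 0) || any(times > protocol$horizon)) {
    stop("`times` must lie within [0, horizon].", call. = FALSE)
  }
  times <- sort(unique(times))
  if (is.null(y0)) y0 <- baseline_state(params, genotype)
  stopifnot(length(y0) == 14)

  rhs <- build_model(params, genotype)
  f <- function(t, y, parms) list(rhs(t, y, dss_input(t, protocol)))

  # integrate piecewise across the forcing discontinuities
  breaks <- sort(unique(c(min(times), protocol$t_on, protocol$t_off,
                          max(times))))
  breaks <- breaks[breaks >= min(times) & breaks <= max(times)]
  out <- matrix(NA_real_, nrow = length(times), ncol = 14)
  state <- as.numeric(y0)
  out[times == breaks[1], ] <- state
  for (i in seq_len(length(breaks) - 1)) {
    seg <- c(breaks[i], times[times > breaks[i] & times < breaks[i + 1]],
             breaks[i + 1])
    seg <- unique(seg)
    sol <- deSolve::lsoda(state, seg, f, parms = NULL, rtol = rtol, atol = atol)
    if (attr(sol, "istate")[1] < 0 || nrow(sol) < length(seg)) {
      stop("ODE integration failed in segment [", breaks[i], ", ",
           breaks[i + 1], "] days (lsoda istate = ",
           attr(sol, "istate")[1], ").", call. = FALSE)
    }
    state <- sol[nrow(sol), -1]
    keep <- sol[, 1] %in% times
    out[match(sol[keep, 1], times), ] <- sol[keep, -1, drop = FALSE]
  }

  if (min(out, na.rm = TRUE) < -1e-9) {
    stop("Simulation produced a state below -1e-9 (min = ",
         format(min(out)), "); model or parameters are inconsistent.",
         call. = FALSE)
  }
  if (any(out < 0)) {
    warning("Clamped ", sum(out < 0),
            " state value(s) in [-1e-9, 0) to zero.", call. = FALSE)
    out[out < 0] <- 0
  }

  colnames(out) <- species_names()
  traj <- tibble::as_tibble(as.data.frame(out))
  traj <- dplyr::bind_cols(tibble::tibble(time = times), traj)
  structure(traj,
            class = c("colitis_trajectory", class(traj)),
            genotype = genotype, protocol = protocol, params = params)
}

#' Normalized observable time courses
#'
#' Extracts the four measured observables (MIR31, p-p65, p-STAT3 and the
#' proliferative cell count N) from a trajectory and normalizes each by its
#' maximum, mirroring how the quantified experimental panels are scaled.  For
#' cross-genotype comparison, pass the wild-type trajectory as `norm_ref` so
#' both genotypes share the wild-type maxima.
#'
#' @param traj A `colitis_trajectory`.
#' @param norm_ref Optional reference trajectory supplying the normalizing
#'   maxima (defaults to `traj` itself).
#' @return A tibble with columns `time`, `observable`, `value` (normalized)
#'   and `genotype`.
#' @export
observables <- function(traj, norm_ref = NULL) {
  stopifnot(inherits(traj, "colitis_trajectory"))
  if (nrow(traj) == 0) stop("Trajectory is empty.", call. = FALSE)
  ref <- norm_ref %||% traj
  obs <- c(MIR31 = "MIR31", pP65 = "pP65", pSTAT3 = "pSTAT3", N = "N")
  maxima <- purrr::map_dbl(obs, ~ max(ref[[.x]]))
  if (any(maxima <= 0)) {
    stop("Cannot normalize: observable(s) identically zero: ",
         paste(names(maxima)[maxima <= 0], collapse = ", "), call. = FALSE)
  }
  purrr::map_dfr(names(obs), function(o) {
    tibble::tibble(
      time = traj$time,
      observable = o,
      value = traj[[obs[[o]]]] / maxima[[o]],
      genotype = attr(traj, "genotype") %||% NA_character_
    )
  })
}

#' Export a trajectory as tidy long-format data
#'
#' @param traj A `colitis_trajectory`.
#' @return Tibble with columns `time_days`, `species`, `value`, `genotype`,
#'   `dss_conc`.
#' @export
trajectory_long <- function(traj) {
  stopifnot(inherits(traj, "colitis_trajectory"))
  prot <- attr(traj, "protocol")
  tibble::as_tibble(traj) |>
    tidyr::pivot_longer(-"time", names_to = "species", values_to = "value") |>
    dplyr::transmute(
      time_days = .data$time,
      species = .data$species,
      value = .data$value,
      genotype = attr(traj, "genotype") %||% NA_character_,
      dss_conc = if (!is.null(prot)) prot$dss_conc else NA_real_
    )
}

#' @export
print.colitis_trajectory <- function(x, ...) {
  cat(sprintf("<colitis_trajectory> %s genotype, %d time points on [%g, %g] days\n",
              attr(x, "genotype") %||% "?", nrow(x),
              min(x$time), max(x$time)))
  NextMethod()
}
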
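# Shared fixtures, computed once per test run.  All simulations here use the
# package defaults (calibrated parameterization, 3.5% / 5-day protocol).

.cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .cache)) assign(key, force(expr), envir = .cache)
  get(key, envir = .cache)
}

default_params <- function() memo("params", colitis_params())
default_protocol <- function() memo("protocol", dose_protocol())

wt_traj <- function() {
  memo("wt_traj", simulate_colitis(default_params(), default_protocol(), "WT"))
}
ko_traj <- function() {
  memo("ko_traj", simulate_colitis(default_params(), default_protocol(), "KO"))
}

# coarser grid for tests that only need qualitative time resolution
coarse_times <- function() seq(0, 15, by = 0.05)

# classic fixed-step RK4 on a right-hand side f(t, y): the independent
# reference integrator used to cross-check the adaptive solver
rk4_integrate <- function(f, y0, times) {
  out <- matrix(NA_real_, nrow = length(times), ncol = length(y0))
  out[1, ] <- y0
  y <- y0
  for (i in seq_len(length(times) - 1)) {
    h <- times[i + 1] - times[i]
    t <- times[i]
    k1 <- f(t, y)
    k2 <- f(t + h / 2, y + h / 2 * k1)
    k3 <- f(t + h / 2, y + h / 2 * k2)
    k4 <- f(t + h, y + h * k3)
    y <- y + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    out[i + 1, ] <- y
  }
  out
}

obs_series <- function(obs, name) obs[obs$observable == name, ]
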
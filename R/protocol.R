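#' DSS dosing protocol
#'
#' Describes the drinking-water DSS schedule used throughout the package: a
#' constant concentration `dss_conc` between `t_on` and `t_off`, followed by a
#' first-order washout of residual DSS after withdrawal.  The default mirrors
#' the standard murine protocol: 3.5% wt/vol DSS for five days, then plain
#' water, observed to day 15.
#'
#' @param dss_conc DSS concentration in drinking water (% wt/vol), `>= 0`.
#' @param t_on Day treatment starts (default 0).
#' @param t_off Day DSS is withdrawn (default 5); must satisfy
#'   `t_on < t_off <= horizon`.
#' @param washout_rate First-order decay rate (per day) of residual DSS after
#'   withdrawal.  Residual DSS is retained in the gut for some time after the
#'   water is switched, so the input is not a hard step.
#' @param horizon Last simulated day (default 15).
#'
#' @return An object of class `dose_protocol` (a named list).
#' @examples
#' prot <- dose_protocol(dss_conc = 3.5)
#' dss_input(c(0, 2, 5, 6), prot)
#' @export
dose_protocol <- function(dss_conc = 3.5, t_on = 0, t_off = 5,
                          washout_rate = 1, horizon = 15) {
  if (dss_conc < 0) stop("`dss_conc` must be >= 0.", call. = FALSE)
  if (!(t_on < t_off && t_off <= horizon)) {
    stop("Protocol must satisfy t_on < t_off <= horizon.", call. = FALSE)
  }
  if (washout_rate <= 0) stop("`washout_rate` must be > 0.", call. = FALSE)
  structure(
    list(dss_conc = dss_conc, t_on = t_on, t_off = t_off,
         washout_rate = washout_rate, horizon = horizon),
    class = "dose_protocol"
  )
}

#' Effective DSS concentration at time t
#'
#' Piecewise forcing used by the model: zero before `t_on`, the nominal
#' concentration during treatment, and exponential washout
#' `dss_conc * exp(-washout_rate * (t - t_off))` after withdrawal.
#'
#' @param t Time(s) in days, `>= 0`.
#' @param protocol A [dose_protocol()].
#' @return Effective DSS concentration (% wt/vol), same length as `t`.
#' @export
dss_input <- function(t, protocol) {
  stopifnot(inherits(protocol, "dose_protocol"))
  if (any(t < 0)) stop("`t` must be >= 0.", call. = FALSE)
  out <- numeric(length(t))
  during <- t >= protocol$t_on & t < protocol$t_off
  after <- t >= protocol$t_off
  out[during] <- protocol$dss_conc
  out[after] <- protocol$dss_conc *
    exp(-protocol$washout_rate * (t[after] - protocol$t_off))
  out
}

#' @export
print.dose_protocol <- function(x, ...) {
  cat(sprintf(
    "<dose_protocol> %.2f%% wt/vol DSS on days [%g, %g), washout %g/day, horizon %g days\n",
    x$dss_conc, x$t_on, x$t_off, x$washout_rate, x$horizon
  ))
  invisible(x)
}
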
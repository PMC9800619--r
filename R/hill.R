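#' Hill activation and repression rate laws
#'
#' The model's kinetics are built from the two complementary Hill forms.
#' `hill_activation()` returns `k * Y^n / (l^n + Y^n)`, the saturating rate at
#' which a regulator at concentration `Y` drives a downstream production term;
#' `hill_repression()` returns `k * l^n / (l^n + Y^n)`, the residual rate when
#' `Y` acts as an inhibitor.  The two forms are exact complements:
#' `hill_activation(Y, k, l, n) + hill_repression(Y, k, l, n) == k` for any `Y`.
#'
#' @param Y Regulator concentration(s), non-negative (a.u.).
#' @param k Maximal rate (per day); strictly positive.
#' @param l Half-saturation constant (a.u.); strictly positive.  At `Y = l`
#'   both forms return `k / 2`.
#' @param n Hill coefficient (dimensionless), `n >= 1`.
#'
#' @return Numeric vector of rates, the same length as `Y`; bounded in `[0, k]`.
#' @examples
#' hill_activation(3, k = 2, l = 1, n = 2)  # 2 * 9 / (1 + 9) = 1.8
#' hill_repression(0, k = 2, l = 1, n = 2)  # full rate: repressor absent
#' @export
hill_activation <- function(Y, k, l, n) {
  check_hill_args(Y, k, l, n)
  Yn <- Y^n
  k * Yn / (l^n + Yn)
}

#' @rdname hill_activation
#' @export
hill_repression <- function(Y, k, l, n) {
  check_hill_args(Y, k, l, n)
  ln <- l^n
  k * ln / (ln + Y^n)
}

check_hill_args <- function(Y, k, l, n) {
  if (any(!is.finite(Y)) || any(Y < 0)) {
    stop("`Y` must be finite and non-negative.", call. = FALSE)
  }
  if (any(k <= 0) || any(l <= 0)) {
    stop("`k` and `l` must be strictly positive.", call. = FALSE)
  }
  if (any(n < 1)) {
    stop("Hill coefficient `n` must be >= 1.", call. = FALSE)
  }
  invisible(TRUE)
}

# Internal unchecked forms used inside the ODE right-hand side, where the
# state has already been validated and the checks would dominate runtime.
h_act <- function(Y, l, n) {
  Yn <- Y^n
  Yn / (l^n + Yn)
}

h_rep <- function(Y, l, n) {
  ln <- l^n
  ln / (ln + Y^n)
}
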
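#' Plot normalized observable time courses
#'
#' @param object A `colitis_trajectory`.
#' @param ... Unused.
#' @return A ggplot: one panel per observable, normalized to its maximum.
#' @export
autoplot.colitis_trajectory <- function(object, ...) {
  observables(object) |>
    ggplot2::ggplot(ggplot2::aes(x = .data$time, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~observable, scales = "free_y") +
    ggplot2::labs(x = "time (days)", y = "normalized level") +
    ggplot2::theme_minimal()
}

#' Plot a wild-type / knockout comparison
#'
#' @param object A [ko_comparison()] result.
#' @param ... Unused.
#' @return A ggplot of the WT-normalized observables by genotype.
#' @export
autoplot.ko_comparison <- function(object, ...) {
  object$observables |>
    ggplot2::ggplot(ggplot2::aes(x = .data$time, y = .data$value,
                                 colour = .data$genotype)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~observable, scales = "free_y") +
    ggplot2::labs(x = "time (days)", y = "level (WT-normalized)") +
    ggplot2::theme_minimal()
}

#' Heatmap of the sensitivity scan
#'
#' @param object A [sensitivity_scan()] result.
#' @param ... Unused.
#' @return A ggplot heatmap of delta over (time, lambda), one facet per
#'   parameter.
#' @export
autoplot.sensitivity_scan <- function(object, ...) {
  tibble::as_tibble(object) |>
    ggplot2::ggplot(ggplot2::aes(x = .data$time, y = .data$lambda,
                                 fill = .data$delta)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_log10() +
    ggplot2::facet_wrap(~parameter) +
    ggplot2::labs(x = "time (days)", y = expression(lambda),
                  fill = expression(delta)) +
    ggplot2::theme_minimal()
}

#' Plot a competition profile
#'
#' @param object A [competition_profile()].
#' @param what `"probabilities"` (p0, p_inh, p_reg) or `"strengths"`
#'   (F0, F1, F2).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.competition_profile <- function(object,
                                         what = c("probabilities", "strengths"),
                                         ...) {
  what <- match.arg(what)
  df <- if (what == "probabilities") {
    object$probabilities |>
      dplyr::select("time", "p0", "p_inh", "p_reg") |>
      tidyr::pivot_longer(-"time", names_to = "series")
  } else {
    object$strengths |>
      dplyr::select("time", "F0", "F1", "F2") |>
      tidyr::pivot_longer(-"time", names_to = "series")
  }
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$value,
                                   colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (days)",
                  y = if (what == "probabilities") "binding probability"
                      else "action strength (a.u.)") +
    ggplot2::theme_minimal()
}
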
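#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a simulated bundle trace
#'
#' Radius of curvature versus time, with the unperturbed radius
#' `R0 = lambda0/sigma` as a dashed reference.
#'
#' @param object A `bundle_trace` from [simulate_global()].
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.bundle_trace <- function(object, ...) {
  R0 <- attr(object, "R0")
  ggplot2::ggplot(object, ggplot2::aes(x = .data$t, y = .data$R)) +
    ggplot2::geom_line(colour = "#B2182B") +
    ggplot2::geom_hline(yintercept = R0, linetype = "dashed",
                        colour = "grey40") +
    ggplot2::labs(x = "time after stretch (s)",
                  y = "radius of curvature (µm)") +
    ggplot2::theme_minimal()
}

#' Plot a kymograph
#'
#' Arc-length x time intensity raster.
#'
#' @param object A [kymograph()].
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.kymograph <- function(object, ...) {
  lab <- switch(object$state,
                raw = "intensity (a.u.)",
                bleach_corrected = "intensity (bleach-corrected)",
                normalized_relative = "ΔI/I0")
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$t, y = .data$s,
                               fill = .data$intensity)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = lab) +
    ggplot2::labs(x = "time (s)", y = "arc length (µm)") +
    ggplot2::theme_minimal()
}

#' Radius-versus-strain summary plot
#'
#' Short- and long-time radius differences against applied strain, the
#' standard summary of a stretch experiment cohort.
#'
#' @param per_strain Tibble with columns `eps`, `d_step`, `d_inf` (and
#'   optional `d_step_sd`, `d_inf_sd`).
#' @return A ggplot.
#' @export
plot_strain_response <- function(per_strain) {
  long <- per_strain |>
    tidyr::pivot_longer(dplyr::any_of(c("d_step", "d_inf")),
                        names_to = "horizon", values_to = "dR") |>
    dplyr::mutate(horizon = dplyr::recode(.data$horizon,
                                          d_step = "short time (R0+ - R0)",
                                          d_inf = "long time (R∞ - R0)"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$eps, y = .data$dR,
                                     colour = .data$horizon)) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         linewidth = 0.5) +
    ggplot2::labs(x = "applied strain", y = "ΔR (µm)",
                  colour = NULL) +
    ggplot2::theme_minimal()
}
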
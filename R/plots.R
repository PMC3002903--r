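#' Scatter of higher moments against mean expression
#'
#' One panel per higher moment (CV, skewness, kurtosis) against per-gene
#' mean, colored by stratum when available — the standard first look at
#' the moment structure of an expression matrix.
#'
#' @param moments Per-gene tibble from [moment_summary()], optionally with
#'   a `stratum` column.
#' @return A ggplot object.
#' @export
plot_moment_scatter <- function(moments) {
  d <- as_tibble(moments) |>
    tidyr::pivot_longer(dplyr::all_of(c("cv", "skewness", "kurtosis")),
                        names_to = "moment", values_to = "value")
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$mean, y = .data$value))
  p <- if ("stratum" %in% names(d)) {
    p + ggplot2::geom_point(ggplot2::aes(color = .data$stratum),
                            alpha = 0.4, size = 0.6)
  } else {
    p + ggplot2::geom_point(alpha = 0.4, size = 0.6)
  }
  p +
    ggplot2::facet_wrap(~moment, scales = "free_y") +
    ggplot2::labs(x = "mean of log expression", y = NULL)
}

#' L-moment ratio diagram
#'
#' Per-gene (L-skewness, L-kurtosis) points overlaid on the theoretical
#' family curves and points, with point color mapped to mean expression
#' (the customary red-intensity coding).
#'
#' @param moments Per-gene tibble with `tau3`, `tau4` and `mean`.
#' @param tau3 Grid for the theoretical curves.
#' @return A ggplot object.
#' @export
plot_lmoment_diagram <- function(moments, tau3 = seq(-0.6, 0.9, length.out = 61L)) {
  theo <- lmoment_diagram_data(tau3)
  curves <- dplyr::filter(theo, .data$geometry == "curve")
  pts <- dplyr::filter(theo, .data$geometry == "point")
  ggplot2::ggplot() +
    ggplot2::geom_point(
      data = as_tibble(moments),
      ggplot2::aes(x = .data$tau3, y = .data$tau4, color = .data$mean),
      alpha = 0.5, size = 0.8
    ) +
    ggplot2::scale_color_gradient(low = "grey85", high = "red3") +
    ggplot2::geom_line(
      data = curves,
      ggplot2::aes(x = .data$tau3, y = .data$tau4, linetype = .data$family)
    ) +
    ggplot2::geom_point(
      data = pts,
      ggplot2::aes(x = .data$tau3, y = .data$tau4, shape = .data$family),
      size = 2
    ) +
    ggplot2::labs(x = "L-skewness", y = "L-kurtosis", color = "mean expr.")
}

#' Autoplot of a trend fit
#'
#' Scatter of the fitted relationship with the OLS curve; the quadratic
#' kurtosis-skewness panel also shows the theoretical lower bound
#' `K = S^2 + 1`.
#'
#' @param object A `trend_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @importFrom ggplot2 autoplot
#' @export
autoplot.trend_fit <- function(object, ...) {
  co <- object$coefficients$estimate
  if (object$model == "linear_logcv_mean") {
    d <- dplyr::mutate(object$data, .y = log10(.data$cv))
    ggplot2::ggplot(d, ggplot2::aes(x = .data$mean, y = .data$.y)) +
      ggplot2::geom_point(alpha = 0.3, size = 0.6) +
      ggplot2::geom_abline(intercept = co[1L], slope = co[2L], color = "red3") +
      ggplot2::labs(x = "mean of log expression", y = "log10(CV)")
  } else {
    grid <- seq(min(object$data$skewness), max(object$data$skewness),
                length.out = 200L)
    curve <- tibble(skewness = grid,
                    fitted = co[1L] + co[2L] * grid + co[3L] * grid^2,
                    bound = kurtosis_lower_bound(grid))
    ggplot2::ggplot(object$data,
                    ggplot2::aes(x = .data$skewness, y = .data$kurtosis)) +
      ggplot2::geom_point(alpha = 0.3, size = 0.6) +
      ggplot2::geom_line(data = curve,
                         ggplot2::aes(y = .data$fitted), color = "red3") +
      ggplot2::geom_line(data = curve,
                         ggplot2::aes(y = .data$bound), color = "blue3") +
      ggplot2::labs(x = "skewness", y = "kurtosis")
  }
}

#' @export
ggplot2::autoplot
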
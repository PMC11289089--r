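#' Plot a correlation curve
#'
#' Correlation amplitude versus temporal lag on a logarithmic lag axis, with
#' a ribbon of +/- 1 s.e.m. when the curve averages several segments.
#'
#' @param object An `fcs_acf` tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.fcs_acf <- function(object, ...) {
  d <- dplyr::filter(as_tibble(object), .data$lag_px > 0)
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$tau_s, y = .data$G)) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::geom_line(linewidth = 0.3, alpha = 0.6) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = expression(tau ~ "(s)"), y = expression(G(tau)),
                  title = attr(object, "label")) +
    ggplot2::theme_minimal()
  if (any(d$sem > 0)) {
    p <- p + ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$G - .data$sem, ymax = .data$G + .data$sem),
      alpha = 0.2)
  }
  p
}

#' Plot a segment intensity map
#'
#' Tile map of per-segment intensity (normalized by default), the view used
#' to pick out subcellular regions by their relative brightness.
#'
#' @param object A [segment_map()] tibble.
#' @param what `"norm"` or `"raw"`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.segment_map <- function(object, what = c("norm", "raw"), ...) {
  what <- match.arg(what)
  v <- if (what == "norm") "norm_mean" else "raw_mean"
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$col, y = .data$row,
                               fill = .data[[v]])) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = if (what == "norm") "I / I_max"
                                  else "mean counts") +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(x = "segment (X)", y = "line / time segment") +
    ggplot2::theme_minimal()
}

#' Plot a fitted correlation curve
#'
#' Overlays the fitted diffusion model (solid line, evaluated on a dense
#' logarithmic lag grid) on the fitted data points.
#'
#' @param object An `fcs_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.fcs_fit <- function(object, ...) {
  d <- object$data
  tau_grid <- exp(seq(log(min(d$tau_s[d$tau_s > 0])),
                      log(max(d$tau_s)), length.out = 200))
  model_d <- tibble(tau_s = tau_grid,
                    G = predict(object, tau_grid))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$tau_s, y = .data$G)) +
    ggplot2::geom_point(size = 0.8, alpha = 0.7) +
    ggplot2::geom_line(data = model_d, colour = "red") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(
      x = expression(tau ~ "(s)"), y = expression(G(tau)),
      subtitle = sprintf("%s: D = %.3g um^2/s, G0 = %.3g", object$model,
                         object$estimate[["D"]], object$estimate[["G0"]])) +
    ggplot2::theme_minimal()
}
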
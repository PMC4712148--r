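#' Plot a tuning curve
#'
#' Mean rates with SEM error bars against the varied stimulus axis
#' (log-scaled, as tuning curves are conventionally shown), with the
#' spontaneous-rate band when available.
#'
#' @param object A `tuning_curve`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot tuning_curve
#' @export
autoplot.tuning_curve <- function(object, ...) {
  spont <- attr(object, "spont_rate")
  spont_sem <- attr(object, "spont_sem") %||% 0
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$value,
                                            y = .data$mean_rate))
  if (!is.null(spont) && is.finite(spont)) {
    p <- p + ggplot2::annotate(
      "rect", xmin = -Inf, xmax = Inf,
      ymin = spont - spont_sem, ymax = spont + spont_sem,
      alpha = 0.2, fill = "grey50") +
      ggplot2::geom_hline(yintercept = spont, colour = "grey40",
                          linewidth = 0.3)
  }
  p +
    ggplot2::geom_errorbar(ggplot2::aes(
      ymin = .data$mean_rate - .data$sem_rate,
      ymax = .data$mean_rate + .data$sem_rate), width = 0) +
    ggplot2::geom_point(shape = 1, size = 2) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = attr(object, "varying") %||% "stimulus value",
                  y = "firing rate (spikes/s)") +
    ggplot2::theme_classic()
}

#' Plot a fitted tuning curve over its data
#'
#' @param object A `tuning_fit` (`dog_fit`, `tf_fit`, or `crf_fit`).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot tuning_fit
#' @export
autoplot.tuning_fit <- function(object, ...) {
  curve <- object$curve
  rng <- range(curve$value)
  grid <- exp(seq(log(max(rng[1], 1e-4)), log(rng[2]), length.out = 256))
  fitted <- tibble::tibble(value = grid,
                           mean_rate = predict(object, grid))
  autoplot(curve) +
    ggplot2::geom_line(data = fitted, colour = "black", linewidth = 0.6) +
    ggplot2::labs(subtitle = sprintf("VE = %.3f", object$variance_explained))
}

#' Plot a receptive-field map
#'
#' Signed STA amplitude on the degree grid, grey-scale, as receptive fields
#' are conventionally displayed.
#'
#' @param object An `rf_map`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot rf_map
#' @export
autoplot.rf_map <- function(object, ...) {
  co <- map_coords(object$map, object$deg_per_pixel)
  df <- tibble::tibble(
    x = rep(co$x, each = length(co$y)),
    y = rep(co$y, times = length(co$x)),
    amplitude = as.numeric(object$map)
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y,
                                   fill = .data$amplitude)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2(low = "black", mid = "grey50",
                                  high = "white", midpoint = 0) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "azimuth (deg)", y = "elevation (deg)",
                  fill = "STA",
                  subtitle = sprintf("lag %.0f ms, %d spikes",
                                     1000 * object$best_lag_s,
                                     object$n_spikes)) +
    ggplot2::theme_classic()
}

#' Polar plot of a direction-tuning response
#'
#' @param rates Mean rates per direction (spikes/s).
#' @param directions_deg Directions, degrees.
#' @param spont_rate Optional spontaneous level drawn as a dashed circle.
#' @return A ggplot object.
#' @export
plot_direction_polar <- function(rates, directions_deg = seq(0, 315, by = 45),
                                 spont_rate = NULL) {
  df <- tibble::tibble(direction = c(directions_deg, directions_deg[1]),
                       rate = c(rates, rates[1]))
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$direction, .data$rate)) +
    ggplot2::geom_path() +
    ggplot2::coord_polar(start = -pi / 2, direction = -1) +
    ggplot2::scale_x_continuous(breaks = seq(0, 315, by = 45),
                                limits = c(0, 360)) +
    ggplot2::labs(x = NULL, y = "rate (spikes/s)") +
    ggplot2::theme_minimal()
  if (!is.null(spont_rate)) {
    p <- p + ggplot2::geom_hline(yintercept = spont_rate,
                                 linetype = "dashed", colour = "red")
  }
  p
}
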
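# Quick-look ggplot2 methods for the main result types.

#' Plot Kaplan-Meier survival curves
#'
#' @param object A `g1span_km` tibble from [survival_curve()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot g1span_km
#' @export
autoplot.g1span_km <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(.data$time, .data$survival,
                               colour = .data$group)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "Lifespan", y = "Fraction surviving",
                  colour = NULL) +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}

#' Plot a decay fit with its data
#'
#' @param object A `decay_fit` from [fit_decay()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot decay_fit
#' @export
autoplot.decay_fit <- function(object, ...) {
  pts <- object$points
  curve <- tibble(
    time_min = seq(min(pts$time_min), max(pts$time_min), length.out = 200)
  )
  curve$fit <- exp(-object$lambda * (curve$time_min - pts$time_min[1])) *
    pts$normalized_density[1]
  ggplot2::ggplot(pts, ggplot2::aes(.data$time_min,
                                    .data$normalized_density)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = curve, ggplot2::aes(y = .data$fit),
                       colour = "steelblue") +
    ggplot2::labs(x = "Time after cycloheximide (min)",
                  y = "Normalized band density",
                  subtitle = sprintf("half-life %.1f min", object$t_half)) +
    ggplot2::theme_minimal()
}

#' Plot a size-control fit
#'
#' Relative G1 growth against log normalized birth size with the fitted
#' line; the slope measures size-control efficiency (0 = timer, -1 =
#' perfect sizer).
#'
#' @param object A `size_control_fit` from [size_control_fit()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot size_control_fit
#' @export
autoplot.size_control_fit <- function(object, ...) {
  ggplot2::ggplot(object$points,
                  ggplot2::aes(.data$log_vb_norm, .data$kt_g1)) +
    ggplot2::geom_point(alpha = 0.5) +
    ggplot2::geom_abline(slope = object$slope, intercept = object$intercept,
                         colour = "steelblue") +
    ggplot2::labs(x = "ln(birth size / reference)",
                  y = expression(k * T[G1]),
                  subtitle = sprintf("slope %.2f (95%% CI %.2f, %.2f)",
                                     object$slope, object$ci95[1],
                                     object$ci95[2])) +
    ggplot2::theme_minimal()
}

#' Plot a hexagonal-binning summary
#'
#' @param object A `g1span_hexbin` from [hexbin_summary()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot g1span_hexbin
#' @export
autoplot.g1span_hexbin <- function(object, ...) {
  cell <- attr(object, "cell")
  # pointy-top hexagon outline around each occupied centre
  ang <- pi / 2 + seq(0, 5) * pi / 3
  verts <- purrr::map_dfr(seq_len(nrow(object)), function(i) {
    tibble(
      id = i,
      x = object$hex_x[i] + cell[["x"]] / sqrt(3) * cos(ang),
      y = object$hex_y[i] + cell[["y"]] / 1.5 * sin(ang),
      count = object$count[i]
    )
  })
  ggplot2::ggplot(verts, ggplot2::aes(.data$x, .data$y, group = .data$id,
                                      fill = .data$count)) +
    ggplot2::geom_polygon() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::theme_minimal()
}

#' Plot an elutriation time course
#'
#' Mean volume (log scale) and budded fraction against time for each label.
#'
#' @param data A tibble with columns `label`, `time_h`, `mean_volume_fl`,
#'   `budded_fraction`.
#' @return A ggplot object.
#' @export
plot_elutriation <- function(data) {
  check_columns(data, c("label", "time_h", "mean_volume_fl",
                        "budded_fraction"))
  long <- tidyr::pivot_longer(data, c("mean_volume_fl", "budded_fraction"),
                              names_to = "measure")
  ggplot2::ggplot(long, ggplot2::aes(.data$time_h, .data$value,
                                     colour = .data$label)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::facet_wrap(~measure, scales = "free_y") +
    ggplot2::labs(x = "Time (h)", y = NULL, colour = NULL) +
    ggplot2::theme_minimal()
}
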
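#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a force curve
#'
#' Force versus piezo displacement for both segments; the canonical
#' approach/retraction figure with the adhesion dips visible below the
#' zero-force line on retraction.
#'
#' @param object A [force_curve()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.force_curve <- function(object, ...) {
  df <- bind_rows(
    mutate(curve_force(object, "approach"), segment = "approach"),
    mutate(curve_force(object, "retraction"), segment = "retraction")
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$z_nm, .data$force_pN / 1000,
                                   colour = .data$segment)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_path() +
    ggplot2::labs(x = "z displacement (nm)", y = "force (nN)",
                  colour = NULL, title = object$label) +
    ggplot2::theme_minimal()
}

#' Histogram of a measured quantity with a fitted density
#'
#' @param values Numeric measurements.
#' @param fit Optional [fit_density()] result to overlay.
#' @param quantity Axis label.
#' @return A ggplot object.
#' @export
plot_population_hist <- function(values, fit = NULL, quantity = "value") {
  values <- values[!is.na(values)]
  df <- tibble(x = values)
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$x)) +
    ggplot2::geom_histogram(ggplot2::aes(y = ggplot2::after_stat(density)),
                            bins = max(grDevices::nclass.FD(values), 5),
                            fill = "grey80", colour = "grey40") +
    ggplot2::labs(x = quantity, y = "density") +
    ggplot2::theme_minimal()
  if (!is.null(fit)) {
    xs <- seq(min(values), max(values), length.out = 256)
    ys <- if (fit$family == "lognormal") {
      stats::dlnorm(xs, fit$estimate[["meanlog"]], fit$estimate[["sdlog"]])
    } else {
      stats::dnorm(xs, fit$estimate[["mean"]], fit$estimate[["sd"]])
    }
    p <- p + ggplot2::geom_line(data = tibble(x = xs, y = ys),
                                ggplot2::aes(.data$x, .data$y),
                                colour = "black", linewidth = 0.8)
  }
  p
}

#' Pixel map of a per-curve quantity over a force-volume grid
#'
#' @param results Per-pixel results from [analyze_force_volume()].
#' @param quantity Column to map (default `"E_Pa"`).
#' @return A ggplot object.
#' @export
plot_force_map <- function(results, quantity = "E_Pa") {
  ggplot2::ggplot(results, ggplot2::aes(.data$col, .data$row,
                                        fill = .data[[quantity]])) +
    ggplot2::geom_tile() +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "column", y = "row", fill = quantity) +
    ggplot2::theme_minimal()
}
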
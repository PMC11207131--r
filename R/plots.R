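#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

.phase_palette <- c(RED = "#c0392b", YELLOW = "#d4ac0d", GREEN = "#1e8449")

#' Quiver plot of an Eulerian velocity field
#'
#' Arrows start at each lattice point and point along the local mean
#' velocity, scaled so the longest arrow spans roughly one lattice spacing;
#' undefined bins are drawn as hollow points.
#'
#' @param object A `fucci_velocity_field` from [velocity_field()].
#' @param arrow_scale Multiplier on the automatic arrow length.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.fucci_velocity_field <- function(object, arrow_scale = 1, ...) {
  fov <- attr(object, "fov_size_px")
  def <- object[object$defined, ]
  speed <- sqrt(def$vx^2 + def$vy^2)
  k <- if (nrow(def) && max(speed) > 0) {
    arrow_scale * 0.05 * fov / max(speed)
  } else {
    1
  }
  p <- ggplot2::ggplot() +
    ggplot2::geom_point(
      data = object[!object$defined, ],
      ggplot2::aes(x = .data$x, y = .data$y), shape = 1, colour = "grey70"
    ) +
    ggplot2::geom_segment(
      data = def,
      ggplot2::aes(x = .data$x, y = .data$y,
                   xend = .data$x + k * .data$vx,
                   yend = .data$y + k * .data$vy,
                   colour = sqrt(.data$vx^2 + .data$vy^2)),
      arrow = ggplot2::arrow(length = ggplot2::unit(0.12, "cm"))
    ) +
    ggplot2::scale_colour_viridis_c(name = paste0("|v| (", attr(object, "units"), ")")) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed(xlim = c(0, fov), ylim = c(fov, 0)) +
    ggplot2::labs(x = "x (px)", y = "y (px)",
                  title = "Mean nuclear velocity field") +
    ggplot2::theme_minimal()
  p
}

#' Phase-count or phase-fraction time series
#'
#' @param object A `fucci_phase_counts` from [phase_counts()].
#' @param fractions Plot fractions instead of absolute counts.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.fucci_phase_counts <- function(object, fractions = FALSE, ...) {
  prefix <- if (fractions) "frac_" else "n_"
  long <- tidyr::pivot_longer(
    as_tibble(object),
    dplyr::all_of(paste0(prefix, c("red", "yellow", "green"))),
    names_to = "phase", values_to = "value",
    names_prefix = prefix
  )
  long$phase <- factor(toupper(long$phase), levels = .VISIBLE_PHASES)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$frame, y = .data$value,
                                     colour = .data$phase)) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::scale_colour_manual(values = .phase_palette, name = "phase") +
    ggplot2::labs(x = "frame",
                  y = if (fractions) "fraction of cells" else "cells",
                  title = if (fractions) "Cell-cycle phase fractions"
                  else "Cell-cycle phase counts") +
    ggplot2::theme_minimal()
}

#' Mean Voronoi area per phase over time with 95% CI ribbons
#'
#' @param object A `fucci_area_by_phase` from [area_by_phase()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.fucci_area_by_phase <- function(object, ...) {
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$frame, y = .data$mean_area,
                                   colour = .data$phase, fill = .data$phase)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$ci_low, ymax = .data$ci_high),
                         alpha = 0.25, colour = NA, na.rm = TRUE) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::scale_colour_manual(values = .phase_palette, name = "phase") +
    ggplot2::scale_fill_manual(values = .phase_palette, name = "phase") +
    ggplot2::labs(x = "frame", y = "mean Voronoi area (px²)",
                  title = "Cell area by cycle phase (95% CI)") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.fucci_velocity_field
#' @export
plot_velocity_field <- function(object, ...) autoplot(object, ...)

#' @rdname autoplot.fucci_phase_counts
#' @export
plot_phase_counts <- function(object, ...) autoplot(object, ...)

#' @rdname autoplot.fucci_area_by_phase
#' @export
plot_area_by_phase <- function(object, ...) autoplot(object, ...)
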
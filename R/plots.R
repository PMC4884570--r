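# ggplot2 views of angiograms, regions and cohort summaries.

#' Plot an angiogram, optionally with the extracted FAZ boundary
#'
#' @param image A [faz_angiogram] object.
#' @param region Optional [faz_region] whose boundary and maximum-diameter
#'   chord are overlaid.
#' @return A ggplot object.
#' @export
plot_angiogram <- function(image, region = NULL) {
  stopifnot(inherits(image, "faz_angiogram"))
  px <- image$pixels
  df <- tidyr::expand_grid(y = seq_len(nrow(px)), x = seq_len(ncol(px)))
  df$value <- as.vector(t(px))
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "black", high = "white", limits = c(0, 1)) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = sprintf("%s (%s layer)", image$eye_id, image$layer),
                  x = "x [px]", y = "y [px]", fill = "flow") +
    ggplot2::theme_minimal()
  if (!is.null(region)) {
    bd <- as.data.frame(region$boundary)
    names(bd) <- c("x", "y")
    md <- max_diameter(region)
    fm <- feret_max(region$boundary)
    chord <- data.frame(x = c(fm$from[1], fm$to[1]), y = c(fm$from[2], fm$to[2]))
    p <- p +
      ggplot2::geom_path(data = bd, ggplot2::aes(.data$x, .data$y),
                         inherit.aes = FALSE, colour = "red") +
      ggplot2::geom_line(data = chord, ggplot2::aes(.data$x, .data$y),
                         inherit.aes = FALSE, colour = "yellow") +
      ggplot2::labs(subtitle = sprintf("max %.0f um at %.1f deg (%s)",
                                       md$length_um, md$angle_deg,
                                       classify_angle(md$angle_deg)))
  }
  p
}

#' @export
autoplot.faz_angiogram <- function(object, ...) plot_angiogram(object, ...)

#' @export
autoplot.faz_region <- function(object, ...) {
  bd <- as.data.frame(object$boundary)
  names(bd) <- c("x", "y")
  ggplot2::ggplot(bd, ggplot2::aes(.data$x, .data$y)) +
    ggplot2::geom_path(colour = "red") +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "x [px]", y = "y [px]") +
    ggplot2::theme_minimal()
}

#' Cohort diameter distributions by group
#'
#' Jittered points with group means, faceted by layer and diameter - the
#' standard view for FAZ-enlargement comparisons.
#'
#' @param measurements Measurement tibble from [measure_cohort()].
#' @return A ggplot object.
#' @export
plot_cohort_diameters <- function(measurements) {
  long <- tidyr::pivot_longer(
    measurements,
    cols = dplyr::any_of(c("horizontal_um", "vertical_um", "max_um", "perp_um")),
    names_to = "diameter", values_to = "um")
  ggplot2::ggplot(long, ggplot2::aes(.data$group, .data$um, colour = .data$group)) +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.6) +
    ggplot2::stat_summary(fun = mean, geom = "point", shape = 18, size = 4,
                          colour = "black") +
    ggplot2::facet_grid(layer ~ diameter) +
    ggplot2::labs(y = "FAZ diameter [um]", x = NULL) +
    ggplot2::theme_bw() +
    ggplot2::theme(legend.position = "none")
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
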
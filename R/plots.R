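#' Plot a niche grid in the PCA plane
#'
#' Occupancy density as filled cells with the 100% (solid) and 75%
#' (dashed) climatic envelopes outlined.
#'
#' @param object a `niche_grid`.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.niche_grid <- function(object, ...) {
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$axis1, .data$axis2)) +
    ggplot2::geom_raster(
      data = dplyr::filter(df, .data$occupancy > 0),
      ggplot2::aes(fill = .data$occupancy)
    ) +
    ggplot2::geom_contour(
      ggplot2::aes(z = as.numeric(.data$in_envelope_100)),
      breaks = 0.5, colour = "grey30", linewidth = 0.4
    ) +
    ggplot2::geom_contour(
      ggplot2::aes(z = as.numeric(.data$in_envelope_75)),
      breaks = 0.5, colour = "grey30", linewidth = 0.4, linetype = "dashed"
    ) +
    ggplot2::scale_fill_viridis_c(name = "occupancy") +
    ggplot2::labs(
      x = "PCA axis 1", y = "PCA axis 2",
      title = paste("Climatic niche:", object$region_id)
    ) +
    ggplot2::theme_minimal()
}

#' Plot a suitability map
#'
#' @param object a [suitability_map()].
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.suitability_map <- function(object, ...) {
  st <- climate_stack(
    list(suitability = object$values),
    object$xmin, object$ymax, object$cell_size
  )
  df <- as_tibble(st)
  ggplot2::ggplot(
    dplyr::filter(df, !is.na(.data$suitability)),
    ggplot2::aes(.data$lon, .data$lat, fill = .data$suitability)
  ) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "longitude", y = "latitude", title = object$provenance) +
    ggplot2::theme_minimal()
}

#' Plot an occupancy profile
#'
#' Normalized suitability mass per covariate bin, with the weighted mean
#' marked.
#'
#' @param object an `occupancy_profile`.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.occupancy_profile <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(
    x = (.data$bin_lo + .data$bin_hi) / 2,
    y = .data$mass
  )) +
    ggplot2::geom_col(width = object$bin_width, fill = "steelblue") +
    ggplot2::geom_vline(
      xintercept = object$weighted_mean,
      linetype = "dashed", colour = "grey20"
    ) +
    ggplot2::labs(
      x = "covariate", y = "suitability mass",
      title = object$source
    ) +
    ggplot2::theme_minimal()
}

#' Overlay two occupancy profiles
#'
#' @param p1,p2 `occupancy_profile`s.
#' @return A ggplot object.
#' @export
plot_profile_comparison <- function(p1, p2) {
  df <- dplyr::bind_rows(tidy(p1), tidy(p2))
  ggplot2::ggplot(df, ggplot2::aes(
    x = (.data$bin_lo + .data$bin_hi) / 2,
    y = .data$mass, fill = .data$source
  )) +
    ggplot2::geom_col(position = "identity", alpha = 0.5, width = p1$bin_width) +
    ggplot2::labs(x = "covariate", y = "suitability mass", fill = NULL) +
    ggplot2::theme_minimal()
}
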
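# ggplot2 views of the result types: trajectories, rasters, risk-class
# maps and PRCC tornado plots.

#' Plot a simulated trajectory
#'
#' Compartment counts over time, one line per compartment.
#'
#' @param object An `irmap_trajectory` from [simulate_model()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.irmap_trajectory <- function(object, ...) {
  tidy(object) |>
    ggplot2::ggplot(ggplot2::aes(x = .data$time, y = .data$count,
                                 colour = .data$compartment)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (days)", y = "individuals",
                  colour = NULL,
                  title = sprintf("S-R-M trajectory (%s)",
                                  attr(object, "model"))) +
    ggplot2::theme_minimal()
}

#' Plot a raster layer
#'
#' Continuous fill over cell centres; nodata cells are blank.
#'
#' @param object An `irmap_raster`.
#' @param ... Unused.
#' @param fill_name Legend title (default "value").
#' @return A ggplot object.
#' @export
autoplot.irmap_raster <- function(object, ..., fill_name = "value") {
  as_tibble(object) |>
    ggplot2::ggplot(ggplot2::aes(x = .data$lon, y = .data$lat,
                                 fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(na.value = "grey90", name = fill_name) +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "longitude", y = "latitude") +
    ggplot2::theme_minimal()
}

#' Plot a risk-class map
#'
#' The map legend used throughout: green (low, R0 < 1), yellow (moderate,
#' 1 <= R0 <= 1.1), red (high, R0 > 1.1).
#'
#' @param classmap An `irmap_raster` of class codes from [classify_map()].
#' @return A ggplot object.
#' @export
plot_risk_map <- function(classmap) {
  stopifnot(inherits(classmap, "irmap_raster"))
  as_tibble(classmap) |>
    dplyr::mutate(risk = factor(.data$value, levels = 1:3,
                                labels = c("low", "moderate", "high"))) |>
    ggplot2::ggplot(ggplot2::aes(x = .data$lon, y = .data$lat,
                                 fill = .data$risk)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_manual(
      values = c(low = "#1a9850", moderate = "#fee08b", high = "#d73027"),
      na.value = "grey90", name = "resistance risk", drop = FALSE) +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "longitude", y = "latitude") +
    ggplot2::theme_minimal()
}

#' Tornado plot of partial rank correlation coefficients
#'
#' Parameters ordered by |PRCC|, bars signed.
#'
#' @param object An `irmap_prcc` from [prcc()] or [r0_prcc()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.irmap_prcc <- function(object, ...) {
  df <- dplyr::arrange(tibble::as_tibble(object), abs(.data$prcc))
  df$parameter <- factor(df$parameter, levels = df$parameter)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$prcc, y = .data$parameter,
                                   fill = .data$prcc > 0)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::geom_vline(xintercept = 0, linewidth = 0.3) +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "#2166ac",
                                          `FALSE` = "#b2182b")) +
    ggplot2::labs(x = "PRCC", y = NULL,
                  title = "Sensitivity of R0 (partial rank correlation)") +
    ggplot2::theme_minimal()
}
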
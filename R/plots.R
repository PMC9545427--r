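#' Plot a capillary oxygen profile
#'
#' Saturation, tension and total content against axial position.
#'
#' @param object A [capillary_profile()].
#' @param ... Unused.
#' @return A ggplot object (facets for SO2, PO2 and content).
#' @export
autoplot.capillary_profile <- function(object, ...) {
  long <- tibble::as_tibble(object) |>
    tidyr::pivot_longer(-"z_m", names_to = "quantity", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$z_m * 1e3, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~quantity, scales = "free_y") +
    ggplot2::labs(
      x = "axial position (mm)", y = NULL,
      title = paste0("Capillary profile (", attr(object, "state_label"), ")")
    )
}

#' Plot a tissue oxygen field
#'
#' Tissue PO2 over the radius x axial-position grid.
#'
#' @param object A [tissue_field()].
#' @param ... Unused.
#' @return A ggplot raster of PO2 (mmHg).
#' @export
autoplot.tissue_field <- function(object, ...) {
  ggplot2::ggplot(tidy.tissue_field(object),
                  ggplot2::aes(x = .data$z_m * 1e3, y = .data$r_m * 1e6,
                               fill = .data$po2_mmhg)) +
    ggplot2::geom_raster() +
    ggplot2::labs(x = "axial position (mm)", y = "radius (um)",
                  fill = "PO2 (mmHg)",
                  title = paste0("Tissue oxygen field (", object$state_label, ")"))
}

#' Plot voxel R1 change against a sweep variable
#'
#' @param x A `"sweep_table"` from [run_sweep()].
#' @param var Variable for the x axis (default `"oef"`).
#' @return A ggplot object, coloured by blood volume and faceted by field
#'   strength.
#' @export
plot_sweep <- function(x, var = "oef") {
  ggplot2::ggplot(
    dplyr::filter(x, .data$feasible),
    ggplot2::aes(x = .data[[var]], y = .data$delta_r1_voxel,
                 colour = factor(.data$bv))) +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~b0, labeller = ggplot2::label_both) +
    ggplot2::labs(y = "voxel dR1 (1/s)", colour = "BV")
}
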
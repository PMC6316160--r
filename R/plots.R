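# ggplot2 presentation layers for the main result types.

#' Plot a spectrum
#'
#' @param spectrum Spectrum tibble (Raman `wavenumber`/`intensity` or UV-Vis
#'   `wavelength`/`absorbance`).
#' @return A ggplot object.
#' @export
plot_spectrum <- function(spectrum) {
  if ("wavenumber" %in% names(spectrum)) {
    ggplot2::ggplot(spectrum,
                    ggplot2::aes(x = .data$wavenumber, y = .data$intensity)) +
      ggplot2::geom_line() +
      ggplot2::labs(x = "Raman shift (cm⁻¹)", y = "Intensity (counts)")
  } else {
    ggplot2::ggplot(spectrum,
                    ggplot2::aes(x = .data$wavelength, y = .data$absorbance)) +
      ggplot2::geom_line() +
      ggplot2::labs(x = "Wavelength (nm)", y = "Absorbance (AU)")
  }
}

#' Plot a reconstructed band-intensity image
#'
#' @param image Tibble from [reconstruct_image()].
#' @return A ggplot object (tile map; pale yellow = highest intensity,
#'   dark brown = lowest, the usual SERS map palette).
#' @export
plot_map_image <- function(image) {
  ggplot2::ggplot(image, ggplot2::aes(x = .data$x_um, y = .data$y_um,
                                      fill = .data$intensity)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "#3b1f0b", high = "#ffef9f") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (µm)", y = "y (µm)",
                  fill = "I (counts/s)")
}

#' @rdname summarize_uptake
#' @param object An `uptake_summary`.
#' @export
autoplot.uptake_summary <- function(object, ...) {
  g <- object$groups
  ggplot2::ggplot(g, ggplot2::aes(x = factor(.data$time_h), y = .data$mean,
                                  fill = .data$cell_line)) +
    ggplot2::geom_col(position = ggplot2::position_dodge(width = 0.8),
                      width = 0.7) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean - .data$sem,
                   ymax = .data$mean + .data$sem),
      position = ggplot2::position_dodge(width = 0.8), width = 0.2) +
    ggplot2::labs(x = "Incubation time (h)",
                  y = expression(I[1078] ~ "(counts/s)"),
                  fill = "Cell line")
}

#' @rdname population_stats
#' @param object A `population_stats` object.
#' @export
autoplot.population_stats <- function(object, ...) {
  ggplot2::ggplot(object$histogram,
                  ggplot2::aes(x = .data$mid, y = .data$count)) +
    ggplot2::geom_col(width = diff(object$histogram$mid[1:2]),
                      fill = "grey40") +
    ggplot2::labs(x = "Equivalent diameter (nm)", y = "Count")
}
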
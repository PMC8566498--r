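# ggplot2 displays for spectra, chromatograms, ion images and labeling fits.

#' Plot a centroid MS/MS spectrum
#'
#' @param spectrum Tibble with `mz`, `intensity`; an optional `label` column
#'   annotates matched fragments.
#' @return A ggplot object.
#' @export
plot_spectrum <- function(spectrum) {
  p <- ggplot2::ggplot(
    spectrum,
    ggplot2::aes(x = .data$mz, ymax = .data$intensity, ymin = 0)
  ) +
    ggplot2::geom_linerange() +
    ggplot2::labs(x = "m/z", y = "intensity") +
    ggplot2::theme_classic()
  if ("label" %in% names(spectrum)) {
    p <- p + ggplot2::geom_text(
      data = spectrum[!is.na(spectrum$label), ],
      ggplot2::aes(y = .data$intensity, label = .data$label),
      vjust = -0.4, size = 2.8
    )
  }
  p
}

#' Plot an extracted ion chromatogram
#'
#' @param eic Output of [extract_eic()].
#' @return A ggplot object.
#' @export
plot_eic <- function(eic) {
  ggplot2::ggplot(eic, ggplot2::aes(x = .data$rt, y = .data$intensity)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "retention time (min)", y = "intensity") +
    ggplot2::theme_classic()
}

#' Plot an ion image on the 0-100 pseudocolor scale
#'
#' Rescales through [render_ion_image()] and draws a raster with a
#' black-to-yellow gradient fixed to \[0, 100\].
#'
#' @param grid MSI intensity matrix.
#' @return A ggplot object.
#' @export
plot_ion_image <- function(grid) {
  img <- render_ion_image(grid)
  df <- tibble::tibble(
    row = rep(seq_len(nrow(img)), times = ncol(img)),
    col = rep(seq_len(ncol(img)), each = nrow(img)),
    value = as.vector(img)
  )
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$col, y = .data$row,
    fill = .data$value
  )) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradientn(
      colours = c("black", "blue", "red", "yellow"),
      limits = c(0, 100), name = "intensity"
    ) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::theme_void()
}

#' @export
autoplot.oxpc_labeling_fit <- function(object, ...) {
  df <- tibble::tibble(
    k = seq_along(object$envelope) - 1L,
    intensity = object$envelope
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$k, y = .data$intensity)) +
    ggplot2::geom_col() +
    ggplot2::labs(
      x = "heavy oxygens per molecule", y = "intensity",
      title = sprintf("labeling efficiency %.1f%%", 100 * object$p_hat)
    ) +
    ggplot2::theme_classic()
}
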
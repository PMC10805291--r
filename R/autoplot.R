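# ggplot2 methods for the package's tabular result types.

#' @exportS3Method ggplot2::autoplot
autoplot.qc_spectrum <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$wavelength, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Wavelength (nm)", y = attr(object, "kind")) +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.channel_set <- function(object, ...) {
  ggplot2::ggplot(
    as_tibble(object),
    ggplot2::aes(x = .data$wavelength, y = .data$value,
                 colour = .data$channel)
  ) +
    ggplot2::geom_line() +
    ggplot2::labs(
      x = "Wavelength (nm)",
      y = if (object$relativized) "Relative sensitivity" else "Sensitivity",
      title = object$name
    ) +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.sensitivity_estimate <- function(object, ...) {
  autoplot(object$channel_set) +
    ggplot2::labs(title = "Estimated sensor sensitivity")
}

#' @exportS3Method ggplot2::autoplot
autoplot.catch_eval <- function(object, ...) {
  long <- tidyr::pivot_longer(
    dplyr::select(object, "receptor", "r_squared", "mape", "rmspe"),
    -"receptor", names_to = "metric", values_to = "value"
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$receptor, y = .data$value)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::theme_minimal()
}

#' Plot an image plane
#'
#' Renders an `image_plane` as a raster. Catch-domain images should be gamma
#' corrected first (see [display_gamma()]).
#'
#' @param x An `image_plane` with 1 or 3 channels, values in \[0, 1\].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot_image <- function(x, ...) {
  a <- pmin(pmax(as_bare_array(x), 0), 1)
  d <- dim(a)
  hex <- if (d[3] >= 3) {
    grDevices::rgb(a[, , 1], a[, , 2], a[, , 3])
  } else {
    grDevices::gray(a[, , 1])
  }
  df <- tibble(
    x = rep(seq_len(d[2]), each = d[1]),
    y = rep(seq_len(d[1]), times = d[2]),
    fill = as.character(hex)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$fill)) +
    ggplot2::scale_fill_identity() +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::theme_void()
}
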
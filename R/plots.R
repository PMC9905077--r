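# Plotting: slice display and ggplot2 autoplot methods for tabular results.

#' Display one axial slice of a volume
#'
#' @param volume [cect_volume()] or 3D array.
#' @param z Slice index (default: middle).
#' @param ... Passed to [graphics::image()].
#' @export
plot_slice <- function(volume, z = NULL, ...) {
  arr <- as_volume_array(volume)
  if (is.null(z)) z <- ceiling(dim(arr)[3] / 2)
  graphics::image(arr[, , z], col = grDevices::gray.colors(256, 0, 1),
                  asp = 1, axes = FALSE, useRaster = TRUE, ...)
  invisible(volume)
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a thickness histogram
#'
#' Bars of the percentage of structure voxels per thickness range, with the
#' bin midpoint on the x axis.
#'
#' @param object A `thickness_histogram`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.thickness_histogram <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$midpoint_mm, y = .data$percent)) +
    ggplot2::geom_col(width = min(diff(object$midpoint_mm), na.rm = TRUE) *
                        0.9, fill = "grey35") +
    ggplot2::labs(x = "thickness (mm, bin midpoint)",
                  y = "% of structure volume") +
    ggplot2::theme_minimal()
}

#' Plot a trauma report
#'
#' Traumatized percentage of the pre-insertion volume per structure,
#' colored by Eshraghi grade.
#'
#' @param object A `trauma_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.trauma_report <- function(object, ...) {
  df <- object[order(-object$percent_of_pre), ]
  ggplot2::ggplot(df, ggplot2::aes(
    x = stats::reorder(.data$structure, -.data$percent_of_pre),
    y = .data$percent_of_pre, fill = factor(.data$grade))) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "% of pre-insertion structure volume",
                  fill = "Eshraghi grade") +
    ggplot2::theme_minimal()
}

#' @importFrom rlang .data
NULL
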
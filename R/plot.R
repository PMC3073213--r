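#' Plot the accumulated explained variance of a spectral PCA
#'
#' @param object a [fit_spectral_pca()] result.
#' @param ... ignored.
#' @return A ggplot: % accumulated variance against the number of eigenvectors,
#'   with the basis default `m` marked.
#' @method autoplot spectral_pca
#' @export
autoplot.spectral_pca <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$component, y = 100 * .data$cumulative)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = object$m, linetype = "dashed") +
    ggplot2::labs(
      x = "number of PC vectors (m)",
      y = "% accumulated variance"
    )
}

#' Plot a mean spectral-error curve with the selected band pair
#'
#' @param object a [select_band_pair()] result.
#' @param ... ignored.
#' @return A ggplot of the per-band mean error with bands r and s highlighted.
#' @method autoplot band_pair
#' @export
autoplot.band_pair <- function(object, ...) {
  df <- band_error_table(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$band, y = .data$mean_error)) +
    ggplot2::geom_hline(yintercept = 0, color = "grey60") +
    ggplot2::geom_line() +
    ggplot2::geom_point(ggplot2::aes(color = .data$role), size = 2) +
    ggplot2::scale_color_manual(
      values = c(r = "firebrick", s = "navy"), na.value = "black",
      breaks = c("r", "s")
    ) +
    ggplot2::labs(x = "band", y = "mean spectral error", color = "pair")
}

raster_df <- function(mat) {
  data.frame(
    row = as.vector(row(mat)),
    col = as.vector(col(mat)),
    value = as.vector(mat)
  )
}

#' Plot the d-map of a residual map
#'
#' @param object a [residual_map()].
#' @param ... ignored.
#' @return A ggplot raster of `d = e_r - e_s`.
#' @method autoplot residual_map
#' @export
autoplot.residual_map <- function(object, ...) {
  df <- raster_df(object$dmap)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::scale_fill_gradient2(low = "navy", mid = "white", high = "firebrick") +
    ggplot2::labs(
      x = NULL, y = NULL,
      fill = sprintf("d = e%d - e%d", object$band_pair$r, object$band_pair$s)
    )
}

#' Plot a segmentation mask
#'
#' @param object a `segmentation_mask`.
#' @param ... ignored.
#' @return A ggplot raster of the binary mask.
#' @method autoplot segmentation_mask
#' @export
autoplot.segmentation_mask <- function(object, ...) {
  df <- raster_df(object$binary * 1)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row, fill = .data$value > 0)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey90", `TRUE` = "firebrick")) +
    ggplot2::labs(x = NULL, y = NULL, fill = "segmented")
}

#' Plot an RGB rendering
#'
#' @param object an [render_rgb()] result.
#' @param ... ignored.
#' @return A ggplot raster of the RGB image.
#' @method autoplot rgb_rendering
#' @export
autoplot.rgb_rendering <- function(object, ...) {
  img <- object$image
  df <- raster_df(img[, , 1L])
  df$hex <- grDevices::rgb(img[, , 1L], img[, , 2L], img[, , 3L])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row, fill = .data$hex)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_identity() +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = NULL, y = NULL)
}

#' @importFrom ggplot2 .data
NULL
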
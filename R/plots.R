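# Plotting helpers (ggplot2). Images are drawn with row 1 at the top,
# matching the storage convention.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom rlang .data
NULL

raster_df <- function(m, value_name = "value") {
  tibble(
    row = as.vector(row(m)),
    col = as.vector(col(m)),
    value = as.vector(m * 1)
  )
}

#' Plot a mammogram with optional mask overlay
#'
#' @param image A `mammogram` or numeric matrix.
#' @param mask Optional logical mask drawn as a translucent overlay.
#' @param mask_color Overlay colour.
#' @return A ggplot.
#' @export
plot_mammogram <- function(image, mask = NULL, mask_color = "red") {
  px <- as_pixels(image)
  p <- ggplot2::ggplot(raster_df(px), ggplot2::aes(.data$col, .data$row)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$value)) +
    ggplot2::scale_fill_gradient(low = "black", high = "white", guide = "none") +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::theme_void()
  if (!is.null(mask)) {
    df <- raster_df(as_mask(mask))
    df <- df[df$value > 0, ]
    p <- p + ggplot2::geom_raster(data = df, fill = mask_color, alpha = 0.35)
  }
  p
}

#' Plot a phantom bundle
#'
#' Shows the phantom image with the gland truth overlaid.
#'
#' @param object A `phantom_bundle`.
#' @param show `"gland"`, `"calc_region"`, `"pectoral"` or `"vessels"`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.phantom_bundle <- function(object, show = "gland", ...) {
  mask <- switch(show,
    gland = object$gland_truth,
    calc_region = object$calc_region,
    pectoral = object$pectoral,
    vessels = object$vessels,
    stop_validation("unknown `show` layer")
  )
  plot_mammogram(object$image, mask) +
    ggplot2::labs(title = sprintf("%s phantom, content ratio %.2f (%s)",
                                  object$spec$laterality,
                                  object$measured_ratio, object$category))
}
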
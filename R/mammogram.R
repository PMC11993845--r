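#' @useDynLib glandseg, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom rlang abort %||%
#' @importFrom tibble tibble as_tibble
#' @importFrom generics tidy glance
NULL

# internal condition helpers ---------------------------------------------------

stop_validation <- function(msg, ...) {
  abort(msg, class = c("glandseg_validation_error", "glandseg_error"), ...)
}

stop_empty_region <- function(msg) {
  abort(msg, class = c("glandseg_empty_region_error", "glandseg_error"))
}

check_same_dim <- function(a, b, what = "inputs") {
  if (!identical(dim(a), dim(b))) {
    stop_validation(sprintf(
      "%s must share the same pixel grid (got %s vs %s)",
      what, paste(dim(a), collapse = "x"), paste(dim(b), collapse = "x")
    ))
  }
  invisible(TRUE)
}

#' Maximum representable intensity for a bit depth
#'
#' @param bit_depth Integer number of bits per pixel.
#' @return `2^bit_depth - 1` as a double.
#' @export
max_intensity <- function(bit_depth) 2^bit_depth - 1

# mammogram container ----------------------------------------------------------

#' Create a mammogram object
#'
#' A mammogram is a grayscale pixel matrix (rows = image rows, columns =
#' image columns) with integer intensities in `[0, 2^bit_depth - 1]`, plus
#' laterality metadata. The MLO convention used throughout the package is
#' portrait orientation (height >= width) with the chest wall flush against
#' the lateral image edge named by `laterality`.
#'
#' @param pixels Numeric matrix of intensities.
#' @param bit_depth Bits per pixel, between 8 and 16 (clinical detectors
#'   commonly store 14-bit data).
#' @param laterality `"left"` or `"right"`, or `NA` when unknown.
#' @return An object of class `mammogram`.
#' @export
mammogram <- function(pixels, bit_depth = 14L, laterality = NA_character_) {
  if (!is.matrix(pixels) || !is.numeric(pixels)) {
    stop_validation("`pixels` must be a numeric matrix")
  }
  if (length(bit_depth) != 1 || is.na(bit_depth) || bit_depth < 8 || bit_depth > 16) {
    stop_validation("`bit_depth` must be a single value between 8 and 16")
  }
  if (!is.na(laterality) && !laterality %in% c("left", "right")) {
    stop_validation('`laterality` must be "left", "right" or NA')
  }
  if (any(pixels < 0, na.rm = TRUE) || any(pixels > max_intensity(bit_depth), na.rm = TRUE)) {
    stop_validation("pixel values outside the representable intensity range")
  }
  structure(
    list(pixels = pixels, bit_depth = as.integer(bit_depth), laterality = laterality),
    class = "mammogram"
  )
}

#' @export
print.mammogram <- function(x, ...) {
  cat(sprintf(
    "<mammogram> %d x %d, %d-bit, laterality: %s, intensity range [%g, %g]\n",
    nrow(x$pixels), ncol(x$pixels), x$bit_depth,
    ifelse(is.na(x$laterality), "unknown", x$laterality),
    min(x$pixels), max(x$pixels)
  ))
  invisible(x)
}

#' @export
dim.mammogram <- function(x) dim(x$pixels)

is_mammogram <- function(x) inherits(x, "mammogram")

as_pixels <- function(image) {
  if (is_mammogram(image)) image$pixels else image
}

# masks ------------------------------------------------------------------------

#' Coerce to a binary region mask
#'
#' Region masks are logical matrices on the image grid (`TRUE` = foreground).
#' Numeric input is thresholded at > 0.
#'
#' @param x Logical or numeric matrix.
#' @return Logical matrix.
#' @export
as_mask <- function(x) {
  if (!is.matrix(x)) stop_validation("a region mask must be a matrix")
  if (is.logical(x)) return(x)
  x > 0
}

#' Mirror an image or mask horizontally
#'
#' Reverses the column order, flipping the chest-wall side. Mammogram
#' laterality metadata is preserved (it describes the breast, not the
#' current display side).
#'
#' @param x A `mammogram`, matrix or logical mask.
#' @return Same type as the input.
#' @export
flip_horizontal <- function(x) {
  if (is_mammogram(x)) {
    x$pixels <- x$pixels[, rev(seq_len(ncol(x$pixels))), drop = FALSE]
    return(x)
  }
  x[, rev(seq_len(ncol(x))), drop = FALSE]
}

# file IO ----------------------------------------------------------------------

#' Write a mammogram to disk
#'
#' Pixel data is stored as 16-bit grayscale TIFF, value-ranged (intensities
#' divided by `2^bit_depth - 1`), with a JSON sidecar (`<path>.json`)
#' recording bit depth, laterality and the stored maximum.
#'
#' @param image A `mammogram`.
#' @param path Output file path (`.tif`/`.tiff`).
#' @return `path`, invisibly.
#' @export
write_mammogram <- function(image, path) {
  stopifnot(is_mammogram(image))
  vmax <- max_intensity(image$bit_depth)
  tiff::writeTIFF(image$pixels / vmax, path, bits.per.sample = 16L)
  jsonlite::write_json(
    list(
      bit_depth = image$bit_depth,
      laterality = image$laterality,
      stored_max = max(image$pixels)
    ),
    paste0(path, ".json"),
    auto_unbox = TRUE
  )
  invisible(path)
}

#' Read a mammogram written by [write_mammogram()]
#'
#' @param path TIFF file path; the JSON sidecar must sit next to it.
#' @return A `mammogram`.
#' @export
read_mammogram <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"))
  v <- tiff::readTIFF(path)
  if (length(dim(v)) == 3) v <- v[, , 1]
  vmax <- max_intensity(meta$bit_depth)
  mammogram(round(v * vmax), bit_depth = meta$bit_depth,
            laterality = meta$laterality %||% NA_character_)
}

#' Write a binary mask as an 8-bit PNG
#'
#' Foreground is stored as 255, background as 0.
#'
#' @param mask Logical matrix.
#' @param path Output PNG path.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  mask <- as_mask(mask)
  png::writePNG(mask * 1, path)
  invisible(path)
}

#' Read a binary mask PNG
#'
#' @param path PNG path.
#' @return Logical matrix.
#' @export
read_mask <- function(path) {
  v <- png::readPNG(path)
  if (length(dim(v)) == 3) v <- v[, , 1]
  v > 0.5
}
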
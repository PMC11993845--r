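# Preprocessing for network input: bit-depth reduction, symmetric padding
# to a square, nearest-neighbour resizing, orientation-dataset variants and
# train/validation/test splitting.

#' Preprocessing configuration
#'
#' @param out_size Output side length in pixels (default 256, the network
#'   input size used throughout).
#' @param out_bits Output bit depth (default 8).
#' @param pad_value Intensity used for the lateral padding (default 0).
#' @param interpolation Only `"nearest"` is supported; nearest-neighbour
#'   resizing keeps mask label sets intact.
#' @return A `preprocess_config` list.
#' @export
preprocess_config <- function(out_size = 256L, out_bits = 8L, pad_value = 0,
                              interpolation = "nearest") {
  if (out_size < 16) stop_validation("`out_size` must be at least 16")
  interpolation <- match.arg(interpolation, "nearest")
  structure(
    list(out_size = as.integer(out_size), out_bits = as.integer(out_bits),
         pad_value = pad_value, interpolation = interpolation),
    class = "preprocess_config"
  )
}

# symmetric lateral pad to a square; widths differ by at most one pixel
pad_to_square <- function(m, pad_value) {
  H <- nrow(m)
  W <- ncol(m)
  total <- H - W
  left <- floor(total / 2)
  right <- total - left
  cbind(
    matrix(pad_value, H, left),
    m,
    matrix(pad_value, H, right)
  )
}

# pixel-centre nearest-neighbour resampling
resize_nearest <- function(m, out_rows, out_cols) {
  ri <- pmin(pmax(ceiling((seq_len(out_rows) - 0.5) * nrow(m) / out_rows), 1), nrow(m))
  ci <- pmin(pmax(ceiling((seq_len(out_cols) - 0.5) * ncol(m) / out_cols), 1), ncol(m))
  m[ri, ci, drop = FALSE]
}

#' Preprocess a mammogram for network input
#'
#' Three steps: (1) intensities are linearly rescaled from the input bit
#' range to the output bit range (`value * (2^out_bits - 1) / (2^in_bits - 1)`,
#' rounded); (2) the portrait image is padded equally on both lateral edges
#' with `pad_value` to a square; (3) nearest-neighbour resize to
#' `out_size x out_size`. Padding precedes resizing so the breast keeps its
#' aspect ratio.
#'
#' @param image A `mammogram` (portrait: height >= width).
#' @param cfg A [preprocess_config()].
#' @return A `mammogram` of size `out_size x out_size` at `out_bits`.
#' @export
preprocess_mammogram <- function(image, cfg = preprocess_config()) {
  stopifnot(is_mammogram(image), inherits(cfg, "preprocess_config"))
  if (ncol(image$pixels) > nrow(image$pixels)) {
    stop_validation("non-portrait input: width exceeds height")
  }
  if (cfg$out_bits > image$bit_depth) {
    stop_validation("`out_bits` exceeds the input bit depth")
  }
  scale <- max_intensity(cfg$out_bits) / max_intensity(image$bit_depth)
  m <- round(image$pixels * scale)
  m <- pad_to_square(m, cfg$pad_value)
  m <- resize_nearest(m, cfg$out_size, cfg$out_size)
  mammogram(m, bit_depth = cfg$out_bits, laterality = image$laterality)
}

#' Preprocess a mask alongside its mammogram
#'
#' Applies the same pad and nearest-neighbour resize as
#' [preprocess_mammogram()] but no intensity step; the output is strictly
#' binary. Padding uses background (`FALSE`).
#'
#' @param mask Logical mask (portrait grid).
#' @param cfg A [preprocess_config()].
#' @return Logical `out_size x out_size` mask.
#' @export
preprocess_mask <- function(mask, cfg = preprocess_config()) {
  mask <- as_mask(mask)
  if (ncol(mask) > nrow(mask)) {
    stop_validation("non-portrait input: width exceeds height")
  }
  m <- pad_to_square(mask, FALSE)
  resize_nearest(m, cfg$out_size, cfg$out_size)
}

#' Orient an image/mask pair for one of the four dataset layouts
#'
#' Dataset modes: mode 1 aligns every image with the chest wall on the
#' left; mode 2 keeps the anatomical layout (chest wall on the laterality
#' side); modes 3 and 4 start from modes 1 and 2 respectively and then
#' apply a horizontal flip with probability `flip_probability` (the
#' augmentation "with random proportions"). Image and mask always flip
#' together. Modes 2 and 4 require laterality metadata.
#'
#' @param image A `mammogram` with chest wall on its laterality side.
#' @param mask Logical mask on the same grid.
#' @param mode Integer 1-4.
#' @param flip_probability Per-image flip probability for modes 3/4
#'   (default 0.5).
#' @return List with `image`, `mask` and `flipped` (logical).
#' @export
orient_pair <- function(image, mask, mode, flip_probability = 0.5) {
  stopifnot(is_mammogram(image))
  mask <- as_mask(mask)
  check_same_dim(image$pixels, mask, "image and mask")
  if (!mode %in% 1:4) stop_validation("`mode` must be 1, 2, 3 or 4")
  if (mode %in% c(2, 4) && is.na(image$laterality)) {
    stop_validation("modes 2 and 4 require laterality metadata")
  }
  if (flip_probability < 0 || flip_probability >= 1) {
    stop_validation("`flip_probability` must be in [0, 1)")
  }
  base_mode <- ifelse(mode %in% c(1, 3), 1L, 2L)
  flip <- FALSE
  if (base_mode == 1L) {
    # chest wall on the left for all; laterality-right phantoms are mirrored
    if (is.na(image$laterality)) {
      stop_validation("mode 1 alignment requires laterality metadata")
    }
    flip <- image$laterality == "right"
  }
  random_flip <- mode %in% c(3, 4) && stats::runif(1) < flip_probability
  do_flip <- xor(flip, random_flip)
  if (do_flip) {
    image <- flip_horizontal(image)
    mask <- flip_horizontal(mask)
  }
  list(image = image, mask = mask, flipped = do_flip)
}

#' Split a manifest into train / validation / test
#'
#' Seeded random, disjoint and exhaustive. Sizes are the fractions times
#' the manifest size, largest-remainder rounded so they always sum to the
#' total (670 images at the study proportions give 530/70/70).
#'
#' @param manifest A data frame (one row per image).
#' @param fractions Numeric length-3 vector summing to 1, in the order
#'   train, validation, test.
#' @param seed Integer seed.
#' @return The manifest as a tibble with an added `split` factor column.
#' @export
split_dataset <- function(manifest, fractions = c(530, 70, 70) / 670, seed = 1L) {
  manifest <- as_tibble(manifest)
  n <- nrow(manifest)
  if (abs(sum(fractions) - 1) > 1e-8 || length(fractions) != 3 || any(fractions < 0)) {
    stop_validation("`fractions` must be three nonnegative values summing to 1")
  }
  if (n < sum(fractions > 0)) {
    stop_validation("fewer images than requested splits")
  }
  raw <- fractions * n
  sizes <- floor(raw)
  rem <- n - sum(sizes)
  if (rem > 0) {
    order_frac <- order(raw - sizes, decreasing = TRUE)
    sizes[order_frac[seq_len(rem)]] <- sizes[order_frac[seq_len(rem)]] + 1
  }
  idx <- withr::with_seed(seed, sample.int(n))
  split <- character(n)
  split[idx[seq_len(sizes[1])]] <- "train"
  if (sizes[2] > 0) split[idx[sizes[1] + seq_len(sizes[2])]] <- "validation"
  if (sizes[3] > 0) split[idx[sizes[1] + sizes[2] + seq_len(sizes[3])]] <- "test"
  manifest$split <- factor(split, levels = c("train", "validation", "test"))
  manifest
}
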
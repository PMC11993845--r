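# Synthetic MLO phantom generator. Clinical mammograms with physician
# ground truth are private, so every downstream stage is exercised on
# phantoms that reproduce the geometry the pipeline cares about: a breast
# contour against the chest-wall edge, a pectoral wedge of gland-like
# brightness, a subcutaneous fat rim, bright curvilinear vessels, and a
# gland region whose area fraction of the calculation region is exact.

#' Phantom generation parameters
#'
#' @param height,width Image size in pixels; portrait (height >= width)
#'   following the MLO convention.
#' @param bit_depth Container bit depth, 8-16 (default 14, matching common
#'   clinical detectors).
#' @param laterality `"left"` or `"right"`; the chest wall sits flush
#'   against that image edge.
#' @param target_content_ratio Desired gland area fraction of the
#'   calculation region, in `[0, 1]`. Zero produces an "unmasked"
#'   (gland-free) phantom.
#' @param vessel_count Number of vessel-like bright curves.
#' @param noise_sd Standard deviation of additive Gaussian intensity noise,
#'   in raw intensity units (default about 1% of the 14-bit range).
#' @param seed Integer seed; phantom generation is fully deterministic
#'   given the spec.
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(height = 256L, width = 192L, bit_depth = 14L,
                         laterality = "left", target_content_ratio = 0.3,
                         vessel_count = 3L, noise_sd = 164, seed = 1L) {
  if (height < width) stop_validation("portrait MLO convention requires height >= width")
  if (height < 32 || width < 24) stop_validation("phantom dimensions too small")
  if (bit_depth < 8 || bit_depth > 16) stop_validation("`bit_depth` must be in 8..16")
  if (!laterality %in% c("left", "right")) stop_validation('`laterality` must be "left" or "right"')
  if (!is.numeric(target_content_ratio) || length(target_content_ratio) != 1 ||
      is.na(target_content_ratio) ||
      target_content_ratio < 0 || target_content_ratio > 1) {
    stop_validation("`target_content_ratio` must be a single value in [0, 1]")
  }
  if (vessel_count < 0) stop_validation("`vessel_count` must be nonnegative")
  if (noise_sd < 0) stop_validation("`noise_sd` must be nonnegative")
  structure(
    list(
      height = as.integer(height), width = as.integer(width),
      bit_depth = as.integer(bit_depth), laterality = laterality,
      target_content_ratio = target_content_ratio,
      vessel_count = as.integer(vessel_count),
      noise_sd = noise_sd, seed = as.integer(seed)
    ),
    class = "phantom_spec"
  )
}

normalize01 <- function(x) {
  r <- range(x)
  if (r[2] == r[1]) return(x * 0)
  (x - r[1]) / (r[2] - r[1])
}

smooth_field <- function(height, width, sigma) {
  f <- matrix(stats::rnorm(height * width), height, width)
  as.matrix(EBImage::imageData(EBImage::gblur(f, sigma = sigma)))
}

dilate_mask <- function(mask, size) {
  if (!any(mask)) return(mask)
  br <- EBImage::makeBrush(size, shape = "disc")
  as.matrix(EBImage::imageData(EBImage::dilate(mask * 1, br))) > 0.5
}

# rasterize a quadratic Bezier curve onto a logical matrix
draw_curve <- function(mask, p0, p1, p2) {
  t <- seq(0, 1, length.out = 4L * nrow(mask))
  x <- (1 - t)^2 * p0[1] + 2 * t * (1 - t) * p1[1] + t^2 * p2[1]
  y <- (1 - t)^2 * p0[2] + 2 * t * (1 - t) * p1[2] + t^2 * p2[2]
  i <- pmin(pmax(round(y), 1), nrow(mask))
  j <- pmin(pmax(round(x), 1), ncol(mask))
  mask[cbind(i, j)] <- TRUE
  mask
}

#' Generate a synthetic MLO phantom
#'
#' Produces an image plus exact ground-truth masks. Geometry (left
#' laterality; mirrored for right): a half-ellipse breast against the left
#' edge, a triangular pectoral wedge in the upper chest-wall corner, and a
#' subcutaneous fat rim along the outer breast contour. The calculation
#' region is the breast interior excluding rim and pectoral wedge. The
#' gland is the top area-fraction of a smoothed random field inside the
#' calculation region, cut at the exact order statistic so the measured
#' content ratio equals the target up to rounding of a single pixel; at mid
#' ratios this yields scattered island-like morphology. Intensity bands (as
#' fractions of the intensity maximum): background ~0.02, fat 0.22-0.30,
#' pectoral 0.53-0.57, vessels ~0.66, gland 0.60-0.76 — gland is sampled at
#' or above the pectoral mean, mirroring the density-based gland
#' definition. Vessels are drawn only where they remain separable from the
#' gland (vessels overlying dense gland are indistinguishable by intensity
#' and are not modelled).
#'
#' @param spec A [phantom_spec()].
#' @return A `phantom_bundle`: list with `image` (a `mammogram`),
#'   `gland_truth`, `calc_region`, `pectoral`, `vessels`, `breast` masks,
#'   the `spec`, `measured_ratio`, `category`, `grouping` and `unmasked`.
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  H <- spec$height
  W <- spec$width
  vmax <- max_intensity(spec$bit_depth)

  withr::with_seed(spec$seed, {
    tmpl <- matrix(0, H, W)
    y <- row(tmpl)
    x <- col(tmpl)

    # geometry in a left-lateral frame
    bx <- 0.80 * W
    by <- 0.46 * H
    cy <- 0.48 * H
    r2 <- ((x - 1) / bx)^2 + ((y - cy) / by)^2
    breast <- r2 <= 1
    pect <- breast & ((x / (0.40 * W)) + (y / (0.52 * H)) <= 1)
    pect_margin <- dilate_mask(pect, 7)
    rim <- breast & r2 > (1 - 0.16)^2
    calc <- breast & !rim & !pect_margin
    n_calc <- sum(calc)

    # gland: exact order-statistic cut of a smoothed random field
    gland_field <- normalize01(smooth_field(H, W, sigma = max(4, round(min(H, W) / 24))))
    k <- round(spec$target_content_ratio * n_calc)
    if (k > 0) {
      cut_val <- sort(gland_field[calc], decreasing = TRUE)[k]
      gland <- calc & gland_field >= cut_val
    } else {
      cut_val <- Inf
      gland <- calc & FALSE
    }

    # vessels: bright curves from near the chest wall across the breast,
    # kept clear of the gland so they form distinct connected components
    vessels <- matrix(FALSE, H, W)
    for (v in seq_len(spec$vessel_count)) {
      p0 <- c(stats::runif(1, 0.03, 0.12) * W, cy + stats::runif(1, -0.6, 0.6) * by)
      theta <- stats::runif(1, -0.9, 0.9)
      p2 <- c(1 + 0.9 * bx * cos(theta), cy + 0.9 * by * sin(theta))
      mid <- (p0 + p2) / 2
      perp <- c(-(p2[2] - p0[2]), p2[1] - p0[1])
      perp <- perp / sqrt(sum(perp^2) + 1e-12)
      p1 <- mid + perp * stats::runif(1, -0.2, 0.2) * min(H, W)
      vessels <- draw_curve(vessels, p0, p1, p2)
    }
    vessels <- dilate_mask(vessels, 3) & breast & !pect_margin
    if (any(gland)) vessels <- vessels & !dilate_mask(gland, 5)

    # intensity assembly
    tone <- normalize01(smooth_field(H, W, sigma = max(6, round(min(H, W) / 16))))
    img <- matrix(0.02, H, W)
    img[breast] <- 0.22 + 0.08 * tone[breast]
    img[pect] <- 0.53 + 0.04 * tone[pect]
    if (any(gland)) {
      gmax <- max(gland_field[gland])
      gn <- (gland_field - cut_val) / (gmax - cut_val + 1e-12)
      img[gland] <- 0.60 + 0.16 * gn[gland]
    }
    img[vessels] <- 0.66 + 0.02 * tone[vessels]
    img <- img * vmax
    if (spec$noise_sd > 0) {
      img <- img + stats::rnorm(length(img), sd = spec$noise_sd)
    }
    img <- round(pmin(pmax(img, 0), vmax))

    if (spec$laterality == "right") {
      img <- flip_horizontal(img)
      breast <- flip_horizontal(breast)
      pect <- flip_horizontal(pect)
      calc <- flip_horizontal(calc)
      gland <- flip_horizontal(gland)
      vessels <- flip_horizontal(vessels)
    }

    measured <- if (n_calc > 0) sum(gland) / n_calc else 0
    label <- classify_composition(measured)

    structure(
      list(
        image = mammogram(img, bit_depth = spec$bit_depth, laterality = spec$laterality),
        gland_truth = gland,
        calc_region = calc,
        pectoral = pect,
        vessels = vessels,
        breast = breast,
        spec = spec,
        measured_ratio = measured,
        category = as.character(label$category),
        grouping = as.character(label$grouping),
        unmasked = !any(gland)
      ),
      class = "phantom_bundle"
    )
  })
}

#' @export
print.phantom_bundle <- function(x, ...) {
  cat(sprintf(
    "<phantom_bundle> %d x %d %s, content ratio %.3f (%s), %d vessel px%s\n",
    nrow(x$image$pixels), ncol(x$image$pixels), x$spec$laterality,
    x$measured_ratio, x$category, sum(x$vessels),
    ifelse(x$unmasked, ", unmasked", "")
  ))
  invisible(x)
}

#' Emulate the semi-subjective physician correction
#'
#' The clinical protocol has a physician delete every structure in the
#' objective thresholding mask that is not mammary gland (vessels, pectoral
#' leakage). On phantoms the judgement is emulated per connected component:
#' a component is kept only if the fraction of its pixels overlapping the
#' gland truth reaches `min_overlap`. The result is always a subset of the
#' input mask — correction only ever deletes.
#'
#' @param objective_mask Logical mask from [extract_objective_mask()].
#' @param bundle The `phantom_bundle` providing the gland truth.
#' @param min_overlap Minimum gland-overlap fraction for a component to
#'   survive (default 0.5; the physician's call is binary per structure).
#' @return Logical mask, subset of `objective_mask`.
#' @export
emulate_correction <- function(objective_mask, bundle, min_overlap = 0.5) {
  stopifnot(inherits(bundle, "phantom_bundle"))
  objective_mask <- as_mask(objective_mask)
  check_same_dim(objective_mask, bundle$gland_truth, "mask and phantom grid")
  if (!any(objective_mask)) return(objective_mask)
  lab <- EBImage::imageData(EBImage::bwlabel(objective_mask * 1))
  n_comp <- max(lab)
  sizes <- tabulate(lab[lab > 0], nbins = n_comp)
  overlap <- tabulate(lab[bundle$gland_truth & lab > 0], nbins = n_comp)
  keep <- which(overlap / sizes >= min_overlap)
  matrix(lab %in% keep, nrow(lab), ncol(lab))
}

#' Generate a phantom dataset
#'
#' Draws `n` phantoms with ratios sampled uniformly from `ratio_range`
#' (or taken from `ratios`, recycled) and random lateralities, each with its
#' own child seed derived from `seed`.
#'
#' @param n Number of phantoms.
#' @param ratios Optional explicit target ratios (recycled to length `n`);
#'   overrides `ratio_range`.
#' @param ratio_range Range to sample target content ratios from.
#' @param seed Master seed.
#' @param ... Passed to [phantom_spec()] (size, noise, vessel count, ...).
#' @return A tibble manifest with one row per phantom: `id`, `seed`,
#'   `target_ratio`, `measured_ratio`, `category`, `grouping`,
#'   `laterality`, `unmasked` and a `bundle` list-column.
#' @export
phantom_dataset <- function(n, ratios = NULL, ratio_range = c(0.05, 0.90),
                            seed = 1L, ...) {
  if (n < 1) stop_validation("`n` must be positive")
  draws <- withr::with_seed(seed, list(
    ratios = if (is.null(ratios)) {
      stats::runif(n, ratio_range[1], ratio_range[2])
    } else {
      rep_len(ratios, n)
    },
    lateralities = sample(c("left", "right"), n, replace = TRUE),
    seeds = sample.int(.Machine$integer.max - 1L, n)
  ))
  bundles <- purrr::pmap(
    list(draws$ratios, draws$lateralities, draws$seeds),
    function(r, lat, s) {
      generate_phantom(phantom_spec(
        target_content_ratio = r, laterality = lat, seed = s, ...
      ))
    }
  )
  tibble(
    id = sprintf("phantom_%03d", seq_len(n)),
    seed = draws$seeds,
    target_ratio = draws$ratios,
    measured_ratio = purrr::map_dbl(bundles, "measured_ratio"),
    category = purrr::map_chr(bundles, "category"),
    grouping = purrr::map_chr(bundles, "grouping"),
    laterality = draws$lateralities,
    unmasked = purrr::map_lgl(bundles, "unmasked"),
    bundle = bundles
  )
}

#' Write a phantom dataset to disk
#'
#' Writes each image as 16-bit TIFF with a JSON sidecar, the masks as 8-bit
#' PNGs, and a `manifest.csv` listing paths, ratios and labels.
#'
#' @param dataset Tibble from [phantom_dataset()].
#' @param dir Output directory (created if needed).
#' @return The manifest tibble (with path columns), invisibly.
#' @export
write_phantom_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- purrr::pmap(list(dataset$id, dataset$bundle), function(id, b) {
    img_path <- file.path(dir, paste0(id, ".tif"))
    write_mammogram(b$image, img_path)
    paths <- list(image = img_path)
    for (m in c("gland_truth", "calc_region", "pectoral", "vessels")) {
      p <- file.path(dir, paste0(id, "_", m, ".png"))
      write_mask(b[[m]], p)
      paths[[m]] <- p
    }
    tibble::as_tibble(paths)
  })
  manifest <- dplyr::bind_cols(
    dplyr::select(dataset, -"bundle"),
    dplyr::bind_rows(rows)
  )
  readr::write_csv(manifest, file.path(dir, "manifest.csv"))
  invisible(manifest)
}
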
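# Mammary gland content ratio and breast composition classification.

#' Breast composition category levels
#'
#' Ordered from least to most dense, following the four-category
#' classification used in Japanese screening guidelines (referencing the
#' ACR BI-RADS atlas).
#'
#' @export
composition_levels <- function() {
  c("fatty", "scattered", "heterogeneous_dense", "extremely_dense")
}

#' Mammary gland content ratio
#'
#' The fraction of the calculation region occupied by mammary gland tissue:
#' `area(gland intersect calc_region) / area(calc_region)`. The calculation
#' region is the part of the breast where gland could plausibly exist,
#' excluding the pectoral muscle, subcutaneous fat and the retromammary gap;
#' gland pixels outside it are ignored.
#'
#' @param gland Logical gland mask.
#' @param calc_region Logical calculation-region mask on the same grid.
#' @return A fraction in `[0, 1]`.
#' @export
content_ratio <- function(gland, calc_region) {
  gland <- as_mask(gland)
  calc_region <- as_mask(calc_region)
  check_same_dim(gland, calc_region, "gland and calculation-region masks")
  n_calc <- sum(calc_region)
  if (n_calc == 0) stop_empty_region("the calculation region is empty")
  sum(gland & calc_region) / n_calc
}

#' Classify breast composition from the gland content ratio
#'
#' Bands: ratio < 10% is `fatty`, 10-50% `scattered`, 50-80%
#' `heterogeneous_dense`, and >= 80% `extremely_dense`. All lower bounds are
#' inclusive, mirroring the explicit ">= 80%" rule of the densest band.
#' `fatty` and `scattered` form the `fatty_breast` grouping; the two dense
#' categories form `dense_breast` (associated with reduced mammographic
#' sensitivity).
#'
#' @param ratio Numeric vector of content ratios in `[0, 1]`.
#' @return A tibble with columns `ratio`, `category` (ordered factor) and
#'   `grouping` (factor).
#' @export
classify_composition <- function(ratio) {
  if (!is.numeric(ratio) || any(!is.finite(ratio)) ||
      any(ratio < 0) || any(ratio > 1)) {
    stop_validation("`ratio` must be numeric in [0, 1]")
  }
  category <- cut(
    ratio,
    breaks = c(0, 0.10, 0.50, 0.80, Inf),
    labels = composition_levels(),
    right = FALSE, ordered_result = TRUE
  )
  grouping <- factor(
    ifelse(category %in% c("fatty", "scattered"), "fatty_breast", "dense_breast"),
    levels = c("fatty_breast", "dense_breast")
  )
  tibble(ratio = ratio, category = category, grouping = grouping)
}
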
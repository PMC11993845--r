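# Dice evaluation: the plain coefficient, the complement rule for
# gland-free ("unmasked") images, per-composition stratified reporting, and
# the corrected-vs-objective truth-source comparison.

#' Dice coefficient of two binary masks
#'
#' `2 |X intersect Y| / (|X| + |Y|)` over foreground pixels. The case where
#' both masks are empty is deliberately an error here: gland-free truths
#' are evaluated with [dice_with_unmasked_rule()].
#'
#' @param X,Y Logical masks on the same grid.
#' @return A fraction in `[0, 1]`.
#' @export
dice <- function(X, Y) {
  X <- as_mask(X)
  Y <- as_mask(Y)
  check_same_dim(X, Y, "masks")
  denom <- sum(X) + sum(Y)
  if (denom == 0) {
    abort(
      "both masks are empty; use dice_with_unmasked_rule() for gland-free truths",
      class = c("glandseg_both_empty_error", "glandseg_error")
    )
  }
  2 * sum(X & Y) / denom
}

#' Dice with the complement rule for unmasked images
#'
#' When the truth mask `X` has no foreground (an "unmasked" image judged to
#' contain no gland), agreement is scored on the background instead: the
#' Dice of the complements of `X` and `Y` over the evaluation domain. Both
#' masks empty therefore score 1. Otherwise this is exactly [dice()].
#'
#' @param X Truth mask (the corrected region image).
#' @param Y Predicted mask.
#' @param domain Evaluation domain for the complement rule; defaults to the
#'   full image grid.
#' @return List with `dice` and `unmasked` (flag).
#' @export
dice_with_unmasked_rule <- function(X, Y, domain = NULL) {
  X <- as_mask(X)
  Y <- as_mask(Y)
  check_same_dim(X, Y, "masks")
  if (is.null(domain)) {
    domain <- matrix(TRUE, nrow(X), ncol(X))
  } else {
    domain <- as_mask(domain)
    check_same_dim(X, domain, "mask and domain")
  }
  if (sum(X) == 0) {
    cx <- !X & domain
    cy <- !Y & domain
    d <- if (sum(cx) + sum(cy) == 0) 1 else 2 * sum(cx & cy) / (sum(cx) + sum(cy))
    list(dice = d, unmasked = TRUE)
  } else {
    list(dice = dice(X, Y), unmasked = FALSE)
  }
}

#' Stratified Dice report
#'
#' Computes per-image Dice (with the unmasked rule), then aggregates:
#' per-composition means over the images of each category, per-replicate
#' means, and the overall mean. Categories with no images are absent from
#' the per-category table rather than reported as zero.
#'
#' @param pairs A data frame with list-columns `truth` and `pred` (logical
#'   masks) and a `category` column; optional `id` and `replicate` columns.
#' @return A `dice_report`: list with `per_image` (tibble),
#'   `per_category` (tibble of means), `replicate_means`, `overall_mean`.
#' @export
stratified_report <- function(pairs) {
  pairs <- as_tibble(pairs)
  if (nrow(pairs) == 0) stop_validation("`pairs` is empty")
  if (!all(c("truth", "pred", "category") %in% names(pairs))) {
    stop_validation("`pairs` needs columns truth, pred, category")
  }
  if (!"id" %in% names(pairs)) pairs$id <- sprintf("img_%03d", seq_len(nrow(pairs)))
  if (!"replicate" %in% names(pairs)) pairs$replicate <- 1L
  res <- purrr::map2(pairs$truth, pairs$pred, dice_with_unmasked_rule)
  per_image <- tibble(
    id = pairs$id,
    replicate = pairs$replicate,
    category = factor(as.character(pairs$category), levels = composition_levels()),
    dice = purrr::map_dbl(res, "dice"),
    unmasked = purrr::map_lgl(res, "unmasked")
  )
  per_category <- per_image |>
    dplyr::group_by(.data$category) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean_dice = mean(.data$dice),
      .groups = "drop"
    )
  replicate_means <- per_image |>
    dplyr::group_by(.data$replicate) |>
    dplyr::summarise(mean_dice = mean(.data$dice), .groups = "drop")
  structure(
    list(
      per_image = per_image,
      per_category = per_category,
      replicate_means = replicate_means,
      overall_mean = mean(per_image$dice)
    ),
    class = "dice_report"
  )
}

#' @export
print.dice_report <- function(x, ...) {
  cat(sprintf("<dice_report> %d images, overall mean Dice %.3f\n",
              nrow(x$per_image), x$overall_mean))
  print(x$per_category)
  invisible(x)
}

#' @rdname stratified_report
#' @param x A `dice_report`.
#' @param ... Unused.
#' @export
tidy.dice_report <- function(x, ...) x$per_category

#' @rdname stratified_report
#' @export
glance.dice_report <- function(x, ...) {
  tibble(
    n_images = nrow(x$per_image),
    n_unmasked = sum(x$per_image$unmasked),
    n_replicates = nrow(x$replicate_means),
    overall_mean = x$overall_mean
  )
}

#' Plot a Dice report by breast composition
#'
#' @param object A `dice_report`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.dice_report <- function(object, ...) {
  ggplot2::ggplot(object$per_category,
                  ggplot2::aes(x = .data$category, y = .data$mean_dice)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_hline(yintercept = object$overall_mean, linetype = 2) +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "breast composition", y = "mean Dice",
                  caption = "dashed line: overall mean") +
    ggplot2::theme_minimal()
}

#' Compare corrected-truth and objective-truth training
#'
#' Evaluates two fitted models on the same test pairs — one trained with
#' semi-subjective corrected masks, one with raw objective thresholding
#' masks — always scoring against the corrected truth. Returns one row per
#' truth source with the overall and per-composition mean Dice, mirroring
#' the usual comparison layout.
#'
#' @param test_pairs Data frame with list-columns `image` (preprocessed
#'   input matrices) and `truth` (corrected truth masks) plus `category`.
#' @param fit_corrected,fit_objective `unet_fit` objects.
#' @return A tibble with columns `truth_source`, `all`, then one column per
#'   composition category present.
#' @export
compare_truth_sources <- function(test_pairs, fit_corrected, fit_objective) {
  test_pairs <- as_tibble(test_pairs)
  if (!all(c("image", "truth", "category") %in% names(test_pairs))) {
    stop_validation("`test_pairs` needs columns image, truth, category")
  }
  one_row <- function(fit, source) {
    preds <- purrr::map(test_pairs$image, function(im) predict(fit, im))
    rep <- stratified_report(tibble(
      truth = test_pairs$truth, pred = preds, category = test_pairs$category
    ))
    wide <- tidyr::pivot_wider(
      dplyr::select(rep$per_category, "category", "mean_dice"),
      names_from = "category", values_from = "mean_dice"
    )
    dplyr::bind_cols(tibble(truth_source = source, all = rep$overall_mean), wide)
  }
  dplyr::bind_rows(
    one_row(fit_corrected, "corrected"),
    one_row(fit_objective, "objective")
  )
}
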
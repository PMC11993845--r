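# Objective gland-region extraction: in-region intensity histogram, peak
# counting, and peak-count-switched thresholding (Kapur maximum entropy for
# unimodal histograms, Otsu discriminant analysis otherwise).

#' Histogram of pixel intensities inside a region
#'
#' Counts in-region pixel values over `n_bins` uniform bins spanning the
#' in-region min-max range. Bins are left-closed; the maximum value falls in
#' the last bin. A constant region yields a single nonzero bin.
#'
#' @param image A `mammogram` or numeric matrix.
#' @param region Logical mask selecting the pixels to histogram (typically
#'   the calculation region).
#' @param n_bins Number of bins (default 256).
#' @return An `intensity_histogram`: list with `counts`, `breaks`, `bin_lo`,
#'   `bin_hi`, `n_bins`.
#' @export
compute_histogram <- function(image, region, n_bins = 256L) {
  px <- as_pixels(image)
  region <- as_mask(region)
  check_same_dim(px, region, "image and region")
  if (n_bins < 2) stop_validation("`n_bins` must be at least 2")
  v <- px[region]
  if (length(v) == 0) stop_empty_region("region contains no pixels")
  lo <- min(v)
  hi <- max(v)
  width <- hi - lo
  if (width <= 0) {
    # degenerate constant region: one populated bin of unit width
    hi <- lo + 1
    width <- 1
  }
  idx <- pmin(floor((v - lo) / width * n_bins) + 1L, n_bins)
  counts <- tabulate(idx, nbins = n_bins)
  structure(
    list(
      counts = counts,
      breaks = seq(lo, hi, length.out = n_bins + 1),
      bin_lo = lo, bin_hi = hi, n_bins = as.integer(n_bins)
    ),
    class = "intensity_histogram"
  )
}

#' @export
print.intensity_histogram <- function(x, ...) {
  cat(sprintf(
    "<intensity_histogram> %d bins on [%g, %g], %d pixels, %d nonzero bins\n",
    x$n_bins, x$bin_lo, x$bin_hi, sum(x$counts), sum(x$counts > 0)
  ))
  invisible(x)
}

bin_mids <- function(hist) (hist$breaks[-1] + hist$breaks[-length(hist$breaks)]) / 2

# centred moving average with truncated windows at the edges
moving_average <- function(x, window) {
  if (window <= 1) return(x)
  h <- window %/% 2
  n <- length(x)
  vapply(seq_len(n), function(i) {
    mean(x[max(1, i - h):min(n, i + h)])
  }, numeric(1))
}

# prominence of each local maximum of y (plateaus collapse to one peak);
# a side with no higher point contributes its minimum down to the boundary
peak_prominences <- function(y) {
  n <- length(y)
  r <- rle(y)
  k <- length(r$values)
  starts <- cumsum(c(1, r$lengths[-k]))
  is_peak <- vapply(seq_len(k), function(i) {
    left <- if (i == 1) -Inf else r$values[i - 1]
    right <- if (i == k) -Inf else r$values[i + 1]
    r$values[i] > left && r$values[i] > right
  }, logical(1))
  peaks <- starts[is_peak]
  prom <- vapply(peaks, function(p) {
    h <- y[p]
    left_min <- h
    i <- p
    while (i > 1 && y[i - 1] <= h) {
      i <- i - 1
      left_min <- min(left_min, y[i])
    }
    right_min <- h
    i <- p
    while (i < n && y[i + 1] <= h) {
      i <- i + 1
      right_min <- min(right_min, y[i])
    }
    h - max(left_min, right_min)
  }, numeric(1))
  list(peaks = peaks, prominences = prom)
}

#' Count histogram peaks
#'
#' Smooths the counts with a centred moving average, normalizes by the
#' maximum, and counts local maxima whose topographic prominence reaches
#' `min_prominence`. Any histogram with at least one nonzero bin reports at
#' least one peak (the global maximum has prominence 1 by construction).
#'
#' @param hist An `intensity_histogram`.
#' @param smooth_window Moving-average window in bins (default 5).
#' @param min_prominence Minimum prominence as a fraction of the smoothed
#'   maximum (default 0.05).
#' @return Integer peak count (>= 1).
#' @export
count_peaks <- function(hist, smooth_window = 5L, min_prominence = 0.05) {
  stopifnot(inherits(hist, "intensity_histogram"))
  if (all(hist$counts == 0)) stop_validation("histogram has all-zero counts")
  y <- moving_average(hist$counts, smooth_window)
  y <- y / max(y)
  pp <- peak_prominences(y)
  sum(pp$prominences >= min_prominence)
}

# shared candidate scan: every boundary between bins k and k+1 with nonzero
# mass on both sides is a candidate threshold; `score` maps k to a criterion
# value; ties break towards the smallest threshold
argmax_boundary <- function(hist, score) {
  counts <- hist$counts
  if (sum(counts > 0) < 2) {
    stop_validation("thresholding needs at least 2 nonzero histogram bins")
  }
  n <- hist$n_bins
  csum <- cumsum(counts)
  total <- csum[n]
  valid <- which(csum[-n] > 0 & csum[-n] < total)  # k with both classes non-empty
  vals <- vapply(valid, score, numeric(1))
  k <- valid[which.max(vals)]  # which.max returns the first (smallest) argmax
  hist$breaks[k + 1]
}

#' Kapur maximum-entropy threshold
#'
#' Chooses the bin boundary maximizing the sum of Shannon entropies of the
#' class-normalized bin probabilities below and above the split
#' (Kapur-Sahoo-Wong criterion). Natural logarithms; `0 log 0 = 0`; ties
#' resolve to the smallest optimal threshold.
#'
#' @param hist An `intensity_histogram` with at least two nonzero bins.
#' @return The threshold intensity (a bin boundary); foreground is intensity
#'   greater than or equal to the threshold.
#' @export
max_entropy_threshold <- function(hist) {
  stopifnot(inherits(hist, "intensity_histogram"))
  p <- hist$counts / sum(hist$counts)
  plogp <- ifelse(p > 0, p * log(p), 0)
  P <- cumsum(p)
  S <- cumsum(plogp)
  total_S <- S[length(S)]
  argmax_boundary(hist, function(k) {
    p0 <- P[k]
    p1 <- 1 - p0
    h0 <- -S[k] / p0 + log(p0)
    h1 <- -(total_S - S[k]) / p1 + log(p1)
    h0 + h1
  })
}

#' Otsu discriminant-analysis threshold
#'
#' Chooses the bin boundary maximizing the between-class variance
#' `w0 * w1 * (mu0 - mu1)^2`, with bin midpoints as class values. Ties
#' resolve to the smallest optimal threshold.
#'
#' @inheritParams max_entropy_threshold
#' @return The threshold intensity (a bin boundary).
#' @export
otsu_threshold <- function(hist) {
  stopifnot(inherits(hist, "intensity_histogram"))
  p <- hist$counts / sum(hist$counts)
  m <- bin_mids(hist)
  P <- cumsum(p)
  M <- cumsum(p * m)
  mu_total <- M[length(M)]
  argmax_boundary(hist, function(k) {
    w0 <- P[k]
    w1 <- 1 - w0
    mu0 <- M[k] / w0
    mu1 <- (mu_total - M[k]) / w1
    w0 * w1 * (mu0 - mu1)^2
  })
}

#' Select a threshold by the peak-count switching rule
#'
#' Applies the objective extraction rule: the maximum-entropy method when
#' the in-region histogram has a single peak, and the discriminant-analysis
#' (Otsu) method when it has two or more peaks.
#'
#' @inheritParams count_peaks
#' @return A `threshold_result`: list with `threshold`, `method`
#'   (`"max_entropy"` or `"discriminant"`) and `peak_count`.
#' @export
select_threshold <- function(hist, smooth_window = 5L, min_prominence = 0.05) {
  peaks <- count_peaks(hist, smooth_window = smooth_window,
                       min_prominence = min_prominence)
  if (peaks == 1) {
    method <- "max_entropy"
    thr <- max_entropy_threshold(hist)
  } else {
    method <- "discriminant"
    thr <- otsu_threshold(hist)
  }
  structure(
    list(threshold = thr, method = method, peak_count = peaks),
    class = "threshold_result"
  )
}

#' @export
print.threshold_result <- function(x, ...) {
  cat(sprintf("<threshold_result> threshold = %g (%s method, %d peak%s)\n",
              x$threshold, x$method, x$peak_count,
              ifelse(x$peak_count == 1, "", "s")))
  invisible(x)
}

#' Extract the objective gland mask by thresholding
#'
#' Foreground is every calculation-region pixel with intensity greater than
#' or equal to the threshold — gland is defined as tissue of density equal
#' or greater than the pectoral-muscle reference, which motivates the
#' inclusive comparison. Bright non-gland structures (vessels, pectoral
#' leakage) survive this step; they are what the semi-subjective correction
#' subsequently deletes.
#'
#' @param image A `mammogram` or numeric matrix.
#' @param calc_region Logical calculation-region mask.
#' @param result A `threshold_result` from [select_threshold()], or a bare
#'   numeric threshold.
#' @return Logical mask, a subset of `calc_region`.
#' @export
extract_objective_mask <- function(image, calc_region, result) {
  px <- as_pixels(image)
  calc_region <- as_mask(calc_region)
  check_same_dim(px, calc_region, "image and calculation region")
  thr <- if (inherits(result, "threshold_result")) result$threshold else result
  if (!is.numeric(thr) || length(thr) != 1) {
    stop_validation("`result` must be a threshold_result or a single number")
  }
  (px >= thr) & calc_region
}
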
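# Independent brute-force oracles used to validate the implementation.
# These deliberately re-derive each quantity from its definition with plain
# loops, sharing no code with the package internals.

# Kapur maximum-entropy criterion: scan every split, computing both class
# entropies directly from the definition.
kapur_brute <- function(hist) {
  p <- hist$counts / sum(hist$counts)
  n <- length(p)
  best <- -Inf
  best_k <- NA
  for (k in 1:(n - 1)) {
    P0 <- sum(p[1:k])
    P1 <- 1 - P0
    if (P0 <= 0 || P1 <= 0) next
    q0 <- p[1:k][p[1:k] > 0] / P0
    q1 <- p[(k + 1):n][p[(k + 1):n] > 0] / P1
    H <- -sum(q0 * log(q0)) - sum(q1 * log(q1))
    if (H > best + 1e-12) {
      best <- H
      best_k <- k
    }
  }
  hist$breaks[best_k + 1]
}

# Otsu between-class variance, scanned directly.
otsu_brute <- function(hist) {
  p <- hist$counts / sum(hist$counts)
  m <- (hist$breaks[-1] + hist$breaks[-length(hist$breaks)]) / 2
  n <- length(p)
  best <- -Inf
  best_k <- NA
  for (k in 1:(n - 1)) {
    w0 <- sum(p[1:k])
    w1 <- 1 - w0
    if (w0 <= 0 || w1 <= 0) next
    mu0 <- sum(p[1:k] * m[1:k]) / w0
    mu1 <- sum(p[(k + 1):n] * m[(k + 1):n]) / w1
    v <- w0 * w1 * (mu0 - mu1)^2
    if (v > best + 1e-12) {
      best <- v
      best_k <- k
    }
  }
  hist$breaks[best_k + 1]
}

# Dice by an explicit pixel loop.
dice_brute <- function(X, Y) {
  inter <- 0
  nx <- 0
  ny <- 0
  for (i in seq_along(X)) {
    if (X[i]) nx <- nx + 1
    if (Y[i]) ny <- ny + 1
    if (X[i] && Y[i]) inter <- inter + 1
  }
  2 * inter / (nx + ny)
}

# Random histogram built through the public constructor from random pixels.
random_histogram <- function(seed, n_bins = 32) {
  withr::with_seed(seed, {
    n <- sample(50:400, 1)
    v <- matrix(c(stats::runif(n, 0, 100), rep(0, 400 - n)), 20, 20)
    compute_histogram(v, matrix(TRUE, 20, 20), n_bins = n_bins)
  })
}

# Histogram object from explicit counts (unit intensity bins).
hist_from_counts <- function(counts) {
  structure(
    list(
      counts = as.integer(counts),
      breaks = seq(0, length(counts), by = 1),
      bin_lo = 0, bin_hi = length(counts), n_bins = length(counts)
    ),
    class = "intensity_histogram"
  )
}

# Small noise-free phantom used across tests.
tiny_phantom <- function(ratio = 0.4, seed = 1, height = 96L, width = 72L, ...) {
  generate_phantom(phantom_spec(
    height = height, width = width, target_content_ratio = ratio,
    noise_sd = 0, seed = seed, ...
  ))
}
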
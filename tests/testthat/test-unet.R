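# Desk-scale network checks. Architectural assertions use an independent
# closed-form parameter count; the training engine is validated against
# central finite differences.

test_that("channel sequence doubles from the base kernel count", {
  cfg <- unet_config(depth = 3, base_kernels = 64, input_size = 256)
  expect_equal(unet_channels(cfg), c(64, 128, 256))
  cfg2 <- unet_config(depth = 5, base_kernels = 8, input_size = 32)
  expect_equal(unet_channels(cfg2), 8 * 2^(0:4))
})

test_that("parameter count matches an independent closed-form computation", {
  # independent arithmetic: 3x3 convs contribute 9*cin*cout + cout, the
  # 2x2 transposed convs 4*cin*cout + cout, the 1x1 output conv cin + 1
  count_by_hand <- function(depth, base) {
    ch <- base * 2^(0:(depth - 1))
    bott <- 2 * ch[depth]
    total <- 0
    conv <- function(ci, co) 9 * ci * co + co
    cin <- 1
    for (k in 1:depth) {
      total <- total + conv(cin, ch[k]) + conv(ch[k], ch[k])
      cin <- ch[k]
    }
    total <- total + conv(ch[depth], bott) + conv(bott, bott)
    for (k in depth:1) {
      up_in <- if (k == depth) bott else ch[k + 1]
      total <- total + 4 * up_in * ch[k] + ch[k] +
        conv(2 * ch[k], ch[k]) + conv(ch[k], ch[k])
    }
    total + ch[1] + 1
  }
  for (d in c(1, 2, 3)) {
    for (base in c(2, 8)) {
      cfg <- unet_config(depth = d, base_kernels = base, input_size = 32)
      expect_equal(unet_param_count(cfg), count_by_hand(d, base))
      model <- build_unet(cfg)
      expect_equal(sum(lengths(model$params)), count_by_hand(d, base))
    }
  }
})

test_that("initialization is deterministic given the seed", {
  cfg <- unet_config(depth = 2, base_kernels = 4, seed = 11, input_size = 16)
  m1 <- build_unet(cfg)
  m2 <- build_unet(cfg)
  expect_identical(m1$params, m2$params)
  cfg2 <- cfg
  cfg2$seed <- 12L
  expect_false(identical(build_unet(cfg2)$params, m1$params))
})

test_that("configuration validation rejects incompatible sizes", {
  expect_error(unet_config(depth = 5, input_size = 48),
               class = "glandseg_validation_error")
  expect_error(unet_config(binarize_threshold = 0), class = "glandseg_validation_error")
  expect_no_error(unet_config(depth = 6, input_size = 256))  # 4-px bottleneck
})

test_that("forward pass yields probabilities and thresholding is monotone", {
  cfg <- unet_config(depth = 2, base_kernels = 4, seed = 2, input_size = 16)
  model <- build_unet(cfg)
  x <- matrix(stats::runif(16 * 16) * 255, 16, 16)
  p <- predict(model, x, type = "prob")
  expect_equal(dim(p), c(16L, 16L))
  expect_true(all(p > 0 & p < 1))

  # all-zero input still yields a valid binary mask
  m0 <- predict(model, matrix(0, 16, 16))
  expect_type(m0, "logical")

  # mask area is non-increasing in the binarization threshold
  areas <- vapply(c(0.1, 0.3, 0.5, 0.7, 0.9), function(t) {
    sum(predict(model, x, threshold = t))
  }, numeric(1))
  expect_true(all(diff(areas) <= 0))

  expect_error(predict(model, matrix(0, 15, 15)),
               class = "glandseg_validation_error")
})

test_that("analytic gradients agree with finite differences along the gradient", {
  cfg <- unet_config(depth = 2, base_kernels = 2, seed = 42, input_size = 8)
  model <- build_unet(cfg)
  params <- model$params
  # random nonzero biases and output weights keep pre-activations away from
  # the ReLU kink, where subgradients and finite differences legitimately
  # disagree
  withr::with_seed(1, {
    for (i in seq_along(params)) {
      if (is.null(dim(params[[i]]))) {
        params[[i]] <- stats::rnorm(length(params[[i]]), sd = 0.3)
      }
    }
    n_fin <- length(params) - 1L
    params[[n_fin]][] <- stats::rnorm(length(params[[n_fin]]), sd = 0.3)
    x <- matrix(stats::runif(64) * 10, 8, 8)
    y <- matrix(stats::rbinom(64, 1, 0.4) * 1, 8, 8)
  })
  loss_of <- function(par) {
    p <- glandseg:::cpp_unet_forward(par, x, cfg$depth)
    -mean(y * log(p) + (1 - y) * log(1 - p))
  }
  grads <- lapply(params, function(p) { p[] <- 0; p })
  loss <- glandseg:::cpp_unet_batch_grad(params, grads, list(x), list(y),
                                         cfg$depth, 0L)
  expect_equal(loss, loss_of(params), tolerance = 1e-5)

  # directional derivative along the analytic gradient: for the correct
  # gradient g, (L(theta + h g/|g|) - L(theta - h g/|g|)) / 2h = |g|.
  # The single-precision forward limits per-coordinate checks, but the
  # directional derivative aggregates over every parameter and would move
  # if any layer's gradient were wrong.
  g <- unlist(grads)
  gnorm <- sqrt(sum(g^2))
  unit <- g / gnorm
  shift_by <- function(par, s) {
    k <- 1
    for (i in seq_along(par)) {
      n <- length(par[[i]])
      par[[i]][] <- par[[i]][] + s * unit[k:(k + n - 1)]
      k <- k + n
    }
    par
  }
  h <- 1e-2
  dd <- (loss_of(shift_by(params, h)) - loss_of(shift_by(params, -h))) / (2 * h)
  expect_equal(dd, gnorm, tolerance = 0.05)
})

make_blob_pairs <- function(n, size = 16, seed = 1) {
  # trivial task: a bright square on dark background
  withr::with_seed(seed, {
    purrr::map(seq_len(n), function(i) {
      m <- matrix(0, size, size)
      r <- sample(2:(size - 6), 2)
      mask <- matrix(FALSE, size, size)
      mask[r[1]:(r[1] + 4), r[2]:(r[2] + 4)] <- TRUE
      m[mask] <- 200
      m <- m + matrix(stats::rnorm(size^2, sd = 5), size, size)
      list(image = m, mask = mask)
    })
  }) |> purrr::transpose() |> tibble::as_tibble() |> dplyr::mutate(
    image = purrr::map(image, identity), mask = purrr::map(mask, identity)
  )
}

test_that("training reduces the loss and is seed-reproducible", {
  pairs <- make_blob_pairs(12)
  cfg <- unet_config(depth = 2, base_kernels = 4, learning_rate = 1e-3,
                     batch_size = 4, epochs = 6, seed = 7, input_size = 16)
  fit <- train_unet(build_unet(cfg), pairs[1:8, ], pairs[9:12, ])
  expect_equal(nrow(fit$history), 6L)
  # loss trends down over training on this trivial task
  expect_lt(mean(tail(fit$history$loss, 2)), mean(head(fit$history$loss, 2)))
  expect_gte(fit$best_val_dice, fit$history$val_dice[1] - 1e-12)

  fit2 <- train_unet(build_unet(cfg), pairs[1:8, ], pairs[9:12, ])
  expect_identical(fit$history, fit2$history)
  expect_identical(fit$params, fit2$params)

  g <- glance(fit)
  expect_equal(g$depth, 2L)
  expect_s3_class(tidy(fit), "tbl_df")
})

test_that("a zero learning rate leaves the weights unchanged", {
  pairs <- make_blob_pairs(6)
  cfg <- unet_config(depth = 2, base_kernels = 4, learning_rate = 0,
                     batch_size = 4, epochs = 2, seed = 3, input_size = 16)
  model <- build_unet(cfg)
  fit <- train_unet(model, pairs[1:4, ], pairs[5:6, ])
  expect_identical(fit$final_params, model$params)
  expect_equal(length(unique(fit$history$val_dice)), 1L)
})

test_that("the full study grid enumerates 20 configurations", {
  g <- unet_grid()
  expect_equal(nrow(g), 20L)
  expect_equal(unique(g$depth), c(3, 4, 5, 6, 7))
  expect_equal(unique(g$learning_rate), c(0.001, 0.0001))
  expect_equal(unique(g$batch_size), c(16, 32))
  expect_equal(nrow(dplyr::distinct(g[, c("depth", "learning_rate", "batch_size")])), 20L)
})

test_that("run_grid reports one averaged row per configuration", {
  pairs <- make_blob_pairs(10)
  g <- unet_grid(depths = c(1, 2), learning_rates = 1e-3, batch_sizes = 4,
                 base_kernels = 2, epochs = 2, input_size = 16)
  rep <- run_grid(g, pairs[1:6, ], pairs[7:8, ], pairs[9:10, ], replicates = 1)
  expect_equal(nrow(rep), 2L)
  expect_true(all(is.na(rep$error)))
  # with one replicate the mean equals the single run
  expect_equal(rep$mean_dice, purrr::map_dbl(rep$replicate_dice, 1))
})
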
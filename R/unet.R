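# U-Net segmentation: configuration, parameter initialization, training
# (Adam + binary cross-entropy on logits, via the C++ engine in src/),
# prediction and the parameter-grid runner.
#
# Architecture (canonical encoder-decoder with skip connections): each
# encoder level applies two 3x3 same convolutions with ReLU and then 2x2
# max pooling; the bottleneck applies two convolutions; each decoder level
# upsamples with a 2x2 stride-2 transposed convolution, concatenates the
# encoder skip tensor, and applies two convolutions; a final 1x1
# convolution with sigmoid yields the per-pixel foreground probability.
# Channel count at level k is base_kernels * 2^(k-1).

#' U-Net configuration
#'
#' One cell of the segmentation parameter grid.
#'
#' @param depth Number of downsampling layers (the study grid uses 3-7).
#' @param learning_rate Adam learning rate (grid values 0.001 and 0.0001).
#' @param batch_size Mini-batch size (grid values 16 and 32).
#' @param base_kernels Convolution kernels in the first level (64 in the
#'   full-scale study; desk-scale experiments use fewer).
#' @param epochs Training epochs (default 50, with best-validation-Dice
#'   checkpointing).
#' @param seed Seed for initialization and batch shuffling.
#' @param loss Loss identifier: `"bce_dice"` (default; binary cross-entropy
#'   plus soft Dice, the usual choice for class-imbalanced segmentation),
#'   `"bce"`, or `"dice"`.
#' @param binarize_threshold Probability cutoff for mask output.
#' @param input_size Expected input side length; must be divisible by
#'   `2^depth`.
#' @return A `unet_config` list.
#' @export
unet_config <- function(depth = 3L, learning_rate = 1e-4, batch_size = 16L,
                        base_kernels = 64L, epochs = 50L, seed = 1L,
                        loss = c("bce_dice", "bce", "dice"),
                        binarize_threshold = 0.5,
                        input_size = 256L) {
  if (depth < 1) stop_validation("`depth` must be at least 1")
  if (input_size %% 2^depth != 0) {
    stop_validation(sprintf("input_size %d is not divisible by 2^depth = %d",
                            input_size, 2^depth))
  }
  if (binarize_threshold <= 0 || binarize_threshold >= 1) {
    stop_validation("`binarize_threshold` must be inside (0, 1)")
  }
  loss <- match.arg(loss)
  if (learning_rate < 0) stop_validation("`learning_rate` must be nonnegative")
  if (batch_size < 1 || epochs < 1) stop_validation("batch size and epochs must be positive")
  structure(
    list(depth = as.integer(depth), learning_rate = learning_rate,
         batch_size = as.integer(batch_size), base_kernels = as.integer(base_kernels),
         epochs = as.integer(epochs), seed = as.integer(seed), loss = loss,
         binarize_threshold = binarize_threshold, input_size = as.integer(input_size)),
    class = "unet_config"
  )
}

#' Encoder channel sequence of a configuration
#'
#' @param cfg A `unet_config`.
#' @return Integer vector `base_kernels * 2^(0:(depth-1))`.
#' @export
unet_channels <- function(cfg) cfg$base_kernels * 2^(seq_len(cfg$depth) - 1)

# layer plan shared by the initializer and the parameter counter; each row
# is one weighted layer: kind ("conv", "up", "final"), cin, cout
unet_layer_plan <- function(cfg) {
  ch <- unet_channels(cfg)
  d <- cfg$depth
  plan <- list()
  add <- function(kind, cin, cout) plan[[length(plan) + 1]] <<- list(kind = kind, cin = cin, cout = cout)
  cin <- 1
  for (k in seq_len(d)) {
    add("conv", cin, ch[k])
    add("conv", ch[k], ch[k])
    cin <- ch[k]
  }
  bott <- 2 * ch[d]
  add("conv", ch[d], bott)
  add("conv", bott, bott)
  for (k in rev(seq_len(d))) {  # deepest decoder level first
    up_in <- if (k == d) bott else ch[k + 1]
    add("up", up_in, ch[k])
    add("conv", 2 * ch[k], ch[k])
    add("conv", ch[k], ch[k])
  }
  add("final", ch[1], 1)
  plan
}

kernel_taps <- c(conv = 9L, up = 4L, final = 1L)

loss_code <- function(loss) c(bce = 0L, dice = 1L, bce_dice = 2L)[[loss]]

#' Total trainable parameter count
#'
#' A pure function of the configuration (weights + biases over all
#' convolution, transposed-convolution and output layers).
#'
#' @param cfg A `unet_config`.
#' @return Integer parameter count.
#' @export
unet_param_count <- function(cfg) {
  sum(vapply(unet_layer_plan(cfg), function(l) {
    kernel_taps[[l$kind]] * l$cin * l$cout + l$cout
  }, numeric(1)))
}

#' Build (initialize) a U-Net model
#'
#' Allocates He-initialized weights (normal with sd `sqrt(2 / fan_in)`) and
#' zero biases, deterministically from `cfg$seed`. The final 1x1 output
#' layer is zero-initialized so the network starts from a neutral
#' probability map (0.5 everywhere) instead of arbitrarily saturated
#' predictions — a standard stabilization for segmentation heads.
#'
#' @param cfg A [unet_config()].
#' @return A `unet_model`: list with `cfg` and `params` (flat list of
#'   weight arrays and bias vectors in engine order).
#' @export
build_unet <- function(cfg) {
  stopifnot(inherits(cfg, "unet_config"))
  plan <- unet_layer_plan(cfg)
  params <- withr::with_seed(cfg$seed, {
    out <- list()
    for (l in plan) {
      taps <- kernel_taps[[l$kind]]
      w <- if (l$kind == "final") {
        array(0, dim = c(l$cin, l$cout, taps))
      } else {
        array(stats::rnorm(l$cin * l$cout * taps, sd = sqrt(2 / (l$cin * taps))),
              dim = c(l$cin, l$cout, taps))
      }
      out[[length(out) + 1]] <- w
      out[[length(out) + 1]] <- numeric(l$cout)
    }
    out
  })
  structure(list(cfg = cfg, params = params), class = "unet_model")
}

#' @export
print.unet_model <- function(x, ...) {
  cat(sprintf("<unet_model> depth %d, base %d kernels (channels %s), %s parameters\n",
              x$cfg$depth, x$cfg$base_kernels,
              paste(unet_channels(x$cfg), collapse = "-"),
              format(unet_param_count(x$cfg), big.mark = ",")))
  invisible(x)
}

unet_probability <- function(params, image, depth) {
  x <- as_pixels(image)
  if (nrow(x) %% 2^depth != 0 || ncol(x) %% 2^depth != 0) {
    stop_validation("input size must be divisible by 2^depth")
  }
  cpp_unet_forward(params, x, depth)
}

#' Predict a segmentation mask
#'
#' Runs the forward pass and thresholds the probability map. Deterministic
#' given the weights.
#'
#' @param object A `unet_model` or `unet_fit` (which uses its
#'   best-validation weights).
#' @param newdata A preprocessed image (`mammogram` or numeric matrix) of
#'   the model's input size.
#' @param type `"mask"` (default) or `"prob"` for the raw probability map.
#' @param threshold Binarization cutoff; defaults to the configuration's.
#' @param ... Unused.
#' @return Logical mask or numeric probability matrix.
#' @export
predict.unet_model <- function(object, newdata, type = c("mask", "prob"),
                               threshold = NULL, ...) {
  type <- match.arg(type)
  threshold <- threshold %||% object$cfg$binarize_threshold
  p <- unet_probability(object$params, newdata, object$cfg$depth)
  if (type == "prob") p else p >= threshold
}

#' @rdname predict.unet_model
#' @export
predict.unet_fit <- function(object, newdata, type = c("mask", "prob"),
                             threshold = NULL, ...) {
  type <- match.arg(type)
  threshold <- threshold %||% object$cfg$binarize_threshold
  p <- unet_probability(object$params, newdata, object$cfg$depth)
  if (type == "prob") p else p >= threshold
}

check_pairs <- function(pairs, what) {
  pairs <- as_tibble(pairs)
  if (nrow(pairs) == 0) stop_validation(sprintf("%s set is empty", what))
  if (!all(c("image", "mask") %in% names(pairs))) {
    stop_validation(sprintf("%s pairs need list-columns `image` and `mask`", what))
  }
  pairs
}

#' Train a U-Net
#'
#' Mini-batch Adam on binary cross-entropy computed from logits. Images are
#' consumed at their stored intensity scale; masks are binary. Per-epoch
#' validation Dice (with the unmasked rule) is recorded and the weights
#' with the best validation Dice are retained. Fully reproducible: the same
#' configuration, seed and data give identical results.
#'
#' @param model A `unet_model` from [build_unet()].
#' @param train_pairs,val_pairs Data frames with list-columns `image`
#'   (numeric matrices at the input size) and `mask` (logical matrices).
#' @param verbose Print per-epoch progress.
#' @return A `unet_fit`: list with `cfg`, `params` (best-validation
#'   weights), `final_params`, `history` tibble (epoch, loss, val_dice),
#'   `best_epoch`, `best_val_dice`.
#' @export
train_unet <- function(model, train_pairs, val_pairs, verbose = FALSE) {
  stopifnot(inherits(model, "unet_model"))
  cfg <- model$cfg
  train_pairs <- check_pairs(train_pairs, "training")
  val_pairs <- check_pairs(val_pairs, "validation")
  xs <- purrr::map(train_pairs$image, as_pixels)
  ys <- purrr::map(train_pairs$mask, function(m) as_mask(m) * 1)
  sz <- dim(xs[[1]])
  ok <- purrr::every(c(xs, ys), function(m) identical(dim(m), sz))
  if (!ok) stop_validation("all training images and masks must share one size")
  if (any(sz %% 2^cfg$depth != 0)) {
    stop_validation("training image size must be divisible by 2^depth")
  }

  params <- model$params
  np <- length(params)
  m_state <- lapply(params, function(p) { p[] <- 0; p })
  v_state <- m_state
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  step <- 0L

  val_dice_of <- function(par) {
    mean(purrr::map2_dbl(val_pairs$mask, val_pairs$image, function(truth, im) {
      p <- cpp_unet_forward(par, as_pixels(im), cfg$depth)
      dice_with_unmasked_rule(as_mask(truth), p >= cfg$binarize_threshold)$dice
    }))
  }

  history <- vector("list", cfg$epochs)
  best <- list(dice = -Inf, params = params, epoch = 0L)

  withr::with_seed(cfg$seed, {
    n <- length(xs)
    for (epoch in seq_len(cfg$epochs)) {
      idx <- sample.int(n)
      batches <- split(idx, ceiling(seq_along(idx) / cfg$batch_size))
      losses <- numeric(length(batches))
      for (b in seq_along(batches)) {
        take <- batches[[b]]
        grads <- lapply(params, function(p) { p[] <- 0; p })
        loss <- cpp_unet_batch_grad(params, grads, xs[take], ys[take], cfg$depth,
                                    loss_code(cfg$loss))
        if (!is.finite(loss)) {
          abort(sprintf("non-finite loss at epoch %d, batch %d", epoch, b),
                class = c("glandseg_training_error", "glandseg_error"))
        }
        losses[b] <- loss
        step <- step + 1L
        for (i in seq_len(np)) {
          g <- grads[[i]]
          m_state[[i]] <- b1 * m_state[[i]] + (1 - b1) * g
          v_state[[i]] <- b2 * v_state[[i]] + (1 - b2) * g * g
          mhat <- m_state[[i]] / (1 - b1^step)
          vhat <- v_state[[i]] / (1 - b2^step)
          params[[i]] <- params[[i]] - cfg$learning_rate * mhat / (sqrt(vhat) + eps)
        }
      }
      vd <- val_dice_of(params)
      history[[epoch]] <- tibble(epoch = epoch, loss = mean(losses), val_dice = vd)
      if (vd > best$dice) best <- list(dice = vd, params = params, epoch = epoch)
      if (verbose) {
        message(sprintf("epoch %3d  loss %.4f  val Dice %.4f", epoch, mean(losses), vd))
      }
    }
  })

  structure(
    list(
      cfg = cfg,
      params = best$params,
      final_params = params,
      history = dplyr::bind_rows(history),
      best_epoch = best$epoch,
      best_val_dice = best$dice
    ),
    class = "unet_fit"
  )
}

#' @export
print.unet_fit <- function(x, ...) {
  cat(sprintf("<unet_fit> depth %d, lr %g, batch %d: best val Dice %.3f at epoch %d/%d\n",
              x$cfg$depth, x$cfg$learning_rate, x$cfg$batch_size,
              x$best_val_dice, x$best_epoch, x$cfg$epochs))
  invisible(x)
}

#' @rdname train_unet
#' @param x A `unet_fit`.
#' @param ... Unused.
#' @export
tidy.unet_fit <- function(x, ...) x$history

#' @rdname train_unet
#' @export
glance.unet_fit <- function(x, ...) {
  tibble(
    depth = x$cfg$depth,
    learning_rate = x$cfg$learning_rate,
    batch_size = x$cfg$batch_size,
    base_kernels = x$cfg$base_kernels,
    epochs = x$cfg$epochs,
    n_parameters = unet_param_count(x$cfg),
    best_epoch = x$best_epoch,
    best_val_dice = x$best_val_dice
  )
}

#' Plot a training history
#'
#' @param object A `unet_fit`.
#' @param ... Unused.
#' @return A ggplot of loss and validation Dice over epochs.
#' @export
autoplot.unet_fit <- function(object, ...) {
  long <- tidyr::pivot_longer(object$history, c("loss", "val_dice"),
                              names_to = "metric")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$epoch, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::theme_minimal()
}

#' Desk-scale demonstration U-Net configuration
#'
#' The configuration used by the package's demonstration experiment and
#' its documentation: the shallow end of the study grid (depth 3) at the
#' grid's small learning rate and batch size (0.0001 / 16), 20 epochs,
#' 128 x 128 inputs, and 16 base kernels — a width chosen so a full
#' training run takes about two minutes on one CPU core while still
#' converging within the short epoch budget.
#'
#' @param seed Seed for initialization and shuffling.
#' @return A [unet_config()].
#' @export
demo_unet_config <- function(seed = 1L) {
  unet_config(depth = 3L, learning_rate = 1e-4, batch_size = 16L,
              base_kernels = 16L, epochs = 20L, seed = seed,
              input_size = 128L)
}

#' Enumerate the study's parameter grid
#'
#' The full grid crosses 5 depths, 2 learning rates and 2 batch sizes (20
#' configurations). Arguments override each axis for desk-scale runs.
#'
#' @param depths,learning_rates,batch_sizes Grid axes.
#' @param ... Further arguments shared by every cell, passed to
#'   [unet_config()].
#' @return A tibble with columns `depth`, `learning_rate`, `batch_size` and
#'   a `config` list-column.
#' @export
unet_grid <- function(depths = c(3, 4, 5, 6, 7),
                      learning_rates = c(0.001, 0.0001),
                      batch_sizes = c(16, 32), ...) {
  g <- tidyr::expand_grid(depth = depths, learning_rate = learning_rates,
                          batch_size = batch_sizes)
  g$config <- purrr::pmap(g, function(depth, learning_rate, batch_size) {
    unet_config(depth = depth, learning_rate = learning_rate,
                batch_size = batch_size, ...)
  })
  g
}

#' Run a training grid with replicates
#'
#' Trains every configuration `replicates` times (replicate r uses seed
#' `config$seed + r - 1`), evaluates the mean test Dice (unmasked rule) of
#' each fit, and reports one row per configuration with the per-replicate
#' and averaged Dice — the layout of a grid-comparison table. A failing
#' cell is recorded with `NA` Dice and its error message; remaining cells
#' continue.
#'
#' @param grid A tibble from [unet_grid()] (needs a `config` list-column).
#' @param train_pairs,val_pairs,test_pairs Data frames with `image`/`mask`
#'   list-columns (`test_pairs` may also carry `category`).
#' @param replicates Training repetitions per cell (default 3).
#' @param keep_fits Keep the fitted models in a list-column (default FALSE;
#'   weights are large).
#' @return A tibble: grid axes, `replicate_dice` list-column, `mean_dice`,
#'   `error`.
#' @export
run_grid <- function(grid, train_pairs, val_pairs, test_pairs,
                     replicates = 3L, keep_fits = FALSE) {
  stopifnot("config" %in% names(grid), replicates >= 1)
  rows <- purrr::map(seq_len(nrow(grid)), function(i) {
    cfg <- grid$config[[i]]
    fits <- list()
    dices <- rep(NA_real_, replicates)
    err <- NA_character_
    for (r in seq_len(replicates)) {
      res <- tryCatch({
        cfg_r <- cfg
        cfg_r$seed <- cfg$seed + r - 1L
        fit <- train_unet(build_unet(cfg_r), train_pairs, val_pairs)
        d <- mean(purrr::map2_dbl(test_pairs$mask, test_pairs$image,
                                  function(truth, im) {
          dice_with_unmasked_rule(as_mask(truth), predict(fit, im))$dice
        }))
        list(fit = fit, dice = d)
      }, error = function(e) e)
      if (inherits(res, "error")) {
        err <- conditionMessage(res)
        break
      }
      dices[r] <- res$dice
      if (keep_fits) fits[[r]] <- res$fit
    }
    out <- tibble(
      depth = cfg$depth,
      learning_rate = cfg$learning_rate,
      batch_size = cfg$batch_size,
      replicate_dice = list(dices),
      mean_dice = if (all(is.na(dices))) NA_real_ else mean(dices, na.rm = TRUE),
      error = err
    )
    if (keep_fits) out$fits <- list(fits)
    out
  })
  dplyr::bind_rows(rows)
}
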
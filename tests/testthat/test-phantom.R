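test_that("phantom generation is deterministic and validates its spec", {
  s <- phantom_spec(target_content_ratio = 0.4, seed = 5, height = 96L, width = 72L)
  b1 <- generate_phantom(s)
  b2 <- generate_phantom(s)
  expect_identical(b1$image$pixels, b2$image$pixels)
  expect_identical(b1$gland_truth, b2$gland_truth)

  expect_error(phantom_spec(target_content_ratio = 1.2),
               class = "glandseg_validation_error")
  expect_error(phantom_spec(height = 64, width = 128),
               class = "glandseg_validation_error")
  expect_error(phantom_spec(bit_depth = 20), class = "glandseg_validation_error")
})

test_that("zero-ratio phantoms are unmasked and labelled fatty", {
  b <- tiny_phantom(ratio = 0, seed = 2)
  expect_equal(sum(b$gland_truth), 0)
  expect_true(b$unmasked)
  expect_equal(b$category, "fatty")
})

test_that("phantom masks satisfy the geometric invariants", {
  for (seed in 1:3) {
    b <- tiny_phantom(ratio = c(0.2, 0.65, 0.9)[seed], seed = seed)
    expect_true(all(b$gland_truth <= b$calc_region))        # gland within calc
    expect_equal(sum(b$pectoral & b$calc_region), 0)        # pectoral excluded
    expect_true(all(b$calc_region <= b$breast))
    # gland brightness sits at or above the pectoral mean
    if (any(b$gland_truth)) {
      expect_gte(min(b$image$pixels[b$gland_truth]),
                 mean(b$image$pixels[b$pectoral]))
    }
    # background outside the breast is near zero
    expect_lt(max(b$image$pixels[!b$breast]) / max_intensity(b$spec$bit_depth), 0.05)
  }
})

test_that("measured content ratio hits the target and label is consistent", {
  for (r in c(0.05, 0.30, 0.65, 0.90)) {
    for (seed in 1:5) {
      b <- tiny_phantom(ratio = r, seed = seed)
      expect_lte(abs(b$measured_ratio - r), 0.02)
      lab <- classify_composition(b$measured_ratio)
      expect_equal(b$category, as.character(lab$category))
      expect_equal(b$grouping, as.character(lab$grouping))
    }
  }
})

test_that("right-laterality phantoms mirror the left-laterality geometry", {
  bl <- generate_phantom(phantom_spec(target_content_ratio = 0.4, seed = 9,
                                      laterality = "left", noise_sd = 0,
                                      height = 96L, width = 72L))
  br <- generate_phantom(phantom_spec(target_content_ratio = 0.4, seed = 9,
                                      laterality = "right", noise_sd = 0,
                                      height = 96L, width = 72L))
  expect_identical(br$image$pixels, flip_horizontal(bl$image$pixels))
  expect_identical(br$gland_truth, flip_horizontal(bl$gland_truth))
})

test_that("emulated correction deletes vessel components but never adds pixels", {
  b <- tiny_phantom(ratio = 0.35, seed = 4)
  objective <- b$gland_truth | (b$vessels & b$calc_region)
  corrected <- emulate_correction(objective, b)

  expect_true(all(corrected <= objective))                 # subset, per pixel
  vessel_only <- b$vessels & b$calc_region & !b$gland_truth
  expect_equal(sum(corrected & vessel_only), 0)            # vessel components gone
  expect_equal(sum(corrected & b$gland_truth), sum(b$gland_truth))  # gland kept

  # identity and empty cases
  expect_identical(emulate_correction(b$gland_truth, b), b$gland_truth)
  empty <- b$gland_truth & FALSE
  expect_identical(emulate_correction(empty, b), empty)

  expect_error(emulate_correction(matrix(TRUE, 3, 3), b),
               class = "glandseg_validation_error")
})

test_that("correction subset property holds on thresholded masks across seeds", {
  for (seed in 1:5) {
    b <- tiny_phantom(ratio = 0.3, seed = seed)
    h <- compute_histogram(b$image, b$calc_region)
    obj <- extract_objective_mask(b$image, b$calc_region, select_threshold(h))
    corr <- emulate_correction(obj, b)
    expect_true(all(corr <= obj))
  }
})

test_that("phantom_dataset builds a coherent manifest", {
  ds <- phantom_dataset(6, seed = 3, height = 96L, width = 72L, noise_sd = 0)
  expect_equal(nrow(ds), 6L)
  expect_equal(ds$measured_ratio, purrr::map_dbl(ds$bundle, "measured_ratio"))
  expect_true(all(ds$target_ratio >= 0.05 & ds$target_ratio <= 0.90))
  # reproducible
  ds2 <- phantom_dataset(6, seed = 3, height = 96L, width = 72L, noise_sd = 0)
  expect_identical(ds$bundle[[4]]$image$pixels, ds2$bundle[[4]]$image$pixels)
})

test_that("phantom bundles round-trip through disk", {
  ds <- phantom_dataset(2, seed = 8, height = 96L, width = 72L)
  dir <- withr::local_tempdir()
  manifest <- write_phantom_dataset(ds, dir)
  expect_true(file.exists(file.path(dir, "manifest.csv")))
  img <- read_mammogram(manifest$image[1])
  expect_identical(img$pixels, ds$bundle[[1]]$image$pixels)
  expect_identical(img$laterality, ds$bundle[[1]]$image$laterality)
  m <- read_mask(manifest$gland_truth[1])
  expect_identical(m, ds$bundle[[1]]$gland_truth)
})
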
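make_img <- function(m, px = 1, channel = "other") {
  channel_image(m, pixel_size_um = px, channel = channel)
}

test_that("background subtraction removes flat background, keeps small objects", {
  flat <- make_img(matrix(0.37, 40, 40))
  expect_true(all(subtract_background(flat, 5)$pixels == 0))

  m <- matrix(0.1, 40, 40)
  m[19:21, 19:21] <- 0.9
  out <- subtract_background(make_img(m), 10)
  ref <- pmax(m - oracle_opening(m, 10), 0)
  expect_equal(out$pixels, ref, tolerance = 1e-12)
  expect_equal(out$pixels[20, 20], 0.8, tolerance = 0.01 * 0.8)
  expect_true(all(out$pixels[1:5, 1:5] == 0))

  # idempotence on an already background-free sparse image
  twice <- subtract_background(out, 10)
  expect_equal(twice$pixels, out$pixels, tolerance = 1e-6)

  expect_error(subtract_background(make_img(matrix(0, 10, 10)), 20),
               "exceeds")
})

test_that("contrast enhancement rescales the percentile window to [0, 1]", {
  span <- make_img(matrix(seq(0, 1, length.out = 100), 10, 10))
  expect_equal(enhance_contrast(span, 0, 100)$pixels, span$pixels,
               tolerance = 1e-12)

  two <- make_img(matrix(rep(c(0.2, 0.8), 50), 10, 10))
  out <- enhance_contrast(two, 0, 100)
  expect_setequal(unique(as.vector(out$pixels)), c(0, 1))

  set.seed(8)
  rnd <- make_img(matrix(runif(400, 0.2, 0.9), 20, 20))
  out2 <- enhance_contrast(rnd, 2, 98)
  expect_equal(min(out2$pixels), 0)
  expect_equal(max(out2$pixels), 1)
  p <- quantile(rnd$pixels, c(0.02, 0.98), names = FALSE)
  inner <- rnd$pixels > p[1] & rnd$pixels < p[2]
  expect_equal(out2$pixels[inner],
               (rnd$pixels[inner] - p[1]) / (p[2] - p[1]),
               tolerance = 1e-12)

  expect_error(enhance_contrast(make_img(matrix(0.5, 5, 5)), 0, 100),
               "degenerate")
})

test_that("Otsu binarization matches the exhaustive sweep oracle", {
  m <- matrix(c(rep(0.1, 1000), rep(0.9, 100)), nrow = 50)
  img <- make_img(m)
  bz <- binarize(img)
  expect_gt(bz$threshold_used, 0.1)
  expect_lt(bz$threshold_used, 0.9)
  expect_equal(sum(bz$mask), 100)
  expect_equal(bz$threshold_used, oracle_otsu_sweep(as.vector(m)),
               tolerance = 1e-9)

  set.seed(12)
  rnd <- matrix(c(rnorm(300, 0.3, 0.05), rnorm(100, 0.8, 0.05)), 20, 20)
  rnd <- pmin(pmax(rnd, 0), 1)
  expect_equal(binarize(make_img(rnd))$threshold_used,
               oracle_otsu_sweep(as.vector(rnd)), tolerance = 1e-9)
})

test_that("Otsu threshold is shift-equivariant; fixed threshold is literal", {
  set.seed(4)
  m <- matrix(c(rnorm(200, 0.2, 0.04), rnorm(200, 0.6, 0.04)), 20, 20)
  t1 <- binarize(make_img(m))$threshold_used
  t2 <- binarize(make_img(m + 0.25))$threshold_used
  expect_equal(t2 - t1, 0.25, tolerance = 1e-12)

  fx <- binarize(make_img(matrix(c(0.4, 0.6), 10, 10)), "fixed",
                 fixed_threshold = 0.5)
  expect_identical(fx$mask, matrix(c(0.4, 0.6), 10, 10) > 0.5)

  expect_error(binarize(make_img(matrix(1, 5, 5))), "constant")
  expect_error(binarize(make_img(matrix(runif(25), 5, 5)), "fixed"),
               "fixed_threshold")
})

test_that("positive pixel percentage is an exact ROI count ratio", {
  roi <- roi_mask(matrix(rep(c(TRUE, FALSE), c(1000, 96)), 2, 548)[, 1:500])
  expect_equal(sum(roi$mask), 1000)
  none <- matrix(FALSE, 2, 500)
  expect_equal(positive_pixel_pct(none, roi), 0)
  expect_equal(positive_pixel_pct(roi$mask, roi), 100)
  some <- none
  some[seq_len(37)] <- TRUE
  expect_equal(positive_pixel_pct(some, roi), 3.7)
  # invariant to pixels outside the ROI
  outside <- some
  outside[!roi$mask] <- TRUE
  expect_equal(positive_pixel_pct(outside, roi), 3.7)
  # monotone in the mask
  more <- some; more[38:50] <- TRUE
  expect_gte(positive_pixel_pct(more, roi), positive_pixel_pct(some, roi))
  expect_error(positive_pixel_pct(none[, 1:10],
                                  roi_mask(matrix(TRUE, 5, 5))),
               "differ")
})

test_that("mean intensity matches the naive summation oracle and is linear", {
  expect_equal(mean_intensity(make_img(matrix(7.7, 6, 6)),
                              roi_mask(matrix(TRUE, 6, 6))), 7.7)
  half <- matrix(rep(c(10, 20), each = 18), 6, 6)
  expect_equal(mean_intensity(make_img(half), roi_mask(matrix(TRUE, 6, 6))),
               15)
  set.seed(2)
  m <- matrix(runif(900), 30, 30)
  roi <- roi_mask(matrix(runif(900) > 0.5, 30, 30))
  naive <- sum(m[roi$mask]) / sum(roi$mask)
  expect_equal(mean_intensity(make_img(m), roi), naive, tolerance = 1e-12)
  expect_equal(mean_intensity(make_img(3 * m), roi), 3 * naive,
               tolerance = 1e-12)
})

test_that("component labeling is 8-connected", {
  m <- matrix(FALSE, 6, 6)
  m[2, 2] <- TRUE; m[3, 3] <- TRUE    # diagonal touch
  m[5, 5] <- TRUE                     # separate
  lab <- label_components(m)
  expect_equal(max(lab), 2)
  expect_equal(lab[2, 2], lab[3, 3])
  expect_true(lab[5, 5] != lab[2, 2])
})

test_that("nuclei counting recovers ground truth on seeded phantoms", {
  for (seed in 1:20) {
    n_true <- 20 + (seed %% 3) * 10
    spec <- image_phantom_spec(width_px = 192, height_px = 192,
                               nucleus_count = n_true,
                               nucleus_radius_px = 4, noise_sd = 0.02,
                               channel = "DAPI", seed = seed)
    ph <- gen_fluorescence_image(spec)
    roi <- roi_mask(matrix(TRUE, 192, 192))
    res <- count_nuclei(ph$image, roi)
    expect_equal(res$n_objects, n_true)
  }
})

test_that("empty phantom yields zero objects and density", {
  spec <- image_phantom_spec(width_px = 96, height_px = 96, noise_sd = 0.01,
                             seed = 5)
  ph <- gen_fluorescence_image(spec)
  res <- count_nuclei(ph$image, roi_mask(matrix(TRUE, 96, 96)))
  expect_equal(res$n_objects, 0)
  expect_equal(res$cell_density_per_mm2, 0)
})

test_that("cell density follows the pixel-scale area arithmetic", {
  px <- 0.5128
  spec <- image_phantom_spec(width_px = 384, height_px = 384,
                             pixel_size_um = px, nucleus_count = 100,
                             nucleus_radius_px = 4, noise_sd = 0.01,
                             channel = "DAPI", seed = 31)
  ph <- gen_fluorescence_image(spec)
  roi <- roi_mask(matrix(TRUE, 384, 384))
  res <- count_nuclei(ph$image, roi)
  area_mm2 <- 384^2 * px^2 * 1e-6
  expect_equal(res$cell_density_per_mm2, res$n_objects / area_mm2,
               tolerance = 1e-12)
  expect_equal(res$n_objects, 100)
  # a full 1 mm^2 ROI at this scale would span ~3.803e6 pixels
  expect_equal(1e6 / px^2, 3.803e6, tolerance = 1e-4)
})

test_that("Otsu-path outputs are invariant under intensity scaling", {
  spec <- image_phantom_spec(width_px = 128, height_px = 128,
                             nucleus_count = 15, noise_sd = 0.02, seed = 17)
  ph <- gen_fluorescence_image(spec)
  roi <- roi_mask(matrix(TRUE, 128, 128))
  scaled <- channel_image(ph$image$pixels * 0.5, ph$image$pixel_size_um,
                          ph$image$channel)
  m1 <- binarize(enhance_contrast(subtract_background(ph$image), 0, 100))
  m2 <- binarize(enhance_contrast(subtract_background(scaled), 0, 100))
  expect_equal(positive_pixel_pct(m1$mask, roi),
               positive_pixel_pct(m2$mask, roi), tolerance = 0.2)
  expect_equal(count_nuclei(ph$image, roi)$n_objects,
               count_nuclei(scaled, roi)$n_objects)
})
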
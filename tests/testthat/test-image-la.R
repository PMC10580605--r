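solid_image <- function(rgb, h = 8, w = 10) {
  array(rep(rgb, each = h * w), c(h, w, 3))
}

test_that("sRGB to CIELAB conversion hits the reference anchor points", {
  lab <- srgb_to_lab(solid_image(c(255, 255, 255)))
  expect_equal(lab$L[1, 1], 100, tolerance = 1e-3)
  expect_lt(abs(lab$a[1, 1]), 0.01)
  expect_lt(abs(lab$b[1, 1]), 0.01)
  lab0 <- srgb_to_lab(solid_image(c(0, 0, 0)))
  expect_equal(lab0$L[1, 1], 0, tolerance = 1e-6)
  labg <- srgb_to_lab(solid_image(c(119, 119, 119)))
  expect_lt(abs(labg$a[1, 1]), 0.5)
  expect_lt(abs(labg$b[1, 1]), 0.5)
  # published sRGB/D65 primaries: R (53.2, 80.1, 67.2), G (87.7, -86.2,
  # 83.2), B (32.3, 79.2, -107.9), within 1 unit per channel
  labr <- srgb_to_lab(solid_image(c(255, 0, 0)))
  expect_equal(c(labr$L[1, 1], labr$a[1, 1], labr$b[1, 1]),
               c(53.2, 80.1, 67.2), tolerance = 1)
  labgr <- srgb_to_lab(solid_image(c(0, 255, 0)))
  expect_equal(c(labgr$L[1, 1], labgr$a[1, 1], labgr$b[1, 1]),
               c(87.7, -86.2, 83.2), tolerance = 1)
  labb <- srgb_to_lab(solid_image(c(0, 0, 255)))
  expect_equal(c(labb$L[1, 1], labb$a[1, 1], labb$b[1, 1]),
               c(32.3, 79.2, -107.9), tolerance = 1)
  expect_error(srgb_to_lab(matrix(1, 3, 3)), "H x W x 3")
})

test_that("warm-half clipping zeroes only the negative opponent values", {
  lab <- list(L = matrix(50), a = matrix(-50), b = matrix(20))
  clipped <- clip_warm_channels(lab)
  expect_equal(clipped$a[1, 1], 0)
  expect_equal(clipped$b[1, 1], 20)
  expect_equal(clipped$L[1, 1], 50)
  lab2 <- list(L = matrix(50), a = matrix(30), b = matrix(-100))
  clipped2 <- clip_warm_channels(lab2)
  expect_equal(clipped2$a[1, 1], 30)
  expect_equal(clipped2$b[1, 1], 0)
  # fixed point
  lab3 <- list(L = matrix(50), a = matrix(0), b = matrix(0))
  expect_equal(clip_warm_channels(lab3), lab3)
})

test_that("warm/cool mask counts partition the pixels", {
  green <- srgb_to_lab(solid_image(c(60, 110, 50)))
  mg <- warm_cool_mask(green)
  expect_equal(mg$warm_count, 0)
  expect_equal(mg$cool_count, 80)
  straw <- srgb_to_lab(solid_image(c(190, 140, 80)))
  ms <- warm_cool_mask(straw)
  expect_equal(ms$cool_count, 0)
  # half green / half straw: warm fraction exactly 0.5
  img <- solid_image(c(60, 110, 50), h = 10, w = 10)
  img[, 6:10, ] <- solid_image(c(190, 140, 80), h = 10, w = 5)
  mh <- warm_cool_mask(clip_warm_channels(srgb_to_lab(img)))
  expect_equal(mh$warm_count + mh$cool_count, 100)
  expect_equal(lodged_area_percent(mh), 50)
})

test_that("lodged-area percent is a pure pixel census", {
  img <- solid_image(c(60, 110, 50), h = 10, w = 10)
  img[, 1:3, ] <- solid_image(c(190, 140, 80), h = 10, w = 3)
  expect_equal(estimate_la_from_image(img), 30)
  # permutation invariance
  withr::with_seed(1, {
    perm <- sample(100)
    shuffled <- img
    for (ch in 1:3) {
      shuffled[, , ch] <- matrix(as.vector(img[, , ch])[perm], 10, 10)
    }
    expect_equal(estimate_la_from_image(shuffled), 30)
  })
  # painting a cool pixel warm never decreases the estimate
  img2 <- img
  img2[1, 10, ] <- c(190, 140, 80)
  expect_gte(estimate_la_from_image(img2), estimate_la_from_image(img))
  # verbose output carries the raw black:white ratio
  msk <- warm_cool_mask(clip_warm_channels(srgb_to_lab(img)))
  v <- lodged_area_percent(msk, verbose = TRUE)
  expect_equal(v$black_white_ratio, 70 / 30, tolerance = 1e-12)
})

test_that("estimator recovers generator truth on noiseless canopies", {
  for (la in c(0, 40, 100)) {
    gen <- gen_canopy_image(canopy_gen_config(la_true = la, seed = 11 + la))
    truth <- 100 * mean(gen$truth_mask)
    expect_lte(abs(truth - la), 0.5)
    expect_lte(abs(estimate_la_from_image(gen$pixels) - truth), 1)
  }
})

test_that("estimator tolerates additive RGB noise", {
  errs <- vapply(1:5, function(s) {
    gen <- gen_canopy_image(canopy_gen_config(la_true = 40, noise_sd = 8,
                                              seed = s))
    abs(estimate_la_from_image(gen$pixels) - 40)
  }, numeric(1))
  expect_lte(mean(errs), 5)
})

test_that("images round-trip through PNG files with exact mask recovery", {
  tmp <- withr::local_tempfile(fileext = ".png")
  gen <- gen_canopy_image(canopy_gen_config(la_true = 30, seed = 3))
  png::writePNG(gen$pixels / 255, tmp)
  est_disk <- estimate_la_from_image(tmp)
  expect_equal(est_disk, estimate_la_from_image(gen$pixels),
               tolerance = 1e-9)
  mtmp <- withr::local_tempfile(fileext = ".png")
  write_mask_png(gen$truth_mask, mtmp)
  back <- png::readPNG(mtmp)
  expect_equal(matrix(as.integer(back > 0.5), nrow(back)), gen$truth_mask)
  # batch interface
  df <- la_from_images(c(tmp, tmp))
  expect_equal(nrow(df), 2)
  expect_equal(df$la_pct[1], est_disk)
  expect_equal(df$warm_count + df$cool_count, rep(120 * 160, 2))
})

test_that("configurable predicate and affine calibration are honored", {
  img <- solid_image(c(60, 110, 50), h = 10, w = 10)
  img[, 1:5, ] <- solid_image(c(190, 140, 80), h = 10, w = 5)
  # warm-intensity rule with a high threshold goes all-cool
  strict <- warm_intensity_predicate(w_a = 1, w_b = 0, tau = 50)
  expect_equal(estimate_la_from_image(img, predicate = strict), 0)
  expect_equal(estimate_la_from_image(img, calibration = c(10, 0.5)),
               10 + 0.5 * 50)
  expect_equal(estimate_la_from_image(img, crop = c(1, 10, 1, 5)), 100)
})
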
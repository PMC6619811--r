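test_that("the valid-pixel threshold follows the diagonal-minus-two form", {
  expect_identical(valid_pixel_threshold(100), 12L)
  expect_identical(valid_pixel_threshold(25), 5L)
  expect_identical(valid_pixel_threshold(9), 2L)
  expect_error(valid_pixel_threshold(8), "at least 9")
  # monotone in window size
  ns <- c(9, 25, 49, 81, 100, 169, 400)
  expect_true(all(diff(valid_pixel_threshold(ns)) >= 0))
})

test_that("denoise removes scatter, keeps lines, and matches the rule oracle", {
  # all-background stays all-background
  expect_false(any(denoise_roughen(matrix(FALSE, 20, 20))))

  # one isolated pixel is removed (N_valid = 1 below threshold)
  m <- matrix(FALSE, 30, 30); m[15, 15] <- TRUE
  expect_false(any(denoise_roughen(m)))

  # a solid 1-px line crossing the mask is retained and thickened
  line <- matrix(FALSE, 40, 40); line[20, ] <- TRUE
  out <- denoise_roughen(line)
  expect_true(all(out[20, 3:38]))
  expect_true(all(out[19, 10:30]))  # thickened at least 1 px each side
  expect_true(all(out[21, 10:30]))
  expect_identical(out, oracle_denoise(line))

  # random masks agree with the literal brute-force evaluation
  set.seed(61)
  for (i in 1:6) {
    mk <- random_mask(24, 24, density = runif(1, 0.05, 0.3))
    expect_identical(denoise_roughen(mk), oracle_denoise(mk))
  }
})

test_that("denoise never creates foreground where a window saw none", {
  set.seed(62)
  mk <- matrix(FALSE, 40, 40)
  mk[5:12, 5:12] <- random_mask(8, 8, 0.6)
  out <- denoise_roughen(mk)
  # far corner windows contain no input foreground
  expect_false(any(out[25:40, 25:40]))
})

test_that("background threshold follows T_b = p_min + (p_max - p_min)/delta", {
  expect_equal(background_threshold(c(10, 60, 110), suppression_params(3.7)),
               10 + 100 / 3.7)
  expect_equal(background_threshold(rep(42, 5)), 42)
  expect_equal(background_threshold(c(0, 120, 200), suppression_params(4)), 50)
  expect_error(background_threshold(numeric(0)), "empty")
})

test_that("background suppression is identity at delta 3, fixes T_b and matches hand values", {
  set.seed(63)
  px <- matrix(sample(1:255, 100, TRUE), 10, 10)
  mask <- matrix(FALSE, 10, 10); mask[5, 5] <- TRUE
  out3 <- suppress_background(px, suppression_params(3), mask = mask)
  expect_identical(out3, matrix(as.integer(px), 10, 10))

  # p' = 50 + 5 * (50 - 37.027) * 0.7 = 95.4 -> 95
  px2 <- matrix(c(10, 50, 110, 0), 2, 2)
  out <- suppress_background(px2, suppression_params(3.7),
                             mask = matrix(FALSE, 2, 2))
  expect_identical(out[2, 1], 95L)
  expect_identical(out[2, 2], 0L)        # exact zeros untouched
  expect_identical(out[1, 1], 0L)        # below threshold darkens to clamp
  expect_identical(out[1, 2], 255L)      # above threshold amplifies to clamp

  # p = T_b is a fixed point: nonzero background {50, 100, 225} with
  # delta 3.5 gives T_b = 50 + 175/3.5 = 100
  px3 <- matrix(c(50, 100, 225, 0), 2, 2)
  out3b <- suppress_background(px3, suppression_params(3.5),
                               mask = matrix(FALSE, 2, 2))
  expect_identical(out3b[2, 1], 100L)
})

test_that("suppression is monotone in p before clamping and bounded after", {
  p <- seq(1, 255)
  tb <- 80
  for (d in c(3, 3.3, 3.7, 4)) {
    tr <- p + 5 * (p - tb) * (d - 3)
    expect_true(all(diff(tr) > 0))
  }
  set.seed(64)
  px <- matrix(sample(0:255, 400, TRUE), 20, 20)
  mask <- random_mask(20, 20, 0.3)
  out <- suppress_background(px, suppression_params(3.9), mask = mask)
  expect_gte(min(out), 0L)
  expect_lte(max(out), 255L)
  expect_identical(out[mask], matrix(as.integer(px), 20, 20)[mask])
})

test_that("full ROI enhancement raises the target/background contrast on a noisy crop", {
  sc <- render_scene(scene_preset("hard", n_targets = 1, seed = 21))
  rois <- extract_rois(sc$frame)
  expect_gte(length(rois), 1L)
  r <- enhance_roi(rois[[1]])
  expect_false(is.null(r$enhanced_crop))
  bg <- !r$mask_crop & r$gray_crop > 0
  if (any(bg)) {
    before <- mean(r$gray_crop[r$mask_crop]) / max(mean(r$gray_crop[bg]), 1)
    after <- mean(r$enhanced_crop[r$mask_crop]) /
      max(mean(r$enhanced_crop[bg]), 1)
    expect_gte(after, before)
  }
  # constant background: only background pixels change, target is intact
  px <- matrix(30L, 12, 12); mask <- matrix(FALSE, 12, 12)
  mask[4:8, 4:8] <- TRUE; px[mask] <- 200L
  rr <- roi(bounding_box(0, 12, 0, 12), px, mask, roi_id = "c")
  er <- suppress_background(rr, suppression_params(3.7))
  expect_identical(er$enhanced_crop[mask], px[mask])
  expect_identical(er$enhanced_crop[!mask], px[!mask]) # constant bg = T_b fixed point
})
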
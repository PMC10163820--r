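test_that("estimate_dark_image is a per-pixel median with oracle agreement", {
  f <- matrix(runif(64, 90, 110), 8, 8)
  expect_equal(estimate_dark_image(list(f, f, f)), f)
  # robust to a hot outlier
  z <- matrix(0, 4, 4)
  hot <- matrix(100, 4, 4)
  expect_equal(estimate_dark_image(list(z, z, hot)), z)
  set.seed(42)
  stack <- replicate(5, matrix(rnorm(256, 100, 3), 16, 16), simplify = FALSE)
  expect_equal(estimate_dark_image(stack), oracle_stack_median(stack))
  expect_error(estimate_dark_image(list()), "non-empty")
  expect_error(estimate_dark_image(list(z, matrix(0, 5, 5))), "shape")
})

test_that("subtract_dark subtracts without clipping", {
  f <- matrix(100, 6, 6)
  d <- matrix(3, 6, 6)
  expect_equal(subtract_dark(f, d), matrix(97, 6, 6))
  expect_equal(subtract_dark(f, f), matrix(0, 6, 6))
  expect_equal(subtract_dark(f, matrix(0, 6, 6)), f)
  # may go negative
  expect_true(all(subtract_dark(d, f) == -97))
  expect_error(subtract_dark(f, matrix(3, 5, 6)), "shape")
})

test_that("build_ratio_correction reproduces constants and gradients", {
  H <- 96L; W <- 120L
  full <- matrix(TRUE, H, W)
  # constant calibration ratio -> constant correction
  rc <- build_ratio_correction(list(matrix(1.7, H, W)), full, 24, 5)
  expect_lt(max(abs(rc$image - 1.7)), 1e-6)
  # linear top-to-bottom gradient 1.0 -> 1.2 recovered within 2% at block centres
  grad <- matrix(seq(1.0, 1.2, length.out = H), H, W)
  rc2 <- build_ratio_correction(list(grad), full, 24, 5)
  centers <- seq(12, H - 12, by = 24)
  expect_lt(max(abs(rc2$image[centers, 60] / grad[centers, 60] - 1)), 0.02)
  # block larger than the image -> constant global median
  rc3 <- build_ratio_correction(list(grad), full, 1000, 5)
  expect_lt(diff(range(rc3$image)), 1e-9)
  expect_equal(rc3$image[1, 1], median(grad))
  # masked-out pixels are ignored; empty blocks filled from neighbours
  msk <- full
  msk[, 1:30] <- FALSE
  rc4 <- build_ratio_correction(list(matrix(1.3, H, W)), list(msk), 24, 2)
  expect_lt(max(abs(rc4$image - 1.3)), 1e-6)
  expect_error(build_ratio_correction(list(matrix(-1, H, W)), full, 24, 2),
               "positive|cell masks")
})

test_that("apply_ratio_correction divides once and propagates missingness", {
  r <- matrix(runif(100, 0.8, 1.4), 10, 10)
  r[3, 3] <- NA
  ones <- matrix(1, 10, 10)
  out <- apply_ratio_correction(r, ones)
  expect_equal(out[-33], r[-33])
  expect_true(is.na(out[3, 3]))
  expect_equal(attr(out, "ratio_correction_applied"), 1L)
  expect_equal(attr(apply_ratio_correction(out, ones), "ratio_correction_applied"), 2L)
  rr <- matrix(runif(100, 0.8, 1.4), 10, 10)
  expect_equal(unname(as.vector(apply_ratio_correction(rr, rr))), rep(1, 100))
  expect_error(apply_ratio_correction(r, matrix(0, 10, 10)), "positive")
  expect_error(apply_ratio_correction(r, matrix(1, 9, 10)), "shape")
})

test_that("correction flattens synthetic vignetting on the frames that built it", {
  p <- test_scene_params(image_height = 120L, image_width = 160L,
                         scratch_half_width = 20)
  flat <- generate_support_frames(p, "flat_calibration", n_frames = 3)
  cfg <- pipeline_config(pixel_scale = 1)
  dark <- generate_support_frames(p, "dark")
  empty <- generate_support_frames(p, "empty_well")
  bundle <- calibrate_corrections(dark, empty, flat, cfg)
  # reprocess a calibration frame and apply the correction: per-block medians
  # should sit within 2% of 1 (relative to the stack's global median)
  st <- fretscratch:::.analyze_frame_core(flat$donor[[1]], flat$acceptor[[1]],
                                          bundle$dark$donor, bundle$dark$acceptor,
                                          bundle$background$donor,
                                          bundle$background$acceptor,
                                          bundle$ratio_correction, cfg)
  corrected <- st$ratio_image$ratio
  corrected <- corrected / median(corrected, na.rm = TRUE)
  blocks <- split(seq_len(120), (seq_len(120) - 1) %/% 24)
  bmed <- vapply(blocks, function(rows) median(corrected[rows, ], na.rm = TRUE),
                 numeric(1))
  expect_lt(max(abs(bmed - 1)), 0.02)
})
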
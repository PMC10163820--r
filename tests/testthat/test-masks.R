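test_that("otsu_threshold equals the exhaustive-search oracle", {
  two_level <- c(rep(0, 50), rep(10, 50))
  expect_equal(otsu_threshold(two_level), oracle_otsu(two_level))
  expect_true(otsu_threshold(two_level) > 0 && otsu_threshold(two_level) <= 10)
  expect_equal(otsu_threshold(c(1, 1, 9, 9)), oracle_otsu(c(1, 1, 9, 9)))
  expect_error(otsu_threshold(rep(4, 10)), "constant")
  set.seed(23)
  for (k in 1:25) {
    v <- sample(0:255, 32 * 32, replace = TRUE)
    expect_identical(otsu_threshold(v), oracle_otsu(v))
  }
})

test_that("background_mask_from_image separates a two-level image exactly", {
  img <- matrix(10, 40, 40)
  img[, 21:40] <- 1000
  m <- background_mask_from_image(img)
  expect_identical(m, img < 500)
  # all-cell image: a mask is still returned (Otsu always splits)
  img2 <- matrix(900, 20, 20) + matrix(seq(0, 200, length.out = 400), 20, 20)
  expect_silent(m2 <- background_mask_from_image(img2))
  expect_true(is.logical(m2))
})

test_that("background mask recall on the synthetic scene is >= 0.95", {
  s <- get_test_scene()
  d0 <- s$donor_frames[[1]] - s$params$dark_offset
  a0 <- s$acceptor_frames[[1]] - s$params$dark_offset
  m <- background_mask_from_image(d0 + a0)
  truth_bg <- s$truth_scratch_mask[[1]] | s$truth_gap_mask
  expect_gte(sum(m & truth_bg) / sum(truth_bg), 0.95)
})

test_that("cell and background masks partition the frame", {
  s <- get_test_scene()
  res <- get_test_analysis()
  ms <- res$frames[[1]]$masks
  expect_true(all(xor(ms$cell, ms$background)))
  expect_gte(jaccard(ms$cell, s$truth_cell_mask[[1]]), 0.90)
})

test_that("background objects below 50 px are removed from the mask", {
  # a 40-px bright blob on dark background: blob is below min area, so the
  # background mask keeps covering it and the cell mask stays empty there
  img <- matrix(10, 60, 60)
  img[10:14, 10:17] <- 5000   # 5x8 = 40 px
  ms <- cell_scratch_masks(img, img)
  expect_false(any(ms$cell[10:14, 10:17]))
  # but a large blob survives
  img2 <- matrix(10, 60, 60)
  img2[10:29, 10:29] <- 5000  # 400 px
  ms2 <- cell_scratch_masks(img2, img2)
  expect_true(all(ms2$cell[12:27, 12:27]))
})

test_that("speckle filter finds injected puncta and ignores uniform images", {
  expect_warning(m0 <- speckle_mask(matrix(7, 40, 40), matrix(7, 40, 40)),
                 "count condition")
  expect_equal(sum(m0), 0)
  s <- get_test_scene()
  res <- get_test_analysis()
  spk <- res$frames[[1]]$masks$speckle
  ctr <- s$truth_speckle_centers[[1]]
  recall <- mean(spk[ctr])
  expect_gte(recall, 0.9)
  # no retained component is a membrane tracing: everything kept must be
  # compact and small
  lab <- label_components(spk, 8)
  if (max(lab) > 0) {
    for (k in seq_len(max(lab))) {
      expect_lte(sum(lab == k), 300)
      expect_lte(object_eccentricity(lab == k), 0.6)
    }
  }
})

test_that("elongated bright lines are rejected, compact squares kept", {
  set.seed(31)
  img <- matrix(rnorm(100 * 100, 500, 30), 100, 100)
  img[50, 20:59] <- 6000       # 1x40 line, eccentricity ~ 1
  img[20:24, 70:74] <- 6000    # 5x5 square
  m <- speckle_mask(img, img)
  expect_true(all(m[21:23, 71:73]))
  expect_false(any(m[50, 25:55]))
})

test_that("raising a punctum's brightness never removes it", {
  set.seed(37)
  base <- matrix(rnorm(80 * 80, 500, 30), 80, 80)
  base[40:42, 40:42] <- 4000
  detected <- vapply(c(1, 2, 5, 10), function(mult) {
    img <- base
    img[40:42, 40:42] <- 4000 * mult
    any(speckle_mask(img, img)[40:42, 40:42])
  }, logical(1))
  expect_true(detected[1])
  expect_true(all(diff(detected) >= 0))
})

test_that("object_eccentricity matches analytic shapes and is rotation-invariant", {
  # disc of radius 12
  g <- expand.grid(y = 1:31, x = 1:31)
  disc <- matrix((g$y - 16)^2 + (g$x - 16)^2 <= 144, 31, 31)
  expect_lte(object_eccentricity(disc), 0.1)
  # 1x20 line
  line <- matrix(FALSE, 5, 25)
  line[3, 3:22] <- TRUE
  expect_gte(object_eccentricity(line), 0.99)
  # ellipse with semi-axes a = 2b -> sqrt(3)/2
  ell <- matrix((g$y - 16)^2 / 6^2 + (g$x - 16)^2 / 12^2 <= 1, 31, 31)
  expect_equal(object_eccentricity(ell), sqrt(3) / 2, tolerance = 0.02)
  expect_equal(object_eccentricity(t(ell)), object_eccentricity(ell),
               tolerance = 1e-6)
  expect_error(object_eccentricity(matrix(FALSE, 3, 3)), "empty")
})
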
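test_that("scene_params validates its invariants", {
  expect_error(scene_params(edge_ratio = 0.9, baseline_ratio = 1.0),
               "edge_ratio")
  expect_error(scene_params(pixel_scale = 0), "pixel_scale")
  expect_error(scene_params(gradient_length = -1), "gradient_length")
  expect_error(scene_params(image_width = 0), "dimensions|scratch")
  # scratch wider than the image is rejected
  expect_error(scene_params(image_width = 100, pixel_scale = 1,
                            scratch_half_width = 60), "wider")
})

test_that("identical seeds give bitwise-identical scenes", {
  p <- test_scene_params(image_height = 64L, image_width = 120L,
                         scratch_half_width = 15)
  s1 <- generate_scene(p)
  s2 <- generate_scene(p)
  expect_identical(s1$donor_frames, s2$donor_frames)
  expect_identical(s1$acceptor_frames, s2$acceptor_frames)
  expect_identical(s1$truth_speckle_centers, s2$truth_speckle_centers)
  s3 <- generate_scene(test_scene_params(image_height = 64L, image_width = 120L,
                                         scratch_half_width = 15, seed = 12L))
  expect_false(identical(s1$donor_frames, s3$donor_frames))
})

test_that("noise-free unit-ratio scene has acceptor equal to donor on cells", {
  p <- test_scene_params(image_height = 48L, image_width = 96L,
                         scratch_half_width = 10, noise_sd = 0,
                         vignetting_amplitude = 0, n_speckles = 0L,
                         edge_ratio = 1.0, baseline_ratio = 1.0)
  s <- generate_scene(p)
  cell <- s$truth_cell_mask[[1]]
  expect_equal(s$acceptor_frames[[1]][cell], s$donor_frames[[1]][cell])
  # dark offset present everywhere
  expect_true(all(s$donor_frames[[1]] >= p$media_level))
})

test_that("true ratio field follows the exponential decay law", {
  p <- test_scene_params(image_height = 64L, image_width = 200L,
                         scratch_half_width = 20, noise_sd = 0,
                         n_speckles = 0L, gap_fraction = 0,
                         edge_waviness_px = 0)
  s <- generate_scene(p)
  tr <- s$truth_ratio_field[[1]]
  edge <- s$truth_edge_mask[[1]]
  # closed form: at d = gradient_length, ratio = 1 + 0.3 * exp(-1)
  d <- fretscratch:::geodesic_dist_cpp(matrix(TRUE, 64, 200), edge) * p$pixel_scale
  cell <- s$truth_cell_mask[[1]]
  at30 <- which(cell & abs(d - 30) < 1e-9)
  expect_gt(length(at30), 0)
  expect_equal(unique(round(tr[at30], 6)), round(1.0 + 0.3 * exp(-1), 6))
  # masks are disjoint and ratio defined exactly on cells
  expect_false(any(s$truth_cell_mask[[1]] & s$truth_scratch_mask[[1]]))
  expect_identical(!is.na(tr), cell)
})

test_that("mean acceptor/donor converges to truth times vignetting", {
  p <- test_scene_params(image_height = 40L, image_width = 80L,
                         scratch_half_width = 10, noise_sd = 5,
                         n_speckles = 0L, gap_fraction = 0)
  n_rep <- 120
  px <- c(10L, 60L)  # a cell pixel, left side
  vals_d <- vals_a <- numeric(n_rep)
  base <- generate_scene(p)
  stopifnot(base$truth_cell_mask[[1]][px[1], px[2]])
  for (r in seq_len(n_rep)) {
    pr <- test_scene_params(image_height = 40L, image_width = 80L,
                            scratch_half_width = 10, noise_sd = 5,
                            n_speckles = 0L, gap_fraction = 0,
                            seed = 1000L + r)
    s <- generate_scene(pr)
    vals_d[r] <- s$donor_frames[[1]][px[1], px[2]] - p$dark_offset
    vals_a[r] <- s$acceptor_frames[[1]][px[1], px[2]] - p$dark_offset
  }
  vig <- fretscratch:::.vignette_profile(40L, p$vignetting_amplitude)[px[1]]
  truth <- base$truth_ratio_field[[1]][px[1], px[2]] * vig
  est <- mean(vals_a) / mean(vals_d)
  sem <- sd(vals_a / vals_d) / sqrt(n_rep)
  expect_lt(abs(est - truth), 3 * sem + 1e-6)
})

test_that("scratch width closes at the stated speed", {
  p <- test_scene_params(image_height = 60L, image_width = 200L,
                         scratch_half_width = 30, closure_speed = 20,
                         frame_interval = 30, n_frames = 4L,
                         edge_waviness_px = 0, noise_sd = 0, n_speckles = 0L)
  s <- generate_scene(p)
  for (t in seq_len(4)) {
    hours <- (t - 1) * 30 / 60
    w_expect <- max(0, 2 * (30 - 20 * hours)) / p$pixel_scale
    width_px <- if (any(s$truth_scratch_mask[[t]]))
      diff(range(which(colSums(s$truth_scratch_mask[[t]]) > 0))) + 1 else 0
    expect_lt(abs(width_px - w_expect), 1.5)
  }
})

test_that("support frames honour their contracts", {
  p <- test_scene_params(image_height = 32L, image_width = 64L,
                         scratch_half_width = 8, noise_sd = 0,
                         vignetting_amplitude = 0, gap_fraction = 0)
  dark <- generate_support_frames(p, "dark")
  expect_true(all(vapply(dark$donor, function(f) all(f == p$dark_offset), logical(1))))
  empty <- generate_support_frames(p, "empty_well")
  expect_length(empty$donor, 8L)   # eight empty-well frames by default
  expect_length(empty$acceptor, 8L)
  expect_true(all(empty$donor[[1]] == p$media_level + p$dark_offset))
  flat <- generate_support_frames(p, "flat_calibration")
  r <- (flat$acceptor[[1]] - p$dark_offset) / (flat$donor[[1]] - p$dark_offset)
  expect_equal(max(abs(r - p$baseline_ratio)), 0, tolerance = 1e-9)
  expect_error(generate_support_frames(p, "bogus"))
})
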
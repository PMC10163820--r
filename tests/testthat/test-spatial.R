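test_that("scratch mask is the largest background component", {
  bg <- matrix(FALSE, 40, 40)
  bg[1:10, 1:10] <- TRUE           # 100 px
  bg[15:39, 15:34] <- TRUE         # 500 px
  m <- scratch_mask_from_background(bg)
  expect_true(all(m[15:39, 15:34]))
  expect_false(any(m[1:10, 1:10]))
  single <- matrix(FALSE, 10, 10); single[3:6, 3:6] <- TRUE
  expect_identical(scratch_mask_from_background(single), single)
  expect_error(scratch_mask_from_background(matrix(FALSE, 5, 5)), "empty")
})

test_that("scratch mask recovery on the synthetic scene", {
  s <- get_test_scene()
  res <- get_test_analysis()
  expect_gte(jaccard(res$frames[[1]]$masks$scratch, s$truth_scratch_mask[[1]]), 0.90)
})

test_that("edge masks of a perfect vertical band are two dilated strips", {
  sc <- matrix(FALSE, 50, 80)
  sc[, 26:55] <- TRUE
  e <- scratch_edge_masks(sc, dilate_px = 2)
  expect_false(any(e$left_edge & e$right_edge))
  # left edge: column 26 dilated by a radius-2 disc -> columns 24..28
  expect_true(all(e$left_edge[10:40, 26]))
  expect_true(any(e$left_edge[, 24]) && any(e$left_edge[, 28]))
  expect_false(any(e$left_edge[, 29:80]))
  expect_true(all(e$right_edge[10:40, 55]))
  # edges exclude the very top/bottom rows before dilation, so no edge pixel
  # originates there; after 2 px dilation rows 1..2 may be touched, interior only
  expect_false(any(e$left_edge[, 1:20]))
})

test_that("scratch touching a lateral border yields a single flagged edge", {
  sc <- matrix(FALSE, 30, 40)
  sc[, 1:10] <- TRUE
  expect_warning(e <- scratch_edge_masks(sc), "absent")
  expect_null(e$left_edge)
  expect_false(is.null(e$right_edge))
})

test_that("side split is symmetric for a centred band and tolerates empty sides", {
  cell <- matrix(TRUE, 40, 81)
  sc <- matrix(FALSE, 40, 81)
  sc[, 36:46] <- TRUE
  cell[sc] <- FALSE
  sp <- side_split_cell_mask(cell, sc)
  expect_equal(sum(sp$left_cells), sum(sp$right_cells))
  expect_false(any(sp$left_cells & sp$right_cells))
  # empty side
  cell2 <- cell; cell2[, 1:35] <- FALSE
  sp2 <- side_split_cell_mask(cell2, sc)
  expect_equal(sum(sp2$left_cells), 0)
  # synthetic scene: sides match truth for >= 99% of cell pixels
  s <- get_test_scene()
  res <- get_test_analysis()
  ms <- res$frames[[1]]$masks
  sp3 <- side_split_cell_mask(ms$cell, ms$scratch)
  W <- ncol(ms$cell)
  truth_side <- matrix(rep(seq_len(W), each = nrow(ms$cell)) > (W + 1) / 2,
                       nrow(ms$cell), W)
  agree <- (sp3$right_cells & truth_side) | (sp3$left_cells & !truth_side)
  expect_gte(sum(agree[ms$cell]) / sum(ms$cell), 0.99)
})

test_that("quasi-euclidean distance honours the metric and the Dijkstra oracle", {
  region <- matrix(TRUE, 9, 9)
  src <- matrix(FALSE, 9, 9); src[5, 5] <- TRUE
  d <- quasi_euclidean_distance(region, src, pixel_scale = 2)
  expect_equal(d[5, 5], 0)
  expect_equal(d[5, 6], 2)          # axial neighbour: pixel_scale
  expect_equal(d[4, 4], 2 * sqrt(2))  # diagonal neighbour
  expect_error(quasi_euclidean_distance(region, matrix(FALSE, 9, 9)), "source")
  set.seed(13)
  for (k in 1:10) {
    region <- matrix(runif(32 * 32) > 0.25, 32, 32)
    src <- matrix(FALSE, 32, 32)
    src[sample(which(region), 3)] <- TRUE
    got <- quasi_euclidean_distance(region, src, 1)
    want <- oracle_dijkstra(region, src)
    expect_lt(max(abs(got - want), na.rm = TRUE), 1e-9)
    expect_identical(is.na(got), is.na(want))
  }
})

test_that("binned profile conserves pixels and recovers uniform ratios", {
  set.seed(8)
  H <- 40; W <- 60
  dist <- matrix(rep(seq(0, 29.5, length.out = W), each = H), H, W)
  donor <- matrix(rnorm(H * W, 1000, 20), H, W)
  acceptor <- donor  # ratio exactly 1 pixelwise
  prof <- bin_fret_profile(dist, donor, acceptor, bin_width = 5)
  expect_equal(sum(prof$n_pixels), H * W)
  expect_true(all(abs(prof$mean_ratio - 1) < 1e-12))
  expect_equal(prof$bin_lo_um, seq(0, 25, by = 5))
  # fully masked bin stays missing, pixel count drops
  acceptor2 <- acceptor; donor2 <- donor
  donor2[dist >= 10 & dist < 15] <- NA
  prof2 <- bin_fret_profile(dist, donor2, acceptor2, bin_width = 5)
  expect_true(is.na(prof2$mean_ratio[prof2$bin_lo_um == 10]))
  expect_equal(prof2$n_pixels[prof2$bin_lo_um == 10], 0L)
  expect_equal(sum(prof2$n_pixels), sum(!is.na(donor2)))
  # bin intervals are half-open: distance 0 is binnable
  expect_gt(prof$n_pixels[1], 0)
})

test_that("bin-level correction is applied exactly once", {
  dist <- matrix(seq(0, 9, length.out = 100), 10, 10)
  donor <- matrix(1000, 10, 10)
  acceptor <- matrix(1200, 10, 10)
  corr <- matrix(1.2, 10, 10)
  prof <- bin_fret_profile(dist, donor, acceptor, correction = corr, bin_width = 5)
  expect_true(all(abs(prof$mean_ratio - 1.0) < 1e-12))
  attr(acceptor, "ratio_correction_applied") <- 1L
  expect_error(bin_fret_profile(dist, donor, acceptor, correction = corr),
               "twice")
})

test_that("group aggregation computes mean and sem across wells", {
  mk <- function(well, vals)
    data.frame(well = well, group = "g", bin_lo_um = seq(0, by = 5, length.out = length(vals)),
               bin_hi_um = seq(5, by = 5, length.out = length(vals)),
               mean_ratio = vals, n_pixels = 100)
  one <- aggregate_group_profile(mk("w1", c(1.2, 1.1)), "g")
  expect_equal(one$mean_ratio, c(1.2, 1.1))
  expect_true(all(is.na(one$sem)))
  two <- aggregate_group_profile(rbind(mk("w1", c(1.0, 1.0)), mk("w2", c(1.2, 1.4))), "g")
  expect_equal(two$mean_ratio, c(1.1, 1.2))
  expect_equal(two$sem, c(0.1, 0.2))
  bad <- rbind(mk("w1", c(1, 1)),
               transform(mk("w2", c(1, 1)), bin_hi_um = bin_lo_um + 7))
  expect_error(aggregate_group_profile(bad, "g"), "grid")
})

test_that("Welch comparison matches t.test and handles degeneracy", {
  set.seed(19)
  a <- rnorm(12, 1.2, 0.05); b <- rnorm(10, 1.15, 0.08)
  got <- compare_profiles_at_distance(a, b, distance = 5)
  ref <- t.test(a, b)
  expect_equal(got$statistic, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(got$df, unname(ref$parameter), tolerance = 1e-12)
  expect_equal(got$p_value, ref$p.value, tolerance = 1e-12)
  # identical groups -> t = 0, p = 1
  same <- compare_profiles_at_distance(a, a, 5)
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  # zero-variance groups: epsilon guard instead of failure
  expect_warning(z <- compare_profiles_at_distance(c(1, 1, 1), c(2, 2, 2), 5),
                 "variance")
  expect_lt(z$p_value, 1e-6)
  expect_error(compare_profiles_at_distance(c(1), c(1, 2), 5), "two wells")
})

test_that("Welch test has high power at the stated effect size", {
  # 200 simulated experiments: true bin-mean difference 0.1, well sd 0.05,
  # 24 wells per group -> essentially always detected at alpha = 0.05
  set.seed(29)
  rej <- vapply(1:200, function(r) {
    a <- rnorm(24, 1.3, 0.05)
    b <- rnorm(24, 1.2, 0.05)
    compare_profiles_at_distance(a, b, 5)$p_value < 0.05
  }, logical(1))
  expect_gte(mean(rej), 0.99)
})
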
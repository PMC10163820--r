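## Camera and illumination corrections: dark-state subtraction and the
## flat-field ("ratio correction") image that removes the top-to-bottom
## illumination gradient seen in FRET ratio images.

#' Estimate the dark-state camera image
#'
#' Per-pixel median over a stack of frames captured without illumination.
#'
#' @param dark_frames non-empty list of equally shaped matrices.
#' @return matrix of per-pixel dark counts.
#' @export
estimate_dark_image <- function(dark_frames) {
  if (!is.list(dark_frames) || length(dark_frames) < 1L)
    stop("dark_frames must be a non-empty list of frames")
  stack_median(dark_frames)
}

#' Subtract the dark-state image from a frame
#'
#' Values may go negative; downstream background subtraction and masking are
#' responsible for them, so no clipping is applied here.
#'
#' @param frame,dark matrices of identical shape.
#' @return matrix.
#' @export
subtract_dark <- function(frame, dark) {
  .check_image(frame, "frame"); .check_image(dark, "dark")
  .same_shape(frame, dark, "frame and dark image")
  frame - dark
}

#' Build the FRET ratio-correction (flat-field) image
#'
#' From ratio images of unstimulated confluent monolayers (processed by the
#' standard pipeline): (1) per-pixel median over the stack, using only pixels
#' inside the matching cell mask; (2) partition into `block_size` x
#' `block_size` blocks (partial blocks at the right/bottom edges use their own
#' median) and take each block's median, ignoring missing values; (3)
#' nearest-neighbour fill of blocks with no valid pixel; (4) Gaussian-smooth
#' the block-resolution image (`smooth_sigma`, in block units) with
#' ramp-preserving borders; (5) bilinear resize to the input shape.
#'
#' @param calibration_ratio_frames list of ratio matrices (NA = missing).
#' @param cell_masks list of logical matrices aligned to the frames, or a
#'   single mask recycled across frames.
#' @param block_size block edge, pixels (default 24).
#' @param smooth_sigma Gaussian sigma in block units (default 5).
#' @return a `ratio_correction` object: list with `image` (strictly positive
#'   matrix), `block_size`, `smooth_sigma`.
#' @export
build_ratio_correction <- function(calibration_ratio_frames, cell_masks,
                                   block_size = 24L, smooth_sigma = 5) {
  if (!is.list(calibration_ratio_frames) || length(calibration_ratio_frames) < 1L)
    stop("need at least one calibration ratio frame")
  if (is.matrix(cell_masks)) cell_masks <- list(cell_masks)
  if (length(cell_masks) == 1L)
    cell_masks <- rep(cell_masks, length(calibration_ratio_frames))
  if (length(cell_masks) != length(calibration_ratio_frames))
    stop("cell_masks must match calibration frames in length")
  masked <- mapply(function(f, m) {
    .same_shape(f, m, "frame and mask")
    f[!m] <- NA_real_
    f
  }, calibration_ratio_frames, cell_masks, SIMPLIFY = FALSE)
  med <- stack_median(masked)
  H <- nrow(med); W <- ncol(med)
  block_size <- as.integer(block_size)
  if (block_size < 1L) stop("block_size must be positive")
  rs <- seq(1L, H, by = block_size)
  cs <- seq(1L, W, by = block_size)
  nbr <- length(rs); nbc <- length(cs)
  grid <- matrix(NA_real_, nbr, nbc)
  row_centers <- col_centers <- numeric(0)
  for (bi in seq_len(nbr)) {
    ri <- rs[bi]:min(H, rs[bi] + block_size - 1L)
    for (bj in seq_len(nbc)) {
      ci <- cs[bj]:min(W, cs[bj] + block_size - 1L)
      v <- med[ri, ci]
      v <- v[is.finite(v)]
      if (length(v) > 0L) grid[bi, bj] <- stats::median(v)
    }
  }
  row_centers <- vapply(seq_len(nbr), function(bi)
    (rs[bi] + min(H, rs[bi] + block_size - 1L)) / 2, numeric(1))
  col_centers <- vapply(seq_len(nbc), function(bj)
    (cs[bj] + min(W, cs[bj] + block_size - 1L)) / 2, numeric(1))
  if (all(is.na(grid)))
    stop("no calibration pixel falls inside the cell masks")
  ## nearest-neighbour fill of empty blocks (grid distance between centres)
  if (anyNA(grid)) {
    valid <- which(!is.na(grid), arr.ind = TRUE)
    empty <- which(is.na(grid), arr.ind = TRUE)
    for (k in seq_len(nrow(empty))) {
      d2 <- (valid[, 1L] - empty[k, 1L])^2 + (valid[, 2L] - empty[k, 2L])^2
      grid[empty[k, 1L], empty[k, 2L]] <- grid[valid[which.min(d2), , drop = FALSE]]
    }
  }
  if (any(grid <= 0))
    stop("non-positive block medians in calibration ratios; check inputs")
  sm <- .gauss_smooth_ramp(grid, smooth_sigma)
  img <- .resize_from_grid(sm, row_centers, col_centers, H, W)
  if (any(img <= 0))
    stop("ratio-correction image is not strictly positive; check calibration data")
  structure(list(image = img, block_size = block_size, smooth_sigma = smooth_sigma),
            class = "ratio_correction")
}

#' Apply the ratio correction to a ratio image
#'
#' Per-pixel division; missing pixels stay missing.
#'
#' @param ratio matrix of FRET ratios (NA = missing).
#' @param correction a `ratio_correction` object or a strictly positive
#'   matrix of the same shape.
#' @return matrix.
#' @export
apply_ratio_correction <- function(ratio, correction) {
  img <- if (inherits(correction, "ratio_correction")) correction$image else correction
  .check_image(ratio, "ratio"); .check_image(img, "correction")
  .same_shape(ratio, img, "ratio and correction")
  if (any(!is.finite(img) | img <= 0))
    stop("correction image must be finite and strictly positive")
  out <- ratio / img
  n_prev <- attr(ratio, "ratio_correction_applied")
  attr(out, "ratio_correction_applied") <- (if (is.null(n_prev)) 0L else n_prev) + 1L
  out
}
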
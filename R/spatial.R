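## Scratch-edge geometry, geodesic distances through the cell mask, and
## distance-binned FRET profiles with group-level aggregation and testing.

#' Scratch mask from a background mask
#'
#' The scratch is the largest object in the background mask; all other
#' background objects are discarded.
#'
#' @param background_mask logical matrix.
#' @param connectivity 4 or 8.
#' @return logical matrix.
#' @export
scratch_mask_from_background <- function(background_mask, connectivity = 8L) {
  .check_image(background_mask, "background_mask")
  if (!any(background_mask)) stop("background mask is empty")
  lab <- label_components(background_mask, connectivity)
  areas <- tabulate(lab[lab > 0L])
  lab == which.max(areas)
}

#' Left/right scratch-edge masks
#'
#' Takes the perimeter of the scratch mask (mask pixels 4-adjacent to
#' non-mask pixels), removes perimeter pixels in the top and bottom image
#' rows (scratches run north-south, so those belong to the image border, not
#' to a wound edge), splits the remainder into connected components, and
#' dilates each by `dilate_px` (euclidean disc) so the edges overlap the
#' cell mask.
#'
#' @param scratch_mask logical matrix; the scratch must span the image top to
#'   bottom.
#' @param dilate_px dilation radius, pixels (default 2).
#' @param connectivity component connectivity.
#' @return list with logical `left_edge` and `right_edge` matrices (either
#'   may be NULL, with a warning, when the scratch touches a lateral image
#'   border).
#' @export
scratch_edge_masks <- function(scratch_mask, dilate_px = 2L, connectivity = 8L) {
  .check_image(scratch_mask, "scratch_mask")
  if (!any(scratch_mask)) stop("scratch mask is empty")
  H <- nrow(scratch_mask)
  perim <- scratch_mask & !(.shift_fill(scratch_mask, -1L, 0L, TRUE) &
                            .shift_fill(scratch_mask, 1L, 0L, TRUE) &
                            .shift_fill(scratch_mask, 0L, -1L, TRUE) &
                            .shift_fill(scratch_mask, 0L, 1L, TRUE))
  perim[c(1L, H), ] <- FALSE
  if (!any(perim))
    stop("scratch perimeter vanished after pruning the top and bottom rows")
  lab <- label_components(perim, connectivity)
  ncomp <- max(lab)
  if (ncomp > 2L)
    stop(sprintf("scratch perimeter splits into %d lateral components (expected 2); irregular scratch",
                 ncomp))
  sc_cols <- which(scratch_mask, arr.ind = TRUE)[, 2L]
  cx <- mean(range(sc_cols))
  left <- right <- NULL
  for (k in seq_len(ncomp)) {
    comp <- lab == k
    mean_col <- mean(which(comp, arr.ind = TRUE)[, 2L])
    if (mean_col <= cx) left <- comp else right <- comp
  }
  if (ncomp == 2L && (is.null(left) || is.null(right))) {
    ## both components on one side of the centroid: order by mean column
    m1 <- mean(which(lab == 1L, arr.ind = TRUE)[, 2L])
    m2 <- mean(which(lab == 2L, arr.ind = TRUE)[, 2L])
    left <- lab == which.min(c(m1, m2))
    right <- lab == which.max(c(m1, m2))
  }
  if (is.null(left)) warning("left scratch edge absent (scratch touches the image border)")
  if (is.null(right)) warning("right scratch edge absent (scratch touches the image border)")
  if (!is.null(left)) left <- .dilate_disc(left, dilate_px)
  if (!is.null(right)) right <- .dilate_disc(right, dilate_px)
  list(left_edge = left, right_edge = right)
}

#' Split the cell mask into left and right sides of the scratch
#'
#' Cell pixels west of the scratch's per-row span go left, east go right;
#' pixels inside the span (overlap from dilation or closing) are assigned to
#' the nearer side.
#'
#' @param cell_mask,scratch_mask logical matrices of equal shape.
#' @return list with logical `left_cells` and `right_cells`.
#' @export
side_split_cell_mask <- function(cell_mask, scratch_mask) {
  .same_shape(cell_mask, scratch_mask, "masks")
  H <- nrow(cell_mask); W <- ncol(cell_mask)
  colm <- matrix(seq_len(W), H, W, byrow = TRUE)
  sc <- scratch_mask
  lo <- apply(sc, 1L, function(r) if (any(r)) min(which(r)) else NA_integer_)
  hi <- apply(sc, 1L, function(r) if (any(r)) max(which(r)) else NA_integer_)
  ## rows without scratch take the global median span (closed-scratch rows)
  if (all(is.na(lo))) {
    lo[] <- hi[] <- stats::median(colm[sc])
  }
  lo_f <- ifelse(is.na(lo), round(stats::median(lo, na.rm = TRUE)), lo)
  hi_f <- ifelse(is.na(hi), round(stats::median(hi, na.rm = TRUE)), hi)
  lo_m <- matrix(lo_f, H, W)
  hi_m <- matrix(hi_f, H, W)
  left <- cell_mask & colm < lo_m
  right <- cell_mask & colm > hi_m
  inside <- cell_mask & !left & !right
  if (any(inside)) {
    nearer_left <- (colm - lo_m) <= (hi_m - colm)
    left <- left | (inside & nearer_left)
    right <- right | (inside & !nearer_left)
  }
  list(left_cells = left, right_cells = right)
}

#' Quasi-euclidean geodesic distance within a mask
#'
#' Shortest-path distance constrained to `region`, axial steps costing 1 and
#' diagonal steps sqrt(2) pixel, scaled to micrometres. Unreachable or
#' out-of-region pixels are NA.
#'
#' @param region logical matrix (e.g. one side's cell mask).
#' @param sources logical matrix of source pixels (the dilated scratch edge);
#'   at least one source must fall inside the region.
#' @param pixel_scale micrometres per pixel.
#' @return numeric matrix of distances in um.
#' @export
quasi_euclidean_distance <- function(region, sources, pixel_scale = 1) {
  .same_shape(region, sources, "region and sources")
  if (pixel_scale <= 0) stop("pixel_scale must be positive")
  if (!any(region & sources)) stop("no source pixel lies inside the region")
  geodesic_dist_cpp(region, sources) * pixel_scale
}

#' Bin donor/acceptor/ratio statistics by distance from the scratch edge
#'
#' Pixels with a finite distance and non-missing channel values are sorted
#' into half-open bins `[k*bin_width, (k+1)*bin_width)` um. Per bin the mean
#' donor and mean acceptor are computed and the bin ratio is the ratio of
#' those means (mean acceptor / mean donor). When `correction` is supplied it
#' is folded into the acceptor exactly once before binning; passing channels
#' that were already corrected is an error.
#'
#' @param distance distance field in um (NA = not binnable).
#' @param donor,acceptor corrected, masked, smoothed channel frames (NA =
#'   missing).
#' @param correction optional `ratio_correction` or matrix.
#' @param bin_width bin width in um (default 5).
#' @param side,time_min,well,group metadata copied into the output.
#' @return data.frame with columns `well`, `group`, `side`, `time_min`,
#'   `bin_lo_um`, `bin_hi_um`, `n_pixels`, `mean_donor`, `mean_acceptor`,
#'   `mean_ratio`; empty bins inside the covered range carry NA means.
#' @export
bin_fret_profile <- function(distance, donor, acceptor, correction = NULL,
                             bin_width = 5, side = NA_character_,
                             time_min = NA_real_, well = NA_character_,
                             group = NA_character_) {
  .same_shape(distance, donor, "distance and donor")
  .same_shape(distance, acceptor, "distance and acceptor")
  if (bin_width <= 0) stop("bin_width must be positive")
  if (!is.null(correction)) {
    prev <- attr(acceptor, "ratio_correction_applied")
    if (!is.null(prev) && prev > 0L)
      stop("ratio correction would be applied twice; pass uncorrected channels or correction = NULL")
    img <- if (inherits(correction, "ratio_correction")) correction$image else correction
    .same_shape(acceptor, img, "acceptor and correction")
    acceptor <- acceptor / img
  }
  ok <- is.finite(distance) & !is.na(donor) & !is.na(acceptor)
  empty <- data.frame(well = character(0), group = character(0),
                      side = character(0), time_min = numeric(0),
                      bin_lo_um = numeric(0), bin_hi_um = numeric(0),
                      n_pixels = integer(0), mean_donor = numeric(0),
                      mean_acceptor = numeric(0), mean_ratio = numeric(0),
                      stringsAsFactors = FALSE)
  if (!any(ok)) return(empty)
  d <- distance[ok]
  bin <- floor(d / bin_width)
  bins <- seq(0L, max(bin))
  f <- factor(bin, levels = bins)
  n <- as.integer(table(f))
  sum_d <- tapply(donor[ok], f, sum)
  sum_a <- tapply(acceptor[ok], f, sum)
  mean_d <- ifelse(n > 0L, sum_d / n, NA_real_)
  mean_a <- ifelse(n > 0L, sum_a / n, NA_real_)
  data.frame(well = well, group = group, side = side, time_min = time_min,
             bin_lo_um = bins * bin_width, bin_hi_um = (bins + 1) * bin_width,
             n_pixels = n,
             mean_donor = as.numeric(mean_d),
             mean_acceptor = as.numeric(mean_a),
             mean_ratio = as.numeric(mean_a) / as.numeric(mean_d),
             stringsAsFactors = FALSE)
}

#' Pool a well's binned profiles into per-bin well-level means
#'
#' Sides are pooled within each frame by pixel-weighted donor/acceptor sums
#' (the bin ratio stays a ratio of means); frames are then averaged, so the
#' well -- not the frame -- is the replication unit.
#'
#' @param profiles data.frame from [bin_fret_profile()] rows (one or more
#'   sides/frames of one or more wells).
#' @param times optional subset of `time_min` values to include.
#' @return data.frame with columns `well`, `group`, `bin_lo_um`, `bin_hi_um`,
#'   `mean_ratio`, `n_pixels`.
#' @export
well_bin_means <- function(profiles, times = NULL) {
  stopifnot(is.data.frame(profiles))
  if (!is.null(times)) profiles <- profiles[profiles$time_min %in% times, , drop = FALSE]
  if (nrow(profiles) == 0L) stop("no profile rows selected")
  ## pool sides within (well, time, bin)
  key <- interaction(profiles$well, profiles$time_min, profiles$bin_lo_um, drop = TRUE)
  pooled <- do.call(rbind, lapply(split(profiles, key), function(g) {
    n <- sum(g$n_pixels)
    data.frame(well = g$well[1L], group = g$group[1L], time_min = g$time_min[1L],
               bin_lo_um = g$bin_lo_um[1L], bin_hi_um = g$bin_hi_um[1L],
               n_pixels = n,
               mean_ratio = if (n > 0L)
                 sum(g$mean_acceptor * g$n_pixels, na.rm = TRUE) /
                 sum(g$mean_donor * g$n_pixels, na.rm = TRUE)
               else NA_real_,
               stringsAsFactors = FALSE)
  }))
  ## average frames within (well, bin)
  key2 <- interaction(pooled$well, pooled$bin_lo_um, drop = TRUE)
  out <- do.call(rbind, lapply(split(pooled, key2), function(g) {
    data.frame(well = g$well[1L], group = g$group[1L],
               bin_lo_um = g$bin_lo_um[1L], bin_hi_um = g$bin_hi_um[1L],
               mean_ratio = mean(g$mean_ratio, na.rm = TRUE),
               n_pixels = sum(g$n_pixels),
               stringsAsFactors = FALSE)
  }))
  out <- out[order(out$well, out$bin_lo_um), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Aggregate well-level profiles into a group profile
#'
#' Per bin: mean and standard error of the well-level mean ratios across
#' wells (wells are the replication unit; sem needs at least two wells).
#'
#' @param profiles data.frame of well-level bin means ([well_bin_means()]
#'   output, or raw [bin_fret_profile()] rows which are pooled first).
#' @param group_label label stored in the output.
#' @return data.frame with columns `group`, `bin_lo_um`, `bin_hi_um`,
#'   `mean_ratio`, `sem`, `n_wells`.
#' @export
aggregate_group_profile <- function(profiles, group_label = NA_character_) {
  stopifnot(is.data.frame(profiles))
  if (!"mean_ratio" %in% names(profiles)) stop("profiles lack a mean_ratio column")
  if (!"bin_lo_um" %in% names(profiles)) stop("profiles lack bin columns")
  wb <- if ("n_pixels" %in% names(profiles) && "side" %in% names(profiles))
    well_bin_means(profiles) else profiles
  widths <- unique(round(wb$bin_hi_um - wb$bin_lo_um, 9))
  if (length(widths) != 1L) stop("mismatched bin grids across wells")
  out <- do.call(rbind, lapply(split(wb, wb$bin_lo_um), function(g) {
    v <- g$mean_ratio[is.finite(g$mean_ratio)]
    nw <- length(v)
    data.frame(group = group_label,
               bin_lo_um = g$bin_lo_um[1L], bin_hi_um = g$bin_hi_um[1L],
               mean_ratio = if (nw > 0L) mean(v) else NA_real_,
               sem = if (nw >= 2L) stats::sd(v) / sqrt(nw) else NA_real_,
               n_wells = nw, stringsAsFactors = FALSE)
  }))
  out <- out[order(out$bin_lo_um), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Welch two-sample t test of well-level bin means at a distance
#'
#' Two-sided unpaired t test with Welch's correction on the well-level mean
#' ratios in the bin containing `distance`. When a group has zero variance a
#' machine-epsilon variance guard is applied (with a warning) instead of
#' failing.
#'
#' @param groupA,groupB data.frames of well-level bin means
#'   ([well_bin_means()] output) or numeric vectors of well values for the
#'   target bin.
#' @param distance distance from the scratch edge, um.
#' @param bin_width bin width used when extracting from data.frames.
#' @return list with `statistic`, `df`, `p_value`, `mean_diff`, `n` (c(nA,
#'   nB)), `bin_lo_um`.
#' @export
compare_profiles_at_distance <- function(groupA, groupB, distance,
                                         bin_width = 5) {
  pick <- function(g) {
    if (is.numeric(g)) return(as.numeric(g))
    lo <- floor(distance / bin_width) * bin_width
    v <- g$mean_ratio[g$bin_lo_um == lo]
    v[is.finite(v)]
  }
  a <- pick(groupA); b <- pick(groupB)
  if (length(a) < 2L || length(b) < 2L)
    stop("need at least two wells per group in the requested bin")
  va <- stats::var(a); vb <- stats::var(b)
  if (va == 0 || vb == 0) {
    if (va == 0 && vb == 0 && mean(a) == mean(b))
      return(list(statistic = 0, df = length(a) + length(b) - 2,
                  p_value = 1, mean_diff = 0,
                  n = c(length(a), length(b)),
                  bin_lo_um = floor(distance / bin_width) * bin_width))
    warning("zero within-group variance; applying epsilon-variance guard")
    eps <- .Machine$double.eps * max(1, abs(mean(a)), abs(mean(b)))^2
    va <- max(va, eps); vb <- max(vb, eps)
  }
  na <- length(a); nb <- length(b)
  se2 <- va / na + vb / nb
  t <- (mean(a) - mean(b)) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  p <- 2 * stats::pt(-abs(t), df)
  list(statistic = t, df = df, p_value = p, mean_diff = mean(a) - mean(b),
       n = c(na, nb), bin_lo_um = floor(distance / bin_width) * bin_width)
}
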
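## Segmentation of background / cells / scratch and bright-speckle rejection.
## Every printed constant of the segmentation recipe lives in
## segmentation_params() so the provenance of each default is auditable.

#' Segmentation parameters
#'
#' Defaults follow the published recipe for MCF7 monolayers: subtract the
#' dimmest 0.5% of the sum image, floor intensities at 20 counts before the
#' log transform, rescale log intensities to the 1st-90th percentile range,
#' remove background-mask objects below 50 px, sharpen with an alpha = 0.9
#' Laplacian for speckle detection, threshold at the first histogram bin with
#' 9 or fewer pixels, drop speckle components above 300 px or with
#' eccentricity above 0.6.
#'
#' @param dim_fraction fraction of dimmest pixels whose level is subtracted.
#' @param intensity_floor minimum count before the log transform.
#' @param rescale_lo,rescale_hi percentiles bounding the log-image rescale.
#' @param min_object_area smallest background-mask object kept, px.
#' @param speckle_alpha alpha of the 3x3 Laplacian kernel family.
#' @param speckle_bin_count_threshold occupancy at or below which a histogram
#'   bin marks the bright-tail threshold.
#' @param speckle_n_bins number of uniform histogram bins over the positive
#'   sharpened values (the published recipe does not state it; config knob).
#' @param speckle_max_area largest speckle component kept, px.
#' @param eccentricity_cutoff components more elongated than this are treated
#'   as membrane tracings and dropped.
#' @param connectivity connected-component connectivity (4 or 8).
#' @return object of class `segmentation_params`.
#' @export
segmentation_params <- function(dim_fraction = 0.005, intensity_floor = 20,
                                rescale_lo = 1, rescale_hi = 90,
                                min_object_area = 50L,
                                speckle_alpha = 0.9,
                                speckle_bin_count_threshold = 9L,
                                speckle_n_bins = 256L,
                                speckle_max_area = 300L,
                                eccentricity_cutoff = 0.6,
                                connectivity = 8L) {
  if (rescale_lo >= rescale_hi) stop("rescale percentiles must be ordered")
  if (dim_fraction < 0 || dim_fraction >= 1) stop("dim_fraction must be in [0, 1)")
  if (intensity_floor <= 0 || min_object_area <= 0 || speckle_max_area <= 0)
    stop("thresholds must be positive")
  structure(list(dim_fraction = dim_fraction, intensity_floor = intensity_floor,
                 rescale_lo = rescale_lo, rescale_hi = rescale_hi,
                 min_object_area = as.integer(min_object_area),
                 speckle_alpha = speckle_alpha,
                 speckle_bin_count_threshold = as.integer(speckle_bin_count_threshold),
                 speckle_n_bins = as.integer(speckle_n_bins),
                 speckle_max_area = as.integer(speckle_max_area),
                 eccentricity_cutoff = eccentricity_cutoff,
                 connectivity = as.integer(connectivity)),
            class = "segmentation_params")
}

#' Otsu's threshold
#'
#' Exact Otsu threshold over the empirical value distribution: the returned
#' threshold `t` maximises the between-class variance of the split
#' `x < t` vs `x >= t`; ties are broken toward the lowest such threshold.
#'
#' @param values numeric vector or matrix with at least two distinct finite
#'   values.
#' @return scalar threshold.
#' @export
otsu_threshold <- function(values) {
  v <- as.numeric(values)
  v <- v[is.finite(v)]
  u <- sort(unique(v))
  if (length(u) < 2L)
    stop("Otsu threshold undefined for constant input")
  cnt <- tabulate(match(v, u))
  n <- length(v)
  csum <- cumsum(cnt)
  cval <- cumsum(cnt * u)
  k <- length(u)
  w0 <- csum[-k] / n
  mu0 <- cval[-k] / csum[-k]
  w1 <- 1 - w0
  mu1 <- (cval[k] - cval[-k]) / (n - csum[-k])
  bcv <- w0 * w1 * (mu0 - mu1)^2
  u[which.max(bcv) + 1L]
}

#' Background mask from a single dark-corrected frame
#'
#' Log-transforms the frame (values clipped to >= 1 first, so dim cell pixels
#' gain contrast), takes the Otsu threshold of the log image, and returns the
#' pixels strictly below it.
#'
#' @param frame dark-corrected matrix.
#' @return logical matrix (TRUE = background).
#' @export
background_mask_from_image <- function(frame) {
  .check_image(frame, "frame")
  l <- log(pmax(frame, 1))
  l < otsu_threshold(l)
}

#' Cell / background / scratch segmentation of an aligned channel pair
#'
#' Sum the two channels (better SNR), subtract the level of the dimmest 0.5%
#' of pixels, floor at `intensity_floor`, log-transform, rescale to the
#' [1st, 90th] percentile window, Otsu-threshold; pixels below the threshold
#' form the background mask, which is morphologically closed, cleared of
#' objects below `min_object_area`, and hole-filled. The cell mask is its
#' inverse; the scratch mask is the background mask's largest connected
#' component (see [scratch_mask_from_background()]).
#'
#' @param donor,acceptor aligned, background-subtracted channel frames.
#' @param params a [segmentation_params()] object.
#' @return a `mask_set`: list with logical `cell`, `background`, `scratch`
#'   matrices and the `connectivity` used.
#' @export
cell_scratch_masks <- function(donor, acceptor, params = segmentation_params()) {
  .check_image(donor, "donor"); .check_image(acceptor, "acceptor")
  .same_shape(donor, acceptor, "channel frames")
  if (nrow(donor) < 3L || ncol(donor) < 3L)
    stop("image smaller than the structuring element")
  s <- donor + acceptor
  dim_level <- stats::quantile(s, params$dim_fraction, names = FALSE)
  s <- s - dim_level
  s <- pmax(s, params$intensity_floor)
  l <- log(s)
  q <- stats::quantile(l, c(params$rescale_lo, params$rescale_hi) / 100, names = FALSE)
  resc <- (l - q[1L]) / max(q[2L] - q[1L], .Machine$double.eps)
  resc <- pmin(pmax(resc, 0), 1)
  th <- otsu_threshold(resc)
  bg <- resc < th
  bg <- binary_closing(bg)
  bg <- remove_small_objects(bg, params$min_object_area, params$connectivity)
  bg <- fill_holes(bg, max_area = params$min_object_area)
  cell <- !bg
  scratch <- if (any(bg)) scratch_mask_from_background(bg, params$connectivity)
             else matrix(FALSE, nrow(bg), ncol(bg))
  structure(list(cell = cell, background = bg, scratch = scratch,
                 speckle = NULL, connectivity = params$connectivity),
            class = "mask_set")
}

#' Bright-speckle mask
#'
#' Sharpen the sum image by subtracting its alpha-Laplacian, histogram the
#' positive sharpened values into `speckle_n_bins` uniform bins, and take as
#' threshold the left edge of the first bin occupied by
#' `speckle_bin_count_threshold` or fewer pixels. The binary mask of sum-image
#' pixels above that threshold is morphologically closed; components larger
#' than `speckle_max_area` px or with eccentricity above
#' `eccentricity_cutoff` (membrane tracings are linear, puncta are round) are
#' dropped.
#'
#' Note the threshold is *derived* on the sharpened image but *applied* to
#' the sum image: sharpening amplifies compact bright objects, so the
#' threshold clears every membrane-rim pixel in sum-image units while true
#' puncta remain far above it.
#'
#' @param donor,acceptor aligned channel frames.
#' @param params a [segmentation_params()] object.
#' @return logical matrix (TRUE = speckle).
#' @export
speckle_mask <- function(donor, acceptor, params = segmentation_params()) {
  .check_image(donor, "donor"); .check_image(acceptor, "acceptor")
  .same_shape(donor, acceptor, "channel frames")
  s <- donor + acceptor
  lap <- .conv3x3(s, laplacian_kernel(params$speckle_alpha))
  sharp <- s - lap
  pos <- sharp[sharp > 0]
  empty <- matrix(FALSE, nrow(s), ncol(s))
  if (length(pos) < 2L) {
    warning("no positive sharpened pixels; empty speckle mask")
    return(empty)
  }
  breaks <- seq(0, max(pos), length.out = params$speckle_n_bins + 1L)
  counts <- tabulate(findInterval(pos, breaks, rightmost.closed = TRUE,
                                  all.inside = TRUE),
                     nbins = params$speckle_n_bins)
  ## scan upward from the histogram mode: the first sparsely occupied bin
  ## past the bulk marks where the bright tail begins
  start <- which.max(counts)
  idx <- which(counts <= params$speckle_bin_count_threshold)
  idx <- idx[idx >= start]
  if (length(idx) == 0L) {
    warning("no histogram bin satisfies the speckle count condition; empty speckle mask")
    return(empty)
  }
  threshold <- breaks[min(idx)]
  mask <- s > threshold
  mask <- binary_closing(mask)
  lab <- label_components(mask, params$connectivity)
  if (max(lab) == 0L) return(empty)
  keep <- logical(max(lab))
  areas <- tabulate(lab[lab > 0L])
  for (k in seq_len(max(lab))) {
    if (areas[k] > params$speckle_max_area) next
    ecc <- object_eccentricity(lab == k)
    keep[k] <- ecc <= params$eccentricity_cutoff
  }
  matrix(lab > 0L & keep[pmax(lab, 1L)], nrow(s), ncol(s))
}

#' Eccentricity of a connected component
#'
#' Eccentricity of the ellipse with the same normalised second central
#' moments as the component (0 = circle, approaching 1 = line). The 1/12
#' per-pixel moment correction treats each pixel as a unit square, matching
#' the convention of standard region-properties tools.
#'
#' @param component logical matrix containing a single non-empty component.
#' @return scalar in [0, 1).
#' @export
object_eccentricity <- function(component) {
  idx <- which(component, arr.ind = TRUE)
  if (nrow(idx) == 0L) stop("empty component")
  y <- idx[, 1L]; x <- idx[, 2L]
  mu20 <- mean((x - mean(x))^2) + 1 / 12
  mu02 <- mean((y - mean(y))^2) + 1 / 12
  mu11 <- mean((x - mean(x)) * (y - mean(y)))
  common <- sqrt((mu20 - mu02)^2 + 4 * mu11^2)
  l1 <- (mu20 + mu02 + common) / 2
  l2 <- (mu20 + mu02 - common) / 2
  sqrt(max(0, 1 - l2 / l1))
}
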
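## Construction of corrected, masked, smoothed FRET ratio images.

#' Compute a masked, smoothed, corrected FRET ratio image
#'
#' Background-mask and speckle-mask pixels are set to missing in both
#' channels; each channel is then Gaussian-smoothed with missing-value-aware
#' normalised convolution (a plain Gaussian would erase a halo around every
#' mask); the ratio is acceptor/donor (higher ratio = higher GTPase activity
#' for these sensors); finally the ratio is divided by the flat-field
#' correction. Pixels where the smoothed donor is non-positive become
#' missing. Missing pixels never become non-missing.
#'
#' @param donor,acceptor aligned, dark- and background-corrected channel
#'   frames.
#' @param masks a `mask_set` from [cell_scratch_masks()]; its `background`
#'   mask plus `speckle` (or the `speckle` argument) define the missing set.
#' @param correction optional `ratio_correction` (or matrix); applied exactly
#'   once, here.
#' @param smooth_sigma Gaussian sigma in pixels (default 2); 0 disables
#'   smoothing.
#' @param speckle optional logical matrix overriding `masks$speckle`.
#' @return list of class `ratio_image` with `ratio` (NA = missing; carries
#'   attribute `ratio_correction_applied`), `donor_smooth`,
#'   `acceptor_smooth` (masked smoothed channels, uncorrected), and
#'   `missing`.
#' @export
compute_ratio_image <- function(donor, acceptor, masks, correction = NULL,
                                smooth_sigma = 2, speckle = NULL) {
  .check_image(donor, "donor"); .check_image(acceptor, "acceptor")
  .same_shape(donor, acceptor, "channel frames")
  if (is.null(speckle)) speckle <- masks$speckle
  excl <- masks$background
  if (!is.null(speckle)) {
    .same_shape(excl, speckle, "masks")
    excl <- excl | speckle
  }
  .same_shape(donor, excl, "frame and masks")
  if (all(excl)) stop("all pixels are masked; nothing to ratio")
  d <- donor; a <- acceptor
  d[excl] <- NA_real_
  a[excl] <- NA_real_
  ds <- gauss_smooth(d, smooth_sigma)
  as <- gauss_smooth(a, smooth_sigma)
  ratio <- as / ds
  ratio[!is.na(ds) & ds <= 0] <- NA_real_
  ratio[!is.finite(ratio) | ratio <= 0] <- NA_real_
  if (!is.null(correction)) ratio <- apply_ratio_correction(ratio, correction)
  else attr(ratio, "ratio_correction_applied") <- 0L
  structure(list(ratio = ratio, donor_smooth = ds, acceptor_smooth = as,
                 missing = is.na(ratio)),
            class = "ratio_image")
}
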
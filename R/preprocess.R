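## Channel registration and scaled empty-well background subtraction.

#' Align the acceptor channel onto the donor channel
#'
#' Rigid integer translation estimated by phase correlation; the acceptor is
#' translated onto the donor and both frames are cropped to the common
#' overlap so shapes remain equal. Subpixel refinement is deliberately not
#' performed.
#'
#' @param donor,acceptor matrices covering the same nominal field of view.
#' @param max_shift largest plausible misregistration, pixels; a larger
#'   estimate aborts (dual-camera systems are mechanically stable, so a large
#'   apparent shift signals misconfiguration rather than drift).
#' @return list with `donor`, `acceptor` (equal shape, registered),
#'   `shift_applied` = c(dy, dx) applied to the acceptor, and `crop` (the
#'   row/col window kept on the donor side).
#' @export
align_channel_pair <- function(donor, acceptor, max_shift = 10L) {
  .check_image(donor, "donor"); .check_image(acceptor, "acceptor")
  .same_shape(donor, acceptor, "channel frames")
  H <- nrow(donor); W <- ncol(donor)
  ## Hann window suppresses the non-circular frame edges; the regularised
  ## whitening keeps noise-dominated high frequencies from drowning the peak.
  hann <- function(n) if (n < 2L) rep(1, n) else 0.5 * (1 - cos(2 * pi * (0:(n - 1)) / (n - 1)))
  w <- hann(H) %o% hann(W)
  f1 <- stats::fft((donor - mean(donor)) * w)
  f2 <- stats::fft((acceptor - mean(acceptor)) * w)
  cp <- f1 * Conj(f2)
  m <- Mod(cp)
  cp <- cp / (m + 0.01 * mean(m))
  r <- Re(stats::fft(cp, inverse = TRUE))
  peak <- which.max(r)
  pi_ <- (peak - 1L) %% H
  pj_ <- (peak - 1L) %/% H
  dy <- if (pi_ > H / 2) pi_ - H else pi_
  dx <- if (pj_ > W / 2) pj_ - W else pj_
  ## peak at (dy, dx) means acceptor[i, j] ~ donor[i + dy, j + dx]; the
  ## aligned acceptor is acceptor[i - dy, j - dx].
  if (abs(dy) > max_shift || abs(dx) > max_shift)
    stop(sprintf("estimated shift (%d, %d) exceeds max_shift = %d; check camera configuration",
                 dy, dx, max_shift))
  rows_d <- max(1L, 1L + dy):min(H, H + dy)
  cols_d <- max(1L, 1L + dx):min(W, W + dx)
  list(donor = donor[rows_d, cols_d, drop = FALSE],
       acceptor = acceptor[rows_d - dy, cols_d - dx, drop = FALSE],
       shift_applied = c(dy = dy, dx = dx),
       crop = list(rows = range(rows_d), cols = range(cols_d)))
}

#' Estimate the empty-well background image
#'
#' Per-pixel median over a stack of dark-corrected empty-well frames (media
#' only), previously aligned and cropped like the experimental data.
#'
#' @param empty_frames non-empty list of matrices (one channel).
#' @return matrix.
#' @export
estimate_well_background <- function(empty_frames) {
  if (!is.list(empty_frames) || length(empty_frames) < 1L)
    stop("empty_frames must be a non-empty list of frames")
  stack_median(empty_frames)
}

#' Scaled empty-well background subtraction
#'
#' The empty-well image is scaled so its median over the experimental
#' frame's background pixels matches the frame's own background median, then
#' subtracted. Negative pixels are retained (masking handles them), keeping
#' ratio statistics unbiased.
#'
#' @param frame dark-corrected experimental frame.
#' @param background empty-well background image (same channel).
#' @param background_mask logical matrix of background pixels in `frame`,
#'   typically from [background_mask_from_image()].
#' @return matrix; the scale factor is attached as attribute `"scale"`.
#' @export
scale_subtract_background <- function(frame, background, background_mask) {
  .check_image(frame, "frame"); .check_image(background, "background")
  .same_shape(frame, background, "frame and background")
  .same_shape(frame, background_mask, "frame and background mask")
  if (!any(background_mask)) stop("background mask is empty")
  m_f <- stats::median(frame[background_mask])
  m_b <- stats::median(background[background_mask])
  if (!is.finite(m_b) || m_b == 0) stop("background median is zero; cannot scale")
  s <- m_f / m_b
  out <- frame - s * background
  attr(out, "scale") <- s
  out
}
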
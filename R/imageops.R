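## Low-level raster primitives shared across the pipeline. Images are plain
## numeric matrices (row 1 = top of the field of view); masks are logical
## matrices of the same shape. Missing pixels are IEEE NA/NaN.

.check_image <- function(x, name = "image") {
  if (!is.matrix(x)) stop(name, " must be a matrix", call. = FALSE)
  if (nrow(x) < 1L || ncol(x) < 1L) stop(name, " has non-positive dimensions", call. = FALSE)
  invisible(x)
}

.same_shape <- function(a, b, what = "images") {
  if (!identical(dim(a), dim(b)))
    stop(what, " differ in shape: ", paste(dim(a), collapse = "x"), " vs ",
         paste(dim(b), collapse = "x"), call. = FALSE)
  invisible(NULL)
}

## Shift a matrix by (dy, dx) with replicate padding: out[i, j] = x[i + dy, j + dx],
## indices clamped to the image.
.shift_replicate <- function(x, dy, dx) {
  H <- nrow(x); W <- ncol(x)
  ri <- pmin(pmax(seq_len(H) + dy, 1L), H)
  ci <- pmin(pmax(seq_len(W) + dx, 1L), W)
  x[ri, ci, drop = FALSE]
}

## Shift with a constant fill value instead of replication.
.shift_fill <- function(x, dy, dx, fill) {
  H <- nrow(x); W <- ncol(x)
  out <- matrix(fill, H, W)
  sr <- max(1L, 1L - dy):min(H, H - dy)
  sc <- max(1L, 1L - dx):min(W, W - dx)
  if (length(sr) > 0L && length(sc) > 0L)
    out[sr, sc] <- x[sr + dy, sc + dx, drop = FALSE]
  out
}

## 3x3 correlation with replicate padding; k indexed k[dy + 2, dx + 2].
.conv3x3 <- function(x, k) {
  out <- matrix(0, nrow(x), ncol(x))
  for (dy in -1:1)
    for (dx in -1:1)
      out <- out + k[dy + 2L, dx + 2L] * .shift_replicate(x, dy, dx)
  out
}

## Alpha-parameterised 3x3 discrete Laplacian (alpha in [0, 1] blends the
## diagonal terms into the stencil; alpha = 0 is the 4-neighbour Laplacian).
laplacian_kernel <- function(alpha = 0.9) {
  if (alpha < 0 || alpha > 1) stop("alpha must lie in [0, 1]")
  (4 / (alpha + 1)) * matrix(c(alpha / 4, (1 - alpha) / 4, alpha / 4,
                               (1 - alpha) / 4, -1, (1 - alpha) / 4,
                               alpha / 4, (1 - alpha) / 4, alpha / 4),
                             3, 3, byrow = TRUE)
}

## Banded one-dimensional Gaussian smoothing operator (n x n). Rows hold the
## truncated kernel; no renormalisation here (callers divide by the smoothed
## weight image, which handles both borders and missing pixels).
.smooth_operator <- function(n, sigma, radius = NULL) {
  r <- if (is.null(radius)) max(1L, as.integer(ceiling(4 * sigma)))
       else max(1L, as.integer(radius))
  k <- stats::dnorm(-r:r, sd = sigma)
  k <- k / sum(k)
  S <- matrix(0, n, n)
  for (o in -r:r) {
    i <- seq_len(n)
    j <- i + o
    ok <- j >= 1L & j <= n
    S[cbind(i[ok], j[ok])] <- k[o + r + 1L]
  }
  S
}

#' Gaussian smoothing with missing-value-aware normalisation
#'
#' Separable Gaussian blur in which missing (NA/NaN) pixels contribute zero
#' weight: each output pixel is the kernel-weighted mean of its available
#' neighbours (normalised convolution). Image borders are handled the same
#' way, so a constant image stays constant. With `sigma <= 0` the input is
#' returned unchanged.
#'
#' @param x numeric matrix, possibly containing NA.
#' @param sigma kernel standard deviation in pixels.
#' @param keep_na logical; if TRUE (default) pixels missing on input stay
#'   missing on output (values are never invented inside masked areas).
#' @return numeric matrix of the same shape.
#' @export
gauss_smooth <- function(x, sigma, keep_na = TRUE) {
  .check_image(x)
  if (sigma <= 0) return(x)
  w <- ifelse(is.na(x), 0, 1)
  x0 <- ifelse(is.na(x), 0, x)
  Sr <- .smooth_operator(nrow(x), sigma)
  Sc <- .smooth_operator(ncol(x), sigma)
  num <- Sr %*% x0 %*% t(Sc)
  den <- Sr %*% w %*% t(Sc)
  out <- num / den
  out[den < 1e-12] <- NA_real_
  if (keep_na) out[is.na(x)] <- NA_real_
  out
}

## Gaussian smoothing that preserves linear ramps at the borders by padding
## with the odd (anti-symmetric) reflection 2*edge - x. The kernel radius is
## clamped to the padding width so every output pixel sees a complete,
## symmetric kernel (any symmetric kernel leaves an exact ramp unchanged).
## Input must be free of missing values. Used for smoothing flat-field block
## images, where the signal of interest is itself a smooth illumination
## gradient.
.gauss_smooth_ramp <- function(x, sigma) {
  if (sigma <= 0) return(x)
  H <- nrow(x); W <- ncol(x)
  r <- max(1L, as.integer(ceiling(4 * sigma)))
  rr <- min(r, H - 1L); rc <- min(r, W - 1L)
  if (H == 1L && W == 1L) return(x)
  pad <- x
  if (rr > 0L) {
    top <- matrix(0, rr, W)
    bot <- matrix(0, rr, W)
    for (m in seq_len(rr)) {
      top[rr - m + 1L, ] <- 2 * x[1L, ] - x[1L + m, ]
      bot[m, ] <- 2 * x[H, ] - x[H - m, ]
    }
    pad <- rbind(top, pad, bot)
  }
  if (rc > 0L) {
    n <- nrow(pad)
    lef <- matrix(0, n, rc)
    rig <- matrix(0, n, rc)
    for (m in seq_len(rc)) {
      lef[, rc - m + 1L] <- 2 * pad[, 1L] - pad[, 1L + m]
      rig[, m] <- 2 * pad[, W] - pad[, W - m]
    }
    pad <- cbind(lef, pad, rig)
  }
  Sr <- .smooth_operator(nrow(pad), sigma, radius = rr)
  Sc <- .smooth_operator(ncol(pad), sigma, radius = rc)
  num <- Sr %*% pad %*% t(Sc)
  den <- Sr %*% matrix(1, nrow(pad), ncol(pad)) %*% t(Sc)
  sm <- num / den
  sm[rr + seq_len(H), rc + seq_len(W), drop = FALSE]
}

#' Label connected components of a binary mask
#'
#' @param mask logical matrix.
#' @param connectivity 4 or 8 (default 8).
#' @return integer matrix; 0 = background, components numbered from 1.
#' @export
label_components <- function(mask, connectivity = 8L) {
  .check_image(mask, "mask")
  if (!connectivity %in% c(4L, 8L)) stop("connectivity must be 4 or 8")
  cc_label_cpp(mask, as.integer(connectivity))
}

## 3x3-square binary dilation / erosion and one-step closing.
.dilate3 <- function(mask) {
  out <- mask
  for (dy in -1:1)
    for (dx in -1:1)
      if (dy != 0L || dx != 0L)
        out <- out | .shift_fill(mask, dy, dx, FALSE)
  out
}

.erode3 <- function(mask) {
  out <- mask
  for (dy in -1:1)
    for (dx in -1:1)
      if (dy != 0L || dx != 0L)
        out <- out & .shift_fill(mask, dy, dx, TRUE)
  out
}

binary_closing <- function(mask) .erode3(.dilate3(mask))

## Dilation by a euclidean disc of radius r (pixels).
.dilate_disc <- function(mask, r) {
  if (r <= 0) return(mask)
  out <- mask
  ri <- as.integer(floor(r))
  for (dy in -ri:ri)
    for (dx in -ri:ri)
      if ((dy != 0L || dx != 0L) && dy * dy + dx * dx <= r * r)
        out <- out | .shift_fill(mask, dy, dx, FALSE)
  out
}

remove_small_objects <- function(mask, min_area, connectivity = 8L) {
  lab <- label_components(mask, connectivity)
  if (max(lab) == 0L) return(mask)
  areas <- tabulate(lab[lab > 0L])
  keep <- which(areas >= min_area)
  matrix(lab %in% keep, nrow(mask), ncol(mask))
}

## Fill holes: complement components not touching the image border (and, if
## `max_area` is finite, not larger than it) are converted to foreground.
## Complement labelled 4-connected so diagonal leaks do not connect holes to
## the outside.
fill_holes <- function(mask, max_area = Inf) {
  lab <- label_components(!mask, connectivity = 4L)
  if (max(lab) == 0L) return(mask)
  border <- unique(c(lab[1L, ], lab[nrow(lab), ], lab[, 1L], lab[, ncol(lab)]))
  border <- border[border > 0L]
  areas <- tabulate(lab[lab > 0L])
  keep <- setdiff(which(areas <= max_area), border)
  hole <- lab > 0L & (lab %in% keep)
  mask | hole
}

## Per-pixel median over a list of equally shaped matrices, NA-aware.
stack_median <- function(frames) {
  if (!is.list(frames) || length(frames) < 1L) stop("need a non-empty list of frames")
  d <- dim(frames[[1L]])
  for (f in frames) {
    .check_image(f, "frame")
    if (!identical(dim(f), d)) stop("frames differ in shape")
  }
  m <- do.call(rbind, lapply(frames, as.vector))
  matrix(stack_median_cpp(m), d[1L], d[2L])
}

## Linear interpolation matrix mapping values at `centers` (strictly
## increasing, in output coordinates) to `n_out` sample points 1..n_out,
## with linear extrapolation beyond the end centers.
.interp_matrix <- function(n_out, centers) {
  k <- length(centers)
  A <- matrix(0, n_out, k)
  if (k == 1L) {
    A[, 1L] <- 1
    return(A)
  }
  for (i in seq_len(n_out)) {
    p <- i
    j <- findInterval(p, centers, all.inside = TRUE)
    x0 <- centers[j]; x1 <- centers[j + 1L]
    t <- (p - x0) / (x1 - x0)
    A[i, j] <- 1 - t
    A[i, j + 1L] <- t
  }
  A
}

## Bilinear resize of a coarse grid (values at given row/col centers) to a
## full-size image, extrapolating linearly past the outermost centers.
.resize_from_grid <- function(grid, row_centers, col_centers, H, W) {
  A <- .interp_matrix(H, row_centers)
  B <- .interp_matrix(W, col_centers)
  A %*% grid %*% t(B)
}

## Jaccard index of two masks (used throughout the tests).
mask_jaccard <- function(a, b) {
  .same_shape(a, b, "masks")
  u <- sum(a | b)
  if (u == 0L) return(1)
  sum(a & b) / u
}

## Evaluate an expression with a locally seeded RNG, restoring global state.
.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}
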
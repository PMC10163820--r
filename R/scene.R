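## Synthetic scratch-assay scene generator. Produces ground-truthed two-channel
## (donor CFP / acceptor YFP) stacks plus every calibration input the pipeline
## needs: dark frames, empty-well media frames, and unstimulated confluent
## monolayers for flat-field construction.

#' Parameters of a synthetic scratch-assay scene
#'
#' The defaults describe a confluent epithelial monolayer (cells ~20-25 um
#' across, modelled at 22.5 um) carrying a membrane-enriched FRET reporter,
#' scratched north-to-south, imaged on a 16-bit sCMOS camera through a 20x
#' objective (0.325 um/px), with an activity gradient that is highest at the
#' wound edge and decays into the monolayer.
#'
#' @param image_height,image_width frame size in pixels.
#' @param pixel_scale micrometres per pixel.
#' @param scratch_half_width half-width of the scratch at t = 0, um.
#' @param cell_diameter_mean mean cell diameter, um.
#' @param edge_ratio true acceptor/donor ratio at distance 0 from the edge.
#' @param baseline_ratio true far-field ratio (must satisfy
#'   `edge_ratio >= baseline_ratio > 0`).
#' @param gradient_length exponential decay length of the ratio gradient, um.
#' @param donor_level nominal donor counts inside cells.
#' @param media_level counts contributed by the culture media (scratch and
#'   empty wells).
#' @param vignetting_amplitude fractional top-to-bottom multiplicative
#'   gradient applied to the acceptor channel (0.2 = +10% at the top row,
#'   -10% at the bottom row).
#' @param n_speckles bright puncta injected per frame.
#' @param speckle_diameter punctum side length, pixels.
#' @param speckle_intensity punctum brightness as a multiple of the local
#'   signal.
#' @param dark_offset camera dark offset, counts.
#' @param noise_sd additive Gaussian read/shot noise, counts.
#' @param texture_sd relative s.d. of the smooth cell-to-cell brightness
#'   field (makes intensity histograms continuous, as in real monolayers).
#' @param gap_fraction fraction of the monolayer occupied by small acellular
#'   gaps (media-level holes); real confluent monolayers are never perfectly
#'   sealed, and these genuine background pixels are what anchors the
#'   empty-well background scaling. Gaps avoid a one-cell-diameter margin
#'   around the scratch.
#' @param edge_waviness_px amplitude of the sinusoidal scratch-edge waviness.
#' @param closure_speed speed at which each wound edge advances, um per hour.
#' @param frame_interval minutes between frames.
#' @param n_frames number of time points.
#' @param seed RNG seed; identical params give bitwise-identical scenes.
#' @return object of class `scene_params`.
#' @export
scene_params <- function(image_height = 512L, image_width = 1024L,
                         pixel_scale = 0.325, scratch_half_width = 30,
                         cell_diameter_mean = 22.5,
                         edge_ratio = 1.3, baseline_ratio = 1.0,
                         gradient_length = 30,
                         donor_level = 1000, media_level = 30,
                         vignetting_amplitude = 0.2,
                         n_speckles = 10L, speckle_diameter = 3L,
                         speckle_intensity = 10,
                         dark_offset = 100, noise_sd = 25,
                         texture_sd = 0.12, gap_fraction = 0.02,
                         edge_waviness_px = 2,
                         closure_speed = 10, frame_interval = 15,
                         n_frames = 5L, seed = 1L) {
  p <- list(image_height = as.integer(image_height),
            image_width = as.integer(image_width),
            pixel_scale = pixel_scale, scratch_half_width = scratch_half_width,
            cell_diameter_mean = cell_diameter_mean,
            edge_ratio = edge_ratio, baseline_ratio = baseline_ratio,
            gradient_length = gradient_length, donor_level = donor_level,
            media_level = media_level,
            vignetting_amplitude = vignetting_amplitude,
            n_speckles = as.integer(n_speckles),
            speckle_diameter = as.integer(speckle_diameter),
            speckle_intensity = speckle_intensity,
            dark_offset = dark_offset, noise_sd = noise_sd,
            texture_sd = texture_sd, gap_fraction = gap_fraction,
            edge_waviness_px = edge_waviness_px,
            closure_speed = closure_speed, frame_interval = frame_interval,
            n_frames = as.integer(n_frames), seed = as.integer(seed))
  class(p) <- "scene_params"
  validate_scene_params(p)
  p
}

validate_scene_params <- function(p) {
  if (p$image_height <= 0L || p$image_width <= 0L)
    stop("image dimensions must be positive")
  if (p$pixel_scale <= 0) stop("pixel_scale must be positive")
  if (!(p$edge_ratio >= p$baseline_ratio) || p$baseline_ratio <= 0)
    stop("need edge_ratio >= baseline_ratio > 0")
  if (p$gradient_length <= 0) stop("gradient_length must be positive")
  if (2 * p$scratch_half_width / p$pixel_scale >= p$image_width)
    stop("scratch wider than the image")
  if (p$n_frames < 1L) stop("need at least one frame")
  invisible(p)
}

## Per-row vignetting factor: linear top-to-bottom gradient of total
## amplitude a, centred on 1 (top row x (1 + a/2), bottom row x (1 - a/2)).
.vignette_profile <- function(H, amplitude) {
  1 + amplitude * (0.5 - (seq_len(H) - 1) / max(1L, H - 1L))
}

## Scratch geometry at frame index t (0-based): logical scratch mask and the
## set of its edge pixels, for a north-south scratch with a wavy edge.
.scratch_geometry <- function(p, t) {
  H <- p$image_height; W <- p$image_width
  hours <- t * p$frame_interval / 60
  hw_um <- max(0, p$scratch_half_width - p$closure_speed * hours)
  hw_px <- hw_um / p$pixel_scale
  cx <- (W + 1) / 2
  wave <- p$edge_waviness_px * sin(2 * pi * seq_len(H) / max(16, H / 3))
  col <- matrix(seq_len(W), H, W, byrow = TRUE)
  lo <- matrix(cx - hw_px + wave, H, W)
  hi <- matrix(cx + hw_px + wave, H, W)
  scratch <- if (hw_px <= 0) matrix(FALSE, H, W) else col > lo & col < hi
  ## edge pixels: scratch pixels 4-adjacent to non-scratch
  edge <- scratch & !(.shift_fill(scratch, -1L, 0L, TRUE) &
                      .shift_fill(scratch, 1L, 0L, TRUE) &
                      .shift_fill(scratch, 0L, -1L, TRUE) &
                      .shift_fill(scratch, 0L, 1L, TRUE))
  list(scratch = scratch, edge = edge, half_width_px = hw_px)
}

## Random elliptical acellular gaps covering ~gap_fraction of the frame.
## `avoid_cols` is a column interval (e.g. around the scratch) kept gap-free.
.gap_mask <- function(p, avoid_cols = NULL) {
  H <- p$image_height; W <- p$image_width
  gaps <- matrix(FALSE, H, W)
  if (p$gap_fraction <= 0) return(gaps)
  target <- p$gap_fraction * H * W
  cd <- p$cell_diameter_mean / p$pixel_scale
  guard <- 0L
  while (sum(gaps) < target && guard < 500L) {
    guard <- guard + 1L
    cy <- stats::runif(1, 1, H)
    cx <- stats::runif(1, 1, W)
    if (!is.null(avoid_cols) && cx >= avoid_cols[1L] - cd && cx <= avoid_cols[2L] + cd)
      next
    a <- stats::runif(1, 0.4, 0.9) * cd
    b <- stats::runif(1, 0.4, 0.9) * cd
    th <- stats::runif(1, 0, pi)
    ri <- max(1L, floor(cy - max(a, b))):min(H, ceiling(cy + max(a, b)))
    ci <- max(1L, floor(cx - max(a, b))):min(W, ceiling(cx + max(a, b)))
    yy <- matrix(ri - cy, length(ri), length(ci))
    xx <- matrix(ci - cx, length(ri), length(ci), byrow = TRUE)
    u <- xx * cos(th) + yy * sin(th)
    v <- -xx * sin(th) + yy * cos(th)
    gaps[ri, ci] <- gaps[ri, ci] | ((u / a)^2 + (v / b)^2 <= 1)
  }
  gaps
}

## Jittered hexagonal lattice of cell centres covering the frame, plus the
## per-pixel distance (px) to the nearest centre, used to paint membrane rims.
.cell_texture <- function(p) {
  H <- p$image_height; W <- p$image_width
  s <- p$cell_diameter_mean / p$pixel_scale      # centre spacing, px
  dy <- s * sqrt(3) / 2
  rows <- seq(1, H + dy, by = dy)
  centers <- NULL
  for (k in seq_along(rows)) {
    off <- if (k %% 2L == 0L) s / 2 else 0
    xs <- seq(1 + off, W + s, by = s)
    jit_x <- stats::runif(length(xs), -0.15 * s, 0.15 * s)
    jit_y <- stats::runif(length(xs), -0.15 * s, 0.15 * s)
    centers <- rbind(centers, cbind(rows[k] + jit_y, xs + jit_x))
  }
  ci <- round(centers)
  keep <- ci[, 1L] >= 1 & ci[, 1L] <= H & ci[, 2L] >= 1 & ci[, 2L] <= W
  ci <- ci[keep, , drop = FALSE]
  src <- matrix(FALSE, H, W)
  src[ci] <- TRUE
  all_px <- matrix(TRUE, H, W)
  d_center <- geodesic_dist_cpp(all_px, src)
  r_b <- 0.5 * s
  rim <- d_center >= 0.76 * r_b & d_center <= 1.08 * r_b
  ## smooth multiplicative brightness field (cell-to-cell heterogeneity)
  field <- gauss_smooth(matrix(stats::rnorm(H * W), H, W), s / 2, keep_na = FALSE)
  field <- field / stats::sd(field)
  tex <- ifelse(rim, 1.5, 0.75) * (1 + p$texture_sd * field)
  list(tex = pmax(tex, 0.05), rim = rim)
}

#' Generate a ground-truthed synthetic scratch-assay scene
#'
#' Renders a two-channel time-lapse of a confluent monolayer with a
#' north-south scratch. The true acceptor/donor ratio at a cell pixel is
#' `baseline_ratio + (edge_ratio - baseline_ratio) * exp(-d / gradient_length)`
#' where `d` is the distance (um) to the nearest scratch-edge pixel. The
#' acceptor channel carries a linear top-to-bottom vignetting gradient; both
#' channels carry the camera dark offset, Gaussian noise, and bright puncta
#' at recorded coordinates. The scratch narrows at `closure_speed` per edge.
#'
#' @param params a [scene_params()] object.
#' @return a `fret_scene`: lists `donor_frames`, `acceptor_frames`,
#'   `truth_ratio_field`, `truth_cell_mask`, `truth_scratch_mask`,
#'   `truth_edge_mask`, `truth_rim_mask`, `truth_speckle_centers` (one entry
#'   per frame), `time_min`, and `params`.
#' @export
generate_scene <- function(params) {
  stopifnot(inherits(params, "scene_params"))
  validate_scene_params(params)
  p <- params
  H <- p$image_height; W <- p$image_width
  .with_seed(p$seed, {
    texture <- .cell_texture(p)
    tex <- texture$tex
    hw0 <- p$scratch_half_width / p$pixel_scale
    cx0 <- (W + 1) / 2
    gaps <- .gap_mask(p, avoid_cols = c(cx0 - hw0, cx0 + hw0))
    vig <- .vignette_profile(H, p$vignetting_amplitude)
    donor_frames <- acceptor_frames <- truth_ratio <- vector("list", p$n_frames)
    cell_masks <- scratch_masks <- edge_masks <- speckles <- vector("list", p$n_frames)
    for (t in seq_len(p$n_frames)) {
      g <- .scratch_geometry(p, t - 1L)
      cell <- !g$scratch & !gaps
      if (any(g$edge)) {
        d_px <- geodesic_dist_cpp(matrix(TRUE, H, W), g$edge)
        d_um <- d_px * p$pixel_scale
        ratio <- p$baseline_ratio +
          (p$edge_ratio - p$baseline_ratio) * exp(-d_um / p$gradient_length)
      } else {
        ratio <- matrix(p$baseline_ratio, H, W)
      }
      ratio[!cell] <- NA_real_
      donor <- ifelse(cell, p$donor_level * tex, p$media_level)
      acceptor <- ifelse(cell, donor * ratio, p$media_level)
      acceptor <- acceptor * matrix(vig, H, W)
      ## speckles: bright square puncta at recorded centres, on cell pixels
      ctr <- NULL
      if (p$n_speckles > 0L) {
        ## complete puncta only: keep centres a radius away from the border
        rb <- (p$speckle_diameter - 1L) %/% 2L + 1L
        inb <- cell
        inb[c(seq_len(rb), H - seq_len(rb) + 1L), ] <- FALSE
        inb[, c(seq_len(rb), W - seq_len(rb) + 1L)] <- FALSE
        idx <- which(inb)
        ## puncta are rare and distinct: enforce a minimum separation so two
        ## draws never fuse into one (elongated) object
        min_sep <- 3L * p$speckle_diameter
        cand <- sample(idx, min(length(idx), 50L * p$n_speckles))
        rows <- (cand - 1L) %% H + 1L
        cols <- (cand - 1L) %/% H + 1L
        keep <- integer(0)
        for (k in seq_along(cand)) {
          if (length(keep) >= p$n_speckles) break
          if (length(keep) == 0L ||
              all(pmax(abs(rows[keep] - rows[k]), abs(cols[keep] - cols[k])) >= min_sep))
            keep <- c(keep, k)
        }
        ctr <- cbind(row = rows[keep], col = cols[keep])
        r <- (p$speckle_diameter - 1L) %/% 2L
        for (k in seq_len(nrow(ctr))) {
          rows <- max(1L, ctr[k, 1L] - r):min(H, ctr[k, 1L] + r)
          cols <- max(1L, ctr[k, 2L] - r):min(W, ctr[k, 2L] + r)
          boost <- (p$speckle_intensity - 1) * donor[ctr[k, 1L], ctr[k, 2L]]
          donor[rows, cols] <- donor[rows, cols] + boost
          acceptor[rows, cols] <- acceptor[rows, cols] + boost
        }
      }
      donor <- donor + p$dark_offset
      acceptor <- acceptor + p$dark_offset
      if (p$noise_sd > 0) {
        donor <- donor + matrix(stats::rnorm(H * W, sd = p$noise_sd), H, W)
        acceptor <- acceptor + matrix(stats::rnorm(H * W, sd = p$noise_sd), H, W)
      }
      donor_frames[[t]] <- donor
      acceptor_frames[[t]] <- acceptor
      truth_ratio[[t]] <- ratio
      cell_masks[[t]] <- cell
      scratch_masks[[t]] <- g$scratch
      edge_masks[[t]] <- g$edge
      speckles[[t]] <- ctr
    }
    structure(list(donor_frames = donor_frames,
                   acceptor_frames = acceptor_frames,
                   truth_ratio_field = truth_ratio,
                   truth_cell_mask = cell_masks,
                   truth_scratch_mask = scratch_masks,
                   truth_edge_mask = edge_masks,
                   truth_rim_mask = texture$rim,
                   truth_gap_mask = gaps,
                   truth_speckle_centers = speckles,
                   time_min = (seq_len(p$n_frames) - 1L) * p$frame_interval,
                   params = p),
              class = "fret_scene")
  })
}

#' @export
print.fret_scene <- function(x, ...) {
  p <- x$params
  cat(sprintf("fret_scene: %d frame(s) %dx%d px (%.3f um/px), scratch half-width %.1f um\n",
              p$n_frames, p$image_height, p$image_width, p$pixel_scale,
              p$scratch_half_width))
  cat(sprintf("  true ratio: %.3f at edge -> %.3f far-field (decay %.1f um)\n",
              p$edge_ratio, p$baseline_ratio, p$gradient_length))
  invisible(x)
}

#' Generate calibration support frames
#'
#' @param params a [scene_params()] object.
#' @param kind `"dark"` (camera offset + noise only), `"empty_well"`
#'   (media-level background; 8 frames by default, matching standard
#'   practice), or `"flat_calibration"` (unscratched confluent monolayer with
#'   spatially constant true ratio plus the vignetting gradient, for building
#'   the ratio-correction image).
#' @param n_frames number of frames; defaults: dark 5, empty_well 8,
#'   flat_calibration 5.
#' @return list with elements `donor` and `acceptor`, each a list of frames.
#' @export
generate_support_frames <- function(params, kind = c("dark", "empty_well", "flat_calibration"),
                                    n_frames = NULL) {
  stopifnot(inherits(params, "scene_params"))
  kind <- match.arg(kind)
  p <- params
  H <- p$image_height; W <- p$image_width
  if (is.null(n_frames))
    n_frames <- switch(kind, dark = 5L, empty_well = 8L, flat_calibration = 5L)
  n_frames <- as.integer(n_frames)
  if (n_frames < 1L) stop("need at least one frame")
  seed_off <- switch(kind, dark = 7919L, empty_well = 104729L, flat_calibration = 1299709L)
  .with_seed((p$seed + seed_off) %% .Machine$integer.max, {
    noise <- function() {
      if (p$noise_sd > 0) matrix(stats::rnorm(H * W, sd = p$noise_sd), H, W)
      else matrix(0, H, W)
    }
    mk <- function(base_d, base_a) {
      list(donor = lapply(seq_len(n_frames), function(i) base_d + noise()),
           acceptor = lapply(seq_len(n_frames), function(i) base_a + noise()))
    }
    if (kind == "dark") {
      z <- matrix(p$dark_offset, H, W)
      mk(z, z)
    } else if (kind == "empty_well") {
      b <- matrix(p$media_level + p$dark_offset, H, W)
      mk(b, b)
    } else {
      tex <- .cell_texture(p)$tex
      gaps <- .gap_mask(p)
      vig <- .vignette_profile(H, p$vignetting_amplitude)
      donor <- ifelse(gaps, p$media_level, p$donor_level * tex)
      acceptor <- ifelse(gaps, p$media_level, donor * p$baseline_ratio)
      acceptor <- acceptor * matrix(vig, H, W)
      mk(donor + p$dark_offset, acceptor + p$dark_offset)
    }
  })
}
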
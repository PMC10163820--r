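## Per-well orchestration: configuration, calibration, the frame-level
## analysis chain, file-based time-lapse runs, and the command-line entry
## point. Every numeric default below is either a published constant of the
## segmentation/correction recipe or a documented design choice.

#' Pipeline configuration
#'
#' @param paths named list of input files (TIFF stacks): `donor`, `acceptor`,
#'   `dark_donor`, `dark_acceptor`, `empty_donor`, `empty_acceptor`,
#'   `calib_donor`, `calib_acceptor`. May be left NULL for in-memory use.
#' @param out_dir output directory for [run_well_timelapse()].
#' @param well_id,group labels carried into all outputs.
#' @param pixel_scale micrometres per pixel (0.325 um/px for a 20x objective
#'   with 6.5 um sCMOS pixels; configuration, not a constant).
#' @param frame_interval minutes between frames (default 15).
#' @param analysis_times minutes of migration at which profiles are computed
#'   (defaults 60, 360, 720 = 1, 6, 12 h); the nearest frame is used.
#' @param max_shift largest accepted channel misregistration, pixels.
#' @param block_size ratio-correction block edge (default 24 px).
#' @param correction_sigma Gaussian sigma for the correction block image, in
#'   block units (default 5).
#' @param ratio_sigma Gaussian sigma for channel smoothing before ratioing
#'   (default 2 px).
#' @param bin_width distance bin width, um (default 5).
#' @param edge_dilate_px scratch-edge dilation (default 2 px).
#' @param report_distances distances (um) at which group comparisons are
#'   reported (defaults 5 and 100).
#' @param seg a [segmentation_params()] object.
#' @param seed RNG seed for any stochastic stage.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(paths = list(), out_dir = NULL,
                            well_id = "well1", group = "control",
                            pixel_scale = 0.325, frame_interval = 15,
                            analysis_times = c(60, 360, 720),
                            max_shift = 10L, block_size = 24L,
                            correction_sigma = 5, ratio_sigma = 2,
                            bin_width = 5, edge_dilate_px = 2L,
                            report_distances = c(5, 100),
                            seg = segmentation_params(), seed = 1L) {
  if (pixel_scale <= 0) stop("pixel_scale must be positive")
  if (bin_width <= 0) stop("bin_width must be positive")
  structure(list(paths = paths, out_dir = out_dir, well_id = well_id,
                 group = group, pixel_scale = pixel_scale,
                 frame_interval = frame_interval,
                 analysis_times = analysis_times, max_shift = as.integer(max_shift),
                 block_size = as.integer(block_size),
                 correction_sigma = correction_sigma, ratio_sigma = ratio_sigma,
                 bin_width = bin_width, edge_dilate_px = as.integer(edge_dilate_px),
                 report_distances = report_distances, seg = seg,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Load a TIFF stack as channel frames
#'
#' @param path TIFF file (grayscale; RGB is rejected).
#' @param channel_role `"donor"` or `"acceptor"`, declared in config and
#'   never inferred from the filename.
#' @param frame_interval minutes between frames; frame k gets time
#'   `(k - 1) * frame_interval`.
#' @return list of matrices with attributes `channel_role` and `time_min`.
#' @export
load_image_stack <- function(path, channel_role = c("donor", "acceptor"),
                             frame_interval = 15) {
  channel_role <- match.arg(channel_role)
  frames <- read_tiff_stack(path)
  times <- (seq_along(frames) - 1) * frame_interval
  attr(frames, "channel_role") <- channel_role
  attr(frames, "time_min") <- times
  frames
}

#' Build the correction bundle from calibration stacks
#'
#' Dark images are per-pixel medians of the dark stacks; empty-well
#' background images are per-pixel medians of the dark-corrected empty-well
#' stacks; the ratio-correction image is built from unstimulated confluent
#' monolayer frames processed by the standard pipeline (dark correction,
#' alignment, scaled background subtraction, segmentation, speckle
#' filtering, smoothing, ratio) with the correction itself left out.
#'
#' @param dark list with `donor`, `acceptor` lists of dark frames.
#' @param empty list with `donor`, `acceptor` lists of empty-well frames.
#' @param calib list with `donor`, `acceptor` lists of monolayer frames.
#' @param config a [pipeline_config()].
#' @return a `correction_bundle`: list with `dark` (per channel),
#'   `background` (per channel) and `ratio_correction`.
#' @export
calibrate_corrections <- function(dark, empty, calib, config = pipeline_config()) {
  dark_d <- estimate_dark_image(dark$donor)
  dark_a <- estimate_dark_image(dark$acceptor)
  bg_d <- estimate_well_background(lapply(empty$donor, subtract_dark, dark = dark_d))
  bg_a <- estimate_well_background(lapply(empty$acceptor, subtract_dark, dark = dark_a))
  ratios <- list(); cmasks <- list()
  for (k in seq_along(calib$donor)) {
    st <- .analyze_frame_core(calib$donor[[k]], calib$acceptor[[k]],
                              dark_d, dark_a, bg_d, bg_a, NULL, config)
    ratios[[k]] <- st$ratio_image$ratio
    cmasks[[k]] <- st$masks$cell
  }
  rc <- build_ratio_correction(ratios, cmasks, config$block_size,
                               config$correction_sigma)
  structure(list(dark = list(donor = dark_d, acceptor = dark_a),
                 background = list(donor = bg_d, acceptor = bg_a),
                 ratio_correction = rc),
            class = "correction_bundle")
}

## Shared per-frame chain: dark correction -> alignment/crop -> background
## mask -> scaled background subtraction -> cell/scratch masks -> speckle
## mask -> ratio image (corrected exactly once when a correction is given).
.analyze_frame_core <- function(donor_raw, acceptor_raw, dark_d, dark_a,
                                bg_d, bg_a, correction, config) {
  d0 <- subtract_dark(donor_raw, dark_d)
  a0 <- subtract_dark(acceptor_raw, dark_a)
  al <- align_channel_pair(d0, a0, config$max_shift)
  crop <- function(img) img[al$crop$rows[1L]:al$crop$rows[2L],
                            al$crop$cols[1L]:al$crop$cols[2L], drop = FALSE]
  bg_d_c <- crop(bg_d); bg_a_c <- crop(bg_a)
  corr_c <- if (is.null(correction)) NULL else {
    img <- if (inherits(correction, "ratio_correction")) correction$image else correction
    crop(img)
  }
  bgmask <- background_mask_from_image(al$donor + al$acceptor)
  d_sub <- scale_subtract_background(al$donor, bg_d_c, bgmask)
  a_sub <- scale_subtract_background(al$acceptor, bg_a_c, bgmask)
  ms <- cell_scratch_masks(d_sub, a_sub, config$seg)
  ms$speckle <- speckle_mask(d_sub, a_sub, config$seg)
  ri <- compute_ratio_image(d_sub, a_sub, ms, corr_c, config$ratio_sigma)
  list(aligned = al, masks = ms, ratio_image = ri, correction_cropped = corr_c,
       qc = data.frame(shift_dy = al$shift_applied[["dy"]],
                       shift_dx = al$shift_applied[["dx"]],
                       bg_scale_donor = attr(d_sub, "scale"),
                       bg_scale_acceptor = attr(a_sub, "scale"),
                       frac_missing = mean(is.na(ri$ratio)),
                       ratio_median = stats::median(ri$ratio, na.rm = TRUE)))
}

#' Analyse one registered frame pair end to end
#'
#' Runs the full chain on a raw donor/acceptor pair and bins the FRET
#' profile by geodesic distance from the scratch edge, per side.
#'
#' @param donor_raw,acceptor_raw raw frames.
#' @param bundle a `correction_bundle` from [calibrate_corrections()].
#' @param config a [pipeline_config()].
#' @param time_min frame time (minutes).
#' @return list with `masks`, `ratio_image`, `geometry` (edges, sides,
#'   distance fields), `profile` (data.frame, both sides), `qc`.
#' @export
analyze_frame_pair <- function(donor_raw, acceptor_raw, bundle, config,
                               time_min = NA_real_) {
  st <- .analyze_frame_core(donor_raw, acceptor_raw,
                            bundle$dark$donor, bundle$dark$acceptor,
                            bundle$background$donor, bundle$background$acceptor,
                            bundle$ratio_correction, config)
  ms <- st$masks
  if (!any(ms$scratch)) stop("no scratch detected in frame at t = ", time_min)
  edges <- scratch_edge_masks(ms$scratch, config$edge_dilate_px, config$seg$connectivity)
  sides <- side_split_cell_mask(ms$cell, ms$scratch)
  prof <- list(); dist_fields <- list()
  for (side in c("left", "right")) {
    edge <- edges[[paste0(side, "_edge")]]
    cells <- sides[[paste0(side, "_cells")]]
    if (is.null(edge) || !any(cells & edge)) next
    dist <- quasi_euclidean_distance(cells, edge, config$pixel_scale)
    dist_fields[[side]] <- dist
    prof[[side]] <- bin_fret_profile(dist, st$ratio_image$donor_smooth,
                                     st$ratio_image$acceptor_smooth,
                                     correction = st$correction_cropped,
                                     bin_width = config$bin_width,
                                     side = side, time_min = time_min,
                                     well = config$well_id, group = config$group)
  }
  if (length(prof) == 0L) stop("no scratch side could be profiled")
  list(masks = ms, ratio_image = st$ratio_image,
       geometry = list(edges = edges, sides = sides, distance = dist_fields),
       profile = do.call(rbind, c(prof, list(make.row.names = FALSE))),
       qc = st$qc)
}

#' Analyse a synthetic scene in memory
#'
#' Convenience wrapper: generates (or accepts) the calibration inputs for a
#' scene, builds the correction bundle, and analyses the requested frames.
#'
#' @param scene a `fret_scene` from [generate_scene()].
#' @param config a [pipeline_config()]; its `pixel_scale` should match the
#'   scene's.
#' @param support optional list with `dark`, `empty`, `calib` stacks
#'   ([generate_support_frames()] output); generated from the scene's params
#'   when NULL.
#' @param times frame times (minutes) to analyse; defaults to all frames.
#' @return list with `profiles` (data.frame over frames and sides),
#'   `bundle`, `frames` (per-frame analysis results), `qc`.
#' @export
analyze_scene <- function(scene, config = NULL, support = NULL, times = NULL) {
  stopifnot(inherits(scene, "fret_scene"))
  p <- scene$params
  if (is.null(config))
    config <- pipeline_config(pixel_scale = p$pixel_scale,
                              frame_interval = p$frame_interval,
                              analysis_times = scene$time_min, seed = p$seed)
  if (is.null(support))
    support <- list(dark = generate_support_frames(p, "dark"),
                    empty = generate_support_frames(p, "empty_well"),
                    calib = generate_support_frames(p, "flat_calibration"))
  bundle <- calibrate_corrections(support$dark, support$empty, support$calib, config)
  if (is.null(times)) times <- scene$time_min
  idx <- vapply(times, function(t) which.min(abs(scene$time_min - t)), integer(1))
  idx <- unique(idx)
  res <- lapply(idx, function(k)
    analyze_frame_pair(scene$donor_frames[[k]], scene$acceptor_frames[[k]],
                       bundle, config, time_min = scene$time_min[k]))
  profiles <- do.call(rbind, c(lapply(res, `[[`, "profile"),
                               list(make.row.names = FALSE)))
  qc <- do.call(rbind, lapply(seq_along(res), function(i)
    cbind(time_min = scene$time_min[idx[i]], res[[i]]$qc)))
  list(profiles = profiles, bundle = bundle, frames = res, qc = qc)
}

#' Simulate and analyse a group of replicate wells
#'
#' Generates `n_wells` independent scenes (seeds `params$seed + 1..n_wells`),
#' analyses each with the full pipeline, and returns well-level bin means.
#' The correction bundle (dark, empty-well background, ratio correction) is
#' built once and shared across wells, as in a real experiment where the
#' flat-field calibration belongs to the instrument, not the well.
#'
#' @param params a [scene_params()] object describing the group's wells.
#' @param n_wells number of replicate wells.
#' @param group group label.
#' @param bundle optional pre-built `correction_bundle` (must match the
#'   scene geometry); built from `params` when NULL.
#' @param config optional [pipeline_config()]; derived from `params` when
#'   NULL.
#' @param times frame times (minutes) to analyse; defaults to all frames.
#' @param well_effect_sd standard deviation (log scale) of a per-well
#'   multiplicative factor on the true ratio field (baseline and edge ratio
#'   scaled together). Models inter-well biosensor/detection variability;
#'   0 (default) gives technically identical wells differing only in noise,
#'   texture and speckle realisations.
#' @return data.frame of well-level bin means ([well_bin_means()] format).
#' @export
simulate_group_wells <- function(params, n_wells, group = "group",
                                 bundle = NULL, config = NULL, times = NULL,
                                 well_effect_sd = 0) {
  stopifnot(inherits(params, "scene_params"))
  if (is.null(config))
    config <- pipeline_config(pixel_scale = params$pixel_scale,
                              frame_interval = params$frame_interval,
                              group = group, seed = params$seed)
  if (is.null(bundle)) {
    support <- list(dark = generate_support_frames(params, "dark"),
                    empty = generate_support_frames(params, "empty_well"),
                    calib = generate_support_frames(params, "flat_calibration"))
    bundle <- calibrate_corrections(support$dark, support$empty, support$calib, config)
  }
  out <- vector("list", n_wells)
  for (w in seq_len(n_wells)) {
    pw <- unclass(params)
    pw$seed <- (params$seed + w) %% .Machine$integer.max
    if (well_effect_sd > 0) {
      f <- .with_seed((pw$seed + 31L) %% .Machine$integer.max,
                      exp(stats::rnorm(1, 0, well_effect_sd)))
      pw$baseline_ratio <- pw$baseline_ratio * f
      pw$edge_ratio <- pw$edge_ratio * f
    }
    scene <- generate_scene(do.call(scene_params, pw))
    cfg_w <- config
    cfg_w$well_id <- sprintf("%s_w%02d", group, w)
    cfg_w$group <- group
    if (is.null(times)) times <- scene$time_min
    idx <- unique(vapply(times, function(t) which.min(abs(scene$time_min - t)),
                         integer(1)))
    prof <- do.call(rbind, lapply(idx, function(k)
      analyze_frame_pair(scene$donor_frames[[k]], scene$acceptor_frames[[k]],
                         bundle, cfg_w, time_min = scene$time_min[k])$profile))
    out[[w]] <- well_bin_means(prof)
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Run the full per-well time-lapse analysis from files
#'
#' Loads the stacks named in `config$paths`, builds the correction bundle,
#' analyses the frames nearest `config$analysis_times`, and writes
#' `profiles.csv`, `qc.csv`, per-frame ratio images (32-bit float TIFF),
#' cell/background/scratch/speckle masks (8-bit TIFF) and a provenance JSON
#' into `config$out_dir`. Outputs are deterministic given the config; partial
#' results are removed on failure.
#'
#' @param config a [pipeline_config()] whose `paths` and `out_dir` are set.
#' @return invisibly, the list from the analysis (profiles, bundle, frames).
#' @export
run_well_timelapse <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  need <- c("donor", "acceptor", "dark_donor", "dark_acceptor",
            "empty_donor", "empty_acceptor", "calib_donor", "calib_acceptor")
  for (nm in need) {
    pth <- config$paths[[nm]]
    if (is.null(pth)) stop("config$paths$", nm, " is not set")
    if (!file.exists(pth)) stop("input not found: paths$", nm, " = ", pth)
  }
  if (is.null(config$out_dir)) stop("config$out_dir is not set")
  donor <- load_image_stack(config$paths$donor, "donor", config$frame_interval)
  acceptor <- load_image_stack(config$paths$acceptor, "acceptor", config$frame_interval)
  if (length(donor) != length(acceptor))
    stop("donor and acceptor stacks differ in frame count")
  support <- list(
    dark = list(donor = read_tiff_stack(config$paths$dark_donor),
                acceptor = read_tiff_stack(config$paths$dark_acceptor)),
    empty = list(donor = read_tiff_stack(config$paths$empty_donor),
                 acceptor = read_tiff_stack(config$paths$empty_acceptor)),
    calib = list(donor = read_tiff_stack(config$paths$calib_donor),
                 acceptor = read_tiff_stack(config$paths$calib_acceptor)))
  times <- attr(donor, "time_min")
  bundle <- calibrate_corrections(support$dark, support$empty, support$calib, config)
  idx <- unique(vapply(config$analysis_times,
                       function(t) which.min(abs(times - t)), integer(1)))
  tmp <- tempfile("well_out_")
  dir.create(tmp, recursive = TRUE)
  ok <- FALSE
  on.exit(if (!ok) unlink(tmp, recursive = TRUE))
  res <- vector("list", length(idx))
  for (i in seq_along(idx)) {
    k <- idx[i]
    r <- tryCatch(
      analyze_frame_pair(donor[[k]], acceptor[[k]], bundle, config, times[k]),
      error = function(e) stop("frame ", k, " (t = ", times[k], " min): ",
                               conditionMessage(e), call. = FALSE))
    res[[i]] <- r
    tag <- sprintf("t%04d", as.integer(times[k]))
    write_tiff_stack(r$ratio_image$ratio, file.path(tmp, paste0("ratio_", tag, ".tif")), 32L)
    write_tiff_stack(lapply(list(r$masks$cell, r$masks$background,
                                 r$masks$scratch, r$masks$speckle),
                            function(m) matrix(as.numeric(m) * 255, nrow(m), ncol(m))),
                     file.path(tmp, paste0("masks_", tag, ".tif")), 8L)
  }
  profiles <- do.call(rbind, c(lapply(res, `[[`, "profile"),
                               list(make.row.names = FALSE)))
  qc <- do.call(rbind, lapply(seq_along(res), function(i)
    cbind(time_min = times[idx[i]], res[[i]]$qc)))
  utils::write.csv(profiles, file.path(tmp, "profiles.csv"), row.names = FALSE)
  utils::write.csv(qc, file.path(tmp, "qc.csv"), row.names = FALSE)
  write_tiff_stack(bundle$ratio_correction$image,
                   file.path(tmp, "ratio_correction.tif"), 32L)
  prov <- list(well_id = config$well_id, group = config$group,
               inputs = config$paths[need],
               parameters = config[c("pixel_scale", "frame_interval",
                                     "analysis_times", "max_shift", "block_size",
                                     "correction_sigma", "ratio_sigma",
                                     "bin_width", "edge_dilate_px", "seed")],
               segmentation = unclass(config$seg),
               analyzed_times_min = times[idx],
               ratio_correction_applications = 1L)
  jsonlite::write_json(prov, file.path(tmp, "provenance.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  for (f in list.files(tmp, full.names = TRUE))
    file.copy(f, file.path(config$out_dir, basename(f)), overwrite = TRUE)
  unlink(tmp, recursive = TRUE)
  ok <- TRUE
  invisible(list(profiles = profiles, bundle = bundle, frames = res, qc = qc))
}

#' Write a synthetic scene and its calibration inputs to TIFF files
#'
#' Emits 16-bit donor/acceptor stacks, all support stacks, 8-bit ground-truth
#' masks and a JSON sidecar with the parameters and speckle coordinates.
#'
#' @param scene a `fret_scene`.
#' @param dir output directory (created).
#' @return named list of the written paths.
#' @export
write_scene <- function(scene, dir) {
  stopifnot(inherits(scene, "fret_scene"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- scene$params
  support <- list(dark = generate_support_frames(p, "dark"),
                  empty = generate_support_frames(p, "empty_well"),
                  calib = generate_support_frames(p, "flat_calibration"))
  paths <- list(
    donor = file.path(dir, "donor.tif"),
    acceptor = file.path(dir, "acceptor.tif"),
    dark_donor = file.path(dir, "dark_donor.tif"),
    dark_acceptor = file.path(dir, "dark_acceptor.tif"),
    empty_donor = file.path(dir, "empty_donor.tif"),
    empty_acceptor = file.path(dir, "empty_acceptor.tif"),
    calib_donor = file.path(dir, "calib_donor.tif"),
    calib_acceptor = file.path(dir, "calib_acceptor.tif"))
  write_tiff_stack(scene$donor_frames, paths$donor, 16L)
  write_tiff_stack(scene$acceptor_frames, paths$acceptor, 16L)
  write_tiff_stack(support$dark$donor, paths$dark_donor, 16L)
  write_tiff_stack(support$dark$acceptor, paths$dark_acceptor, 16L)
  write_tiff_stack(support$empty$donor, paths$empty_donor, 16L)
  write_tiff_stack(support$empty$acceptor, paths$empty_acceptor, 16L)
  write_tiff_stack(support$calib$donor, paths$calib_donor, 16L)
  write_tiff_stack(support$calib$acceptor, paths$calib_acceptor, 16L)
  to8 <- function(m) matrix(as.numeric(m) * 255, nrow(m), ncol(m))
  write_tiff_stack(lapply(scene$truth_cell_mask, to8),
                   file.path(dir, "truth_cell_mask.tif"), 8L)
  write_tiff_stack(lapply(scene$truth_scratch_mask, to8),
                   file.path(dir, "truth_scratch_mask.tif"), 8L)
  jsonlite::write_json(list(params = unclass(p),
                            time_min = scene$time_min,
                            speckle_centers = lapply(scene$truth_speckle_centers,
                                                     function(m) if (is.null(m)) NULL
                                                     else as.data.frame(m))),
                       file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  paths
}
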
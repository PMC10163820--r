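# Shared synthetic-world fixtures. The test world uses a coarser pixel scale
# (1 um/px) and a smaller field of view than the paper's 2048-px sCMOS
# frames so the whole suite runs in minutes; all biological/optical
# parameters (cell size, ratio gradient, vignetting, noise) keep their
# stated values. Expensive fixtures are computed once per run and cached.

.fixtures <- new.env(parent = emptyenv())

test_scene_params <- function(...) {
  defaults <- list(image_height = 160L, image_width = 280L, pixel_scale = 1,
                   scratch_half_width = 30, cell_diameter_mean = 22.5,
                   edge_ratio = 1.3, baseline_ratio = 1.0, gradient_length = 30,
                   vignetting_amplitude = 0.2, n_speckles = 20L, noise_sd = 25,
                   n_frames = 1L, seed = 11L)
  do.call(scene_params, utils::modifyList(defaults, list(...)))
}

cached <- function(key, expr) {
  if (!exists(key, envir = .fixtures)) assign(key, expr, envir = .fixtures)
  get(key, envir = .fixtures)
}

get_test_scene <- function() cached("scene", generate_scene(test_scene_params()))

get_test_analysis <- function() cached("analysis", analyze_scene(get_test_scene()))
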
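# fretscratch

Spatially resolved FRET-biosensor analysis of collectively migrating cell
monolayers, in R.

## The problem

Intramolecular FRET biosensors for Rho-family GTPases (RhoA, Rac1) report
activity as the emission ratio of an acceptor (YFP) to a donor (CFP)
fluorophore. In a wound-healing ("scratch") assay, a confluent epithelial
monolayer is scratched and imaged in two channels over hours; the question is
how GTPase activity is organised in space — are the *leader cells* at the
wound edge (the first ~25 µm, roughly one MCF7 cell diameter) signalling
differently from *followers* deeper in the monolayer, and does a genetic
perturbation change that?

Getting a trustworthy answer from raw two-camera fluorescence frames requires
a chain of corrections and measurements, each of which this package
implements as a tested, reusable component:

1. **Dark-state correction** — per-pixel median over frames captured without
   illumination, subtracted from every image.
2. **Channel alignment** — rigid integer translation of the acceptor camera
   onto the donor by Hann-windowed, regularised phase correlation, with a
   crop to the common overlap.
3. **Scaled background subtraction** — empty-well media frames (per-pixel
   median over 8 frames) scaled so their median over the image's own
   background pixels (log-transform + Otsu) matches, then subtracted.
4. **Segmentation** — cells vs background/scratch from the two-channel sum
   image: subtract the dimmest 0.5% level, floor at 20 counts, log, rescale
   to the 1st–90th percentile window, Otsu threshold, morphological cleanup
   (close, drop objects < 50 px, fill small holes); the cell mask is the
   inverse of the background mask, and the scratch is the background's
   largest connected component.
5. **Speckle rejection** — bright debris puncta are found by sharpening the
   sum image with an α = 0.9 Laplacian, thresholding at the first sparse
   (≤ 9-pixel) histogram bin past the bulk, then dropping components larger
   than 300 px or with eccentricity > 0.6 (elongated membrane tracings).
6. **Ratio images** — masked pixels become NaN in both channels, each channel
   is smoothed with a missing-value-aware Gaussian (σ = 2 px), the ratio
   R = YFP/CFP is formed and divided (exactly once) by a **flat-field ratio
   correction** built from unstimulated confluent monolayers (masked
   per-pixel median → 24 × 24-px block medians → Gaussian smooth, σ = 5
   blocks → bilinear resize).
7. **Spatial profiles** — the scratch edge is split into left/right
   perimeter masks (dilated 2 px), the cell mask is split by side, and each
   cell pixel gets its *quasi-euclidean geodesic distance* (axial step 1,
   diagonal √2, constrained to the cell mask) from its edge. Pixels are
   sorted into 5 µm bins; each bin's ratio is (mean acceptor)/(mean donor).
8. **Statistics** — wells are the replication unit: per-well bin means are
   averaged into group profiles (mean ± sem across wells) and compared
   between groups at chosen distances (5 µm, 100 µm) with a two-sided
   unpaired Welch t test.

Because raw microscopy of this kind is rarely deposited, the package includes
a first-class **synthetic scene generator**: ground-truthed two-channel
scratch scenes (hexagonal cells with membrane-enriched rims, an imposed
exponential activity gradient `R(d) = R_base + (R_edge − R_base)·exp(−d/λ)`,
acceptor vignetting, camera dark offset, noise, speckles, acellular gaps, and
scratch closure over time) plus every calibration input, so the entire
pipeline is testable end to end.

## Worked example

```r
library(fretscratch)

p <- scene_params(image_height = 160L, image_width = 280L, pixel_scale = 1,
                  scratch_half_width = 30, cell_diameter_mean = 22.5,
                  edge_ratio = 1.3, baseline_ratio = 1.0, gradient_length = 30,
                  vignetting_amplitude = 0.2, noise_sd = 25, n_speckles = 20L,
                  n_frames = 1L, seed = 11L)
scene <- generate_scene(p)
res   <- analyze_scene(scene)          # calibrate + analyse, in memory
wb    <- well_bin_means(res$profiles)  # one well, sides pooled
head(wb[, c("bin_lo_um", "bin_hi_um", "mean_ratio", "n_pixels")], 5)
#>   bin_lo_um bin_hi_um mean_ratio n_pixels
#> 1         0         5   1.269871     1985
#> 2         5        10   1.226481     1595
#> 3        10        15   1.192363     1582
#> 4        15        20   1.162226     1596
#> 5        20        25   1.137100     1586
```

The first bin (0–5 µm from the wound edge) reads 1.270 against a true value
of 1.276 for the bin (edge ratio 1.30 decayed over 0–5 µm): activity is
highest in the leader cells and decays toward the 100 µm bin (1.009 here,
true far field 1.01), recovering the imposed gradient. Group-level use:

```r
ctrl <- simulate_group_wells(p, n_wells = 10, group = "control")
aggregate_group_profile(ctrl, "control")          # mean ± sem per bin
compare_profiles_at_distance(ctrl, kd, 5)         # Welch t test at 5 µm
```

A file-based run (TIFF in, CSV/TIFF/JSON out) goes through
`run_well_timelapse(pipeline_config(...))` or the CLI wrapper
`inst/cli/fret-scratch` with subcommands `simulate`, `calibrate`, `analyze`,
`aggregate`, `report` (see `fret_cli()`).

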
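---
title: "Methods: spatial FRET ratio profiling of scratch-wound migration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spatial FRET ratio profiling of scratch-wound migration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(fretscratch)
```

## The measurement model

A ratiometric FRET biosensor reports GTPase activity as the per-pixel ratio
of acceptor (YFP) to donor (CFP) emission. Ratioing cancels expression level
and optical path length, but three instrument effects survive it and must be
corrected before ratios can be compared across a field of view:

* a **camera dark offset** (additive, per pixel, per camera),
* **non-shared background** — media autofluorescence adds counts to both
  channels that do not scale with the sensor, biasing ratios wherever signal
  is low,
* a **spatial detection gradient** in the ratio channel (dichroic/illumination
  asymmetry between the two cameras), visible as a top-to-bottom ratio tilt.

The pipeline applies, in order: dark subtraction (per-pixel median of
unilluminated frames); rigid alignment of the acceptor camera onto the donor;
scaled empty-well background subtraction; segmentation and speckle masking;
missing-value-aware Gaussian smoothing of each channel; ratioing; and a
single division by the flat-field ratio-correction image. The spatial readout
is the mean bin ratio — (mean acceptor)/(mean donor) per 5 µm geodesic
distance bin from the wound edge, per side, frame, and well.

## Parameters that matter

| Parameter | Default | Units | Why |
|---|---|---|---|
| pixel_scale | 0.325 | µm/px | 20x objective with 6.5 µm sCMOS pixels; configuration, never inferred |
| frame_interval | 15 | min | acquisition cadence over a 12 h assay |
| analysis_times | 60, 360, 720 | min | profiles at 1, 6, 12 h of migration |
| block_size / correction_sigma | 24 px / 5 blocks | — | flat-field block-median grid and its smoothing |
| ratio smooth_sigma | 2 | px | channel smoothing before ratioing |
| bin_width | 5 | µm | distance bin width |
| edge dilation | 2 | px | guarantees scratch-edge/cell-mask overlap |
| dim_fraction / intensity_floor | 0.5% / 20 | — / counts | pedestal removal before the log transform |
| rescale percentiles | 1st–90th | — | contrast window of the log image |
| min_object_area | 50 | px | background-mask object cleanup |
| speckle alpha / bin rule / max area / eccentricity | 0.9 / ≤9 px / 300 px / 0.6 | — | bright-punctum detection and shape filtering |

Welch's t test (two-sided, unpaired) compares *well-level* bin means:
frames within a well are averaged first and sides pooled by pixel-weighted
sums, because wells, not frames or pixels, are the independent replicates.

## The synthetic world

`generate_scene()` renders what the assay looks like to the analysis code —
not cell biology. It emulates: a confluent monolayer of ~22.5 µm cells
(jittered hexagonal lattice) with membrane-enriched rims (the biosensors are
plasma-membrane-associated, and bright rims are exactly what the speckle
filter's eccentricity branch must *not* flag); a north–south scratch with
wavy edges that narrows at `closure_speed` per edge; an imposed activity
gradient `R(d) = R_base + (R_edge − R_base)·exp(−d/λ)` with the activity
highest at the wound edge; linear top-to-bottom acceptor vignetting; camera
dark offset; additive Gaussian noise (sCMOS regime — Poisson shot noise is
deliberately not modelled); rare bright puncta at recorded coordinates; and
a few percent of small acellular gaps. Matching calibration inputs (dark,
empty-well, unscratched-monolayer stacks) come from
`generate_support_frames()`.

Two generator choices deserve justification:

* **Acellular gaps** (`gap_fraction`, default 2%). A perfectly sealed
  synthetic monolayer contains *no* true background pixel, so the Otsu-based
  background mask lands on dim cell interiors and the empty-well scale
  factor explodes (we measured ~25x over-subtraction, which distorts the
  calibration ratio gradient by ~60%). Real confluent monolayers always
  carry small acellular gaps; modelling them restores the genuine media
  pixels that anchor the background scaling, with scale factors near 1.
* **Exponential gradient with λ = 30 µm.** The source observation is only
  that activity peaks within ~5–10 µm of the edge; the exponential form and
  its length are configurable, and the tests treat them as ground truth to
  recover, not as biology.
* **Inter-well variability** (`simulate_group_wells(well_effect_sd = ...)`).
  A per-well log-normal factor on the true ratio field models the
  well-to-well spread every ratiometric experiment shows. It matters for the
  knockdown-mirror test: with technically identical wells, 24 replicates
  detect even the 0.007 residual difference between exponential tails at
  100 µm — a *correct* detection that would break the mirror's "equal
  far-field" premise. The mirror world therefore uses λ = 20 µm (tail
  < 2·10⁻³ at 100 µm, at least as consistent with an edge-localised
  activity peak) and a 5% well effect; the parameter-recovery test keeps
  λ = 30 µm and zero well effect, because there the question is pipeline
  accuracy, not biological inference.

What a green test establishes: that the *pipeline* recovers imposed spatial
structure through realistic instrument effects. What it does not establish:
anything about real cells — the generator has no motility, no photobleaching,
no optical PSF, and its noise is Gaussian.

## Numerical choices

* **Otsu's threshold** is computed exactly over the empirical value
  distribution (every distinct value a candidate cut), ties broken toward
  the lowest threshold; constant inputs are rejected. The acceptance suite
  checks exact agreement of the class split with an exhaustive search.
* **Quasi-euclidean geodesic distance** is Dijkstra over the cell mask with
  steps {1, √2}, in C++ with a binary heap; the acceptance oracle is an
  independent linear-scan Dijkstra in R (agreement < 1e-9).
* **Missing-aware smoothing** is normalised convolution: Gaussian-smooth the
  zero-filled image and the availability mask, divide, and re-impose the
  missing set. A plain Gaussian over NaN-bearing images would erase a halo
  around every mask, which the recipe clearly does not intend. Output pixels
  never gain values inside masked areas.
* **Flat-field smoothing** of the block-median grid uses odd-reflection
  (anti-symmetric) padding with the kernel radius clamped to the pad width,
  so every output pixel sees a complete symmetric kernel. This makes linear
  illumination ramps exact fixed points of the smoother; with the default
  renormalising edge handling, a 20% gradient was flattened enough at the
  borders to fail its own 5-fold-reduction requirement. Bilinear resize with
  linear extrapolation past the outer block centres, for the same reason.
* **Speckle threshold.** The histogram of positive Laplacian-sharpened
  values is scanned *upward from its modal bin* for the first bin with ≤ 9
  pixels; scanning from absolute zero would stop in the empty region below
  the image bulk and threshold everything. The threshold is derived on the
  sharpened image and applied to the sum image: sharpening amplifies compact
  bright objects ~2–3x, so a tail threshold calibrated on sharpened values
  clears every membrane-rim pixel in sum-image units while true puncta stay
  far above it.
* **Phase correlation** uses a Hann window and regularised whitening
  (`cp / (|cp| + 0.01·mean|cp|)`). Pure whitening is exact for broadband
  images but fails on smooth images with non-circular shifts, where
  noise-dominated high frequencies outvote the peak.
* **Hole filling** in the background mask is capped at `min_object_area`:
  "small holes" are filled, but a large bright island fully surrounded by
  background is not silently converted to background.
* **Degenerate inputs**: constant images are rejected by Otsu; an empty
  background mask rejects background scaling; a scratch touching a lateral
  border yields a single edge with a warning; zero-variance Welch groups get
  a machine-epsilon variance guard and a warning rather than failure.
* **Correction single-application.** The flat-field divides the signal
  exactly once on every path: ratio images carry a
  `ratio_correction_applied` counter, and `bin_fret_profile()` refuses
  channels already corrected. (The recipe mentions applying the correction
  both at the ratio stage and to the acceptor at binning; the two are
  algebraically equivalent, so each output path applies it once.)

## Scaling in the tests

The source imaging used 2048-px sCMOS frames at 0.325 µm/px. The test and
acceptance worlds use 80–240-px frames at 1 µm/px so the suite runs in
minutes; cell diameter, gradient parameters, vignetting, noise and all
segmentation constants keep their stated values. The Welch power mirror runs
40 replicates instead of 100 (thresholds applied at the same rates), and the
acceptance script condenses the same checks further. Because the flat-field
smoother preserves linear ramps exactly, the paper-scale `correction_sigma
= 5` blocks remains valid on small grids.

## Known limitations

* Alignment is integer-pixel rigid translation only (no rotation, no
  subpixel refinement); the spec's cited alignment algorithm is not
  recoverable, and phase correlation is the stated substitute.
* No spectral bleed-through or photobleaching correction — not part of the
  recipe being reproduced.
* The TIFF layer reads only what the package writes (uncompressed,
  little-endian, grayscale 8/16-bit unsigned or 32-bit float); anything else
  is rejected loudly. No R TIFF reader was available in the target
  environment, and this subset round-trips with standard tools.
* The speckle histogram binning rule (256 uniform bins over the positive
  sharpened values) is a configuration default; the original bin width is
  unstated.
* With `gap_fraction = 0` the background-scaling step is undefined in
  principle (no true background); the generator default keeps it positive.
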
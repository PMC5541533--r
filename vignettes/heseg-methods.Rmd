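---
title: "Quantifying liver inflammation from high-variance H&E images: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying liver inflammation from high-variance H&E images: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Histological sections of inflamed liver tissue, stained with haematoxylin
and eosin (H&E), carry quantitative information that pathology scoring
reduces to ordinal grades: the number, extent and cellular density of
inflammatory foci, and the density of hepatocyte nuclei in the surrounding
parenchyma. Field-collected material — necropsy samples fixed for months
before processing — adds severe, spatially varying differences in staining
intensity, contrast and luminosity, plus physical tears, so any segmentation
has to be robust to image-level variance rather than tuned to one pristine
slide.

`heseg` implements a two-magnification analysis:

* **Widefield** (≈ 2 × 3 mm fields): every pixel is classified as
  inflammatory or not, and as vein lumen or not, so that the number, sizes
  and spatial arrangement of inflammatory zones can be measured per image.
* **Narrowfield** (≈ 0.8 × 1.2 mm fields centred on one focus): the contour
  and area of the central inflammatory focus are extracted, and individual
  nuclei — including overlapping ones — are separated and counted for
  density estimation.

A third component provides the validation algebra used to compare any two
binary segmentations of the same image (algorithm vs. human operator, or
algorithm vs. synthetic ground truth), and a robust regression for
cohort-level agreement.

## The widefield model

The physical model is Beer–Lambert light absorption. With transmitted
intensity $I_c$ in channel $c$ and unabsorbed illumination $I^0_c$, the
optical density $\mathrm{OD}_c = -\log_{10}(I_c / I^0_c)$ is linear in the
amounts of absorbing stain, so for stain concentrations
$(c_H, c_E, c_U)$ and a matrix $M$ whose rows are the unit OD vectors of
haematoxylin, eosin and an unstained residual,
$\mathrm{OD} = (c_H, c_E, c_U)\, M$. `separateStains()` inverts this 3×3
system per pixel (colour deconvolution); `calibrateStainMatrix()` estimates
the H and E rows from single-stain slides as normalized mean OD vectors over
stained pixels, with the residual row their normalized cross product.

Two decisions here are the package's own:

* **White reference.** The unabsorbed illumination is estimated as the
  per-channel *maximum* intensity. Unstained lumina are the brightest
  legitimate class in these slides; a trimmed percentile (a common
  dust-robust choice) lands inside their intensity distribution under
  luminosity gradients and clips their optical densities to zero. A stray
  hot pixel only shifts all ODs by an additive constant, which the local
  thresholds downstream ignore. The reference is config-exposed.
* **Unstained ratio guard.** Vein detection uses $U / (E + \varepsilon)$
  with $\varepsilon = 0.02$ on the concentration scale. With a tiny guard,
  zero-eosin pixels (bare glass, tears) produce ratios of order $10^4$ that
  dominate the subsequent max-normalization; a guard on the scale of real
  concentrations bounds the ratio physically.

Inflammatory zones are nuclear-density structures: immune cells carry a
much higher nucleus-to-cytoplasm ratio than hepatocytes, so a focus is a
region of elevated haematoxylin. The segmentation chain on the H channel is

1. contrast-limited adaptive histogram equalization (CLAHE; removes global
   illumination gradients; tile 256 px, clip limit 2),
2. Gaussian smoothing, σ = 5 px — wide enough to merge the per-nucleus
   bumps of a dense focus into a plateau while isolated hepatocyte nuclei
   stay as separate bumps,
3. a contrast sigmoid (cutoff 0.5, gain 8),
4. Gaussian-weighted adaptive thresholding (block 301 px, offset 0.07):
   a pixel is white when it exceeds its neighbourhood mean by the offset,
   so smooth regional trends never threshold,
5. removal of connected components below 250 px — this is the step that
   discards isolated single nuclei, which do threshold locally,
6. an 11-px maximum filter and a closing with a 15-px disc, which
   consolidate each focus into one compact zone.

Vein lumina are segmented from the unstained ratio by σ = 11 px smoothing,
adaptive thresholding (same block, offset 0.03), a 25-px-disc closing, and
removal of components of 200 px or fewer — the rule that drops thin tears
while keeping lumina.

All pixel-denominated parameters refer to the quarter-resolution analysis
scale (images are area-average downscaled by 2 per axis before analysis).
The thresholds and tile/block sizes are the package's defaults where no
published value exists; every one of them is exposed in
`pipelineConfig()`.

Global preprocessing (`preprocessGlobal()`) applies a luminance sigmoid,
saturation gain, light denoising, an unsharp mask, and hue-targeted edits
(yellows/oranges brightened and desaturated; blues/purples saturated and
darkened). The defaults are deliberately gentle: strong stylistic hue edits
are nonlinear in RGB and distort the Beer–Lambert mixing model that colour
deconvolution inverts — in our measurements an aggressive default compressed
the focus-to-background haematoxylin contrast from 1.8× to 1.45×. A
luminance sigmoid gain must exceed 4 to be contrast-expanding at its
midpoint (its slope there is gain/4); the default is 5.

## The narrowfield model

At narrowfield resolution nuclei are tens of pixels across, so the red
channel alone separates them: haematoxylin-stained chromatin is dark in
red, while cytoplasm, vessels and background are red-bright.
`binarizeNuclei()` applies a sigmoid, an adaptive threshold with
below-local-mean polarity, a closing of the *non-nucleus* phase with a
3-px disc (removing pinholes and smoothing outlines), then removes nucleus
components of 100 px or fewer.

The central focus is localized by combining two cues computed from the
binary nucleus mask:

* **density** — a strong Gaussian blur of the mask (σ = 61 px at full
  frame), i.e. the local areal fraction of nuclear material;
* **texture** — base-2 local Shannon entropy in a 3-px-radius disc,
  blurred with σ = 75 px: high where nuclear boundaries are dense and
  irregularly packed.

Each map is min–max normalized and the two are combined by their
**geometric mean**. The product was considered first (it vanishes wherever
either cue is absent), but its quadratic roll-off at the focus margin pulls
the subsequent Otsu iso-contour 15–30 px inside the focus envelope,
biasing the area fraction by −0.04 to −0.06 on synthetic scenes; the
geometric mean is monotone in the product, preserves each cue's normalized
scale, and puts the boundary at the density midpoint (measured bias within
±0.02). Product and min remain selectable via `narrowfieldParams(combine=)`.

The two saliency sigmas measure structure at the *focus* scale, so they
are specified at the full 5184-px frame and scaled by
`frameScale = width / 5184` on smaller fields of view; nucleus-scale
parameters (closing disc, entropy disc, component cut-off, peak distance)
are resolution-native and never scaled.

`extractFocusContour()` applies Otsu's threshold to the saliency map and
selects the most central and largest bright object: the connected component
containing the image centre, else the component (among the three largest)
whose centroid is nearest the centre. Holes are filled and the outer
boundary is traced by marching squares on a zero-padded copy of the
component mask, so the contour is closed even when the object touches the
frame edge. A degenerate (constant) saliency map yields an explicit
"no focus" value, never a silent zero.

Overlapping nuclei are separated by the classic distance-transform
watershed: the Euclidean distance transform of the nucleus mask (edge
whites at zero — the transform reports distance-to-background minus one),
one seed per distance peak with a minimum separation of 7 px (≈ an immune
nucleus radius), and priority flooding of the negated distance surface.
Two partially overlapping nuclei form twin distance peaks and are split
along the neck; any component left without a peak is seeded at its distance
maximum so the labels always partition the mask.

## Validation algebra

For an algorithm mask $I$ and operator mask $T$ over $S$ pixels:

* $M_P = |\,(1-T) \otimes I\,| / S$ — false-positive pixel fraction,
* $M_N = |\,T \otimes (1-I)\,| / S$ — false-negative pixel fraction,
* $M = M_P + M_N$ — total mislabelled fraction (the identity is exact by
  construction and asserted in the tests),

where $\otimes$ is the pixelwise conjunction. At the zone level, with
zones the connected components (8-connected by default, configurable):

* $F_A$ (validity): the fraction of algorithm zones sharing ≥ 80 % of
  their pixels with the operator mask,
* $F_G$ (recall): the fraction of operator zones ≥ 50 % covered by the
  algorithm mask (the coverage threshold is configurable; one quarter is a
  documented variant).

When a mask has no zones the corresponding score is *undefined* and
reported as missing — never coerced to 0 or 1 — mirroring the exclusion of
un-annotatable images from operator comparisons.

Cohort agreement is summarized by robust linear regression:
M-estimation with Huber's weighting (tuning constant 1.345, via
`MASS::rlm`), $R^2$ reported as the squared Pearson correlation (no
standard $R^2$ exists for M-estimation), and 95 % percentile bootstrap
intervals over case resampling (1000 replicates, seed mandatory).

Physical conversions use the printed fields of view: at 3456 × 5184 px,
a 2 × 3 mm widefield pixel covers 0.335 µm² and a 0.8 × 1.2 mm narrowfield
pixel 0.0536 µm². Nuclear density is reported per 1000 µm².

## The synthetic scene generator

No annotated slides ship with the package, so every end-to-end claim is
validated on synthetic scenes with exact ground truth
(`generateScene()`). The generator renders, at the *native* pixel
resolutions of the two magnifications (0.579 µm/px widefield capture,
0.231 µm/px narrowfield):

* eosin-toned parenchyma with smooth spatial texture;
* vein lumina as unstained ellipses (low E, neutral residual absorption);
* hepatocyte nuclei as a spatial Poisson process (default
  1.5 nuclei / 1000 µm², radius 4.5 µm) excluded from lumina;
* inflammatory foci as discs in which immune nuclei (half the hepatocyte
  radius — the higher nucleus-to-cytoplasm ratio) are placed at 18× the
  background rate. That multiplier comes from packing arithmetic, not from
  tuning: dense, non-confluent immune packing of ≈ 45 % areal fill at the
  15 % maximum pairwise-overlap constraint implies
  rate × multiplier ≈ 28 / 1000 µm², i.e. ≈ 18 at the background rate.
  Ground truth for a focus is its placement disc dilated by the immune
  nucleus radius (the extent of nuclear material);
* concentrations rendered to RGB through the Beer–Lambert model with the
  default stain matrix. The residual (U) row used for rendering is neutral
  grey rather than the H×E cross product: the cross product has negative
  OD components, which would transmit intensities above the white point
  and break exact round trips.

Degradation (`degradationSpec()`) is layered on the rendered image only —
ground truth is invariant: a ±15 % linear luminosity gradient in a random
direction, per-channel stain-intensity shifts applied as OD gains
(0.9–1.1), additive Gaussian noise (sd 0.02), thin white tear polylines
(one per widefield scene), and slight defocus blur (σ 0.3). One seeded
generator drives the whole scene; the same spec is byte-reproducible.

Reduced fields of view (default 768 × 1152 widefield capture,
512 × 768 narrowfield) keep the 20-scene validation suites at desk scale;
because resolution is native, all pixel-denominated chain parameters apply
unchanged, and only the two frame-scale saliency sigmas are scaled as
described above.

**What passing these suites does and does not show.** The generator
reproduces the *geometry and radiometry* the pipelines exploit — stain
mixing, nuclear crowding, lumina, gradients, tears — but not real
chromatin texture, lobular architecture, sinusoids, or focus shapes more
complex than discs, and its variance model is far milder than real
overfixed field material. Recovery numbers on the suites (mislabelled
fractions near 0.01, perfect zone validity) are therefore upper bounds on
clean-data behaviour and a regression harness, not predictions of
performance on real slides, where published operator-agreement figures are
an order of magnitude looser.

## Numerical conventions and degenerate inputs

* Rasters are base R matrices/arrays in [0, 1], indexed (row i, column j);
  masks are 0/1; connectivity defaults to 8-connected foreground
  (4-connected background for hole filling).
* Otsu's threshold is the exhaustive between-class-variance maximizer over
  midpoints of consecutive distinct values, ties resolved toward the lowest
  threshold; a constant image is an error.
* Peak detection resolves plateaus deterministically: candidates are sorted
  by decreasing height then raster order, and greedily accepted under the
  minimum-distance constraint. The watershed's priority queue breaks
  elevation ties first-in-first-out, so all outputs are byte-reproducible.
* Closing pads with background by the disc radius, making it extensive,
  idempotent and increasing; those laws are asserted on random masks.
* The distance transform of an all-white mask is an error under
  normalization (no background exists); an all-black mask maps to zeros.
* `huberFit` requires n ≥ 3 and non-degenerate x; bootstrap resamples with
  zero x-variance are dropped from the percentile interval.
* The 20-scene suites use seeds `baseSeed + 0 … 19`; scene generation and
  degradation consume a private RNG stream and restore the caller's RNG
  state.

## Known limitations

* Stain deconvolution assumes the calibrated (or default) matrix applies
  to the whole image; no per-slide stain normalization is attempted.
* The adaptive-threshold blocks (301 px widefield, 101 px narrowfield)
  assume structures smaller than the block; a focus or lumen approaching
  the block size loses contrast against its own local mean.
* Vein/tear discrimination is purely size-based, per the published rule;
  a wide tear would be labelled a vein.
* The focus contour is a single object; multifocal narrowfield images
  yield the most central focus only.
* Operator annotations are supported as masks or polygon tables for
  validation, but no annotation interface is provided.
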
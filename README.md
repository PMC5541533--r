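# heseg

Robust, fully automated extraction of quantitative structural information
from haematoxylin & eosin (H&E) stained liver histology — built for
high-variance material (field necropsies, overfixed tissue, uneven staining
and illumination) where per-slide manual tuning is not an option.

## What it measures

**Widefield images (≈ 2 × 3 mm):** every pixel is labelled inflammatory or
not, and vein lumen or not. Inflammatory foci are regions of dense immune
nuclei, detected from the haematoxylin channel after Beer–Lambert colour
deconvolution; vein lumina come from the unstained/eosin concentration
ratio, with thin tears rejected by a component-size rule. Output: binary
masks, a per-zone table (area in px and µm², centroid, bounding box), and a
blue/green overlay.

**Narrowfield images (≈ 0.8 × 1.2 mm, one focus per frame):** nuclei are
binarized from the red channel; the central inflammatory focus is contoured
by thresholding an entropy × density saliency map; overlapping nuclei are
split by a marker-seeded watershed on the Euclidean distance transform and
counted for nuclear density (per 1000 µm²).

**Agreement statistics** between an algorithm mask `I` and an operator (or
ground-truth) mask `T` over `S` pixels:

- pixel level: `M_P = |(1−T)⊗I|/S` (false positives),
  `M_N = |T⊗(1−I)|/S` (false negatives), `M = M_P + M_N`;
- zone level: `F_A` — fraction of algorithm zones sharing ≥ 80 % of their
  pixels with operator zones (validity); `F_G` — fraction of operator zones
  ≥ 50 % covered by the algorithm (recall). Undefined scores (no zones) are
  reported as missing, never 0 or 1;
- cohort level: robust regression (Huber M-estimation, k = 1.345) with
  squared Pearson `R²` and 95 % percentile-bootstrap intervals.

Because no annotated slides are distributable, the package ships a seeded
synthetic H&E scene generator (`generateScene()`) producing eosin-toned
parenchyma, hepatocyte and immune nuclei, vein lumina, luminosity
gradients, stain-intensity shifts, noise and tears — with exact ground-truth
masks and centroids — so the entire pipeline is testable end to end.

## Worked example

```r
library(heseg)

# a synthetic widefield scene with known ground truth
spec  <- sceneSpec("widefield", seed = 3)
scene <- generateScene(spec)
scene
#> SyntheticScene 768 x 1152 (widefield): 1144 nuclei, focus 9.0%, veins 2.7% of pixels

# full pipeline: preprocess, downscale, deconvolve, segment
res <- widefieldPipeline(sceneImage(scene), stainMat = spec$stainMatrix,
                         pixelAreaUm2 = spec$pixelSizeUm^2)
res
#> WidefieldResult 384 x 576: 2 inflammatory zones (8.6% of pixels), veins 3.2%

# score against the downscaled ground truth
gt <- matrix(as.integer(downscaleQuarter(focusMask(scene) + 0) >= 0.5), 384)
pixelScores(inflammationMask(res), gt)
#> PixelScores: M_P = 0.0017, M_N = 0.0061, M = 0.0078
zoneAgreement(inflammationMask(res), gt)
#> ZoneAgreement: F_A = 1.000 (2/2), F_G = 1.000 (2/2)
```

`M` is the fraction of all pixels labelled differently by the algorithm and
the truth (here 0.8 %); `F_A = 1` says every detected zone lies ≥ 80 %
inside true foci; `F_G = 1` says every true focus is ≥ 50 % recovered.

On the narrowfield side:

```r
nspec <- sceneSpec("narrowfield", seed = 3)
nsc   <- generateScene(nspec)
cfg   <- pipelineConfig()
cfg$narrowfield$params <- narrowfieldParams(frameScale = 768 / 5184)
nres  <- narrowfieldPipeline(sceneImage(nsc), cfg,
                             pixelAreaUm2 = nspec$pixelSizeUm^2)
nres
#> NarrowfieldResult: 152 nuclei; focus area fraction 0.254
mean(focusMask(nsc))        # ground-truth fraction
#> [1] 0.2619
nrow(centroids(nsc))        # true nucleus count
#> [1] 152
```

A command-line wrapper with subcommands `widefield`, `narrowfield`,
`validate`, `synth` and `calibrate` is installed at `exec/heseg`
(exit codes: 0 success, 2 configuration, 3 I/O, 4 validation). All chain
parameters live in one YAML-serializable configuration
(`pipelineConfig()`, `loadConfig()`, `saveConfig()`); unknown keys are
rejected.

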
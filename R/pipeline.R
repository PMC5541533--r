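# File-level runners tying the pipelines together, plus the seeded synthetic
# evaluation suites used to validate the whole workflow end to end.

.logStage <- function(verbose, fmt, ...) {
  if (verbose) message(sprintf(fmt, ...))
}

#' Run the widefield pipeline on an image file
#'
#' Reads the image, runs \code{\link{widefieldPipeline}}, and writes the
#' inflammation and vein masks (0/255 PNG), the zone table (CSV) and a
#' blue/green overlay PNG into \code{outDir}. Every stage and parameter in
#' use is logged when \code{verbose}.
#'
#' @param imagePath input RGB image (PNG/TIFF/JPEG), capture scale.
#' @param config a \code{\link{pipelineConfig}}.
#' @param outDir output directory (created if missing).
#' @param stainMatrixFile optional YAML config file whose stain matrix
#'   overrides the default.
#' @param verbose log stages via \code{message}.
#' @return the \linkS4class{WidefieldResult}, invisibly.
#' @export
runWidefield <- function(imagePath, config = pipelineConfig(), outDir,
                         stainMatrixFile = NULL, verbose = TRUE) {
  img <- readImageFile(imagePath)
  if (length(dim(img)) != 3L)
    .stopConfig("widefield input must be a colour image")
  if (!is.null(stainMatrixFile)) {
    config$stains$matrix <- loadConfig(stainMatrixFile)$stains$matrix
  }
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  wr <- if (identical(config$stains$whiteRef, "auto")) NULL
        else config$stains$whiteRef
  .logStage(verbose, "widefield: %s (%d x %d)", imagePath,
            dim(img)[1], dim(img)[2])
  .logStage(verbose, "  preprocess: %s",
            paste(names(config$widefield$preprocess),
                  unlist(config$widefield$preprocess), sep = "=",
                  collapse = " "))
  res <- widefieldPipeline(img, config, whiteRef = wr)
  .logStage(verbose, "  inflammation: %s",
            paste(names(config$widefield$inflammation),
                  unlist(config$widefield$inflammation), sep = "=",
                  collapse = " "))
  .logStage(verbose, "  veins: %s",
            paste(names(config$widefield$veins),
                  unlist(config$widefield$veins), sep = "=", collapse = " "))
  .logStage(verbose, "  %d zones found", length(zones(res)))
  writeMaskFile(inflammationMask(res), file.path(outDir, "inflammation.png"))
  writeMaskFile(veinMask(res), file.path(outDir, "veins.png"))
  writeZonesCsv(zones(res), file.path(outDir, "zones.csv"), res@pixelArea)
  writeOverlayPng(downscaleQuarter(preprocessGlobal(
    img, config$widefield$preprocess)),
    inflammationMask(res), veinMask(res),
    file.path(outDir, "overlay.png"))
  invisible(res)
}

#' Run the narrowfield pipeline on an image file
#'
#' Writes the nucleus mask (PNG), nucleus label map (16-bit PNG), centroid
#' CSV, focus contour CSV and GeoJSON-like polygon into \code{outDir}.
#'
#' @param imagePath input RGB image at narrowfield resolution.
#' @param config a \code{\link{pipelineConfig}}.
#' @param outDir output directory.
#' @param verbose log stages.
#' @return the \linkS4class{NarrowfieldResult}, invisibly.
#' @export
runNarrowfield <- function(imagePath, config = pipelineConfig(), outDir,
                           verbose = TRUE) {
  img <- readImageFile(imagePath)
  if (length(dim(img)) != 3L)
    .stopConfig("narrowfield input must be a colour image")
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  .logStage(verbose, "narrowfield: %s; params: %s", imagePath,
            paste(names(config$narrowfield$params),
                  unlist(config$narrowfield$params), sep = "=",
                  collapse = " "))
  res <- narrowfieldPipeline(img, config)
  ns <- nucleusSet(res)
  .logStage(verbose, "  %d nuclei; focus %s", nucleusCount(ns),
            if (isEmptyFocus(focusContour(res))) "not found"
            else sprintf("area fraction %.4f",
                         focusAreaFraction(focusContour(res))))
  writeMaskFile(nucleusMask(res), file.path(outDir, "nuclei.png"))
  writeLabelTiff(labelMap(ns), file.path(outDir, "nucleus_labels.tiff"))
  writeCentroidsCsv(ns, file.path(outDir, "centroids.csv"))
  writeContourCsv(focusContour(res), file.path(outDir, "focus_contour.csv"))
  writeContourGeoJson(focusContour(res),
                      file.path(outDir, "focus_contour.geojson"))
  invisible(res)
}

#' Validate an algorithm mask against an operator mask
#'
#' Computes the pixel scores and zone agreement for one image pair and, when
#' \code{outPath} is given, appends/writes a one-row CSV: m_p, m_n, m, f_a,
#' f_g and the zone counts. Undefined agreement scores are written as empty
#' fields, never as 0 or 1.
#'
#' @param algoMaskPath,truthMaskPath mask rasters (any nonzero pixel is
#'   white).
#' @param config a \code{\link{pipelineConfig}}.
#' @param outPath optional output CSV path.
#' @return list with elements \code{scores} (\linkS4class{PixelScores}) and
#'   \code{agreement} (\linkS4class{ZoneAgreement}).
#' @export
runValidate <- function(algoMaskPath, truthMaskPath,
                        config = pipelineConfig(), outPath = NULL) {
  i <- readMaskFile(algoMaskPath)
  t <- readMaskFile(truthMaskPath)
  .assertSameShape(i, t)
  ps <- pixelScores(i, t)
  za <- zoneAgreement(i, t, config$metrics$validityThreshold,
                      config$metrics$recallThreshold,
                      config$metrics$connectivity)
  if (!is.null(outPath)) {
    pf <- pixelFractions(ps); ag <- agreementScores(za); ct <- zoneCounts(za)
    df <- data.frame(m_p = pf[["mP"]], m_n = pf[["mN"]], m = pf[["m"]],
                     f_a = ag[["fA"]], f_g = ag[["fG"]],
                     validated = ct[["validated"]],
                     algorithm_zones = ct[["algorithmZones"]],
                     recalled = ct[["recalled"]],
                     operator_zones = ct[["operatorZones"]])
    utils::write.csv(df, outPath, row.names = FALSE, na = "")
  }
  list(scores = ps, agreement = za)
}

#' Calibrate a stain matrix from single-stain image files
#'
#' @param hOnlyPath,eOnlyPath images of slides stained by haematoxylin only /
#'   eosin only.
#' @param outPath optional YAML path; the calibrated matrix is written in
#'   the configuration's stain-matrix format.
#' @param odFloor minimum OD magnitude for a pixel to enter calibration.
#' @return the 3x3 stain matrix.
#' @export
runCalibrate <- function(hOnlyPath, eOnlyPath, outPath = NULL,
                         odFloor = 0.15) {
  h <- readImageFile(hOnlyPath)
  e <- readImageFile(eOnlyPath)
  if (length(dim(h)) != 3L || length(dim(e)) != 3L)
    .stopConfig("calibration images must be colour images")
  m <- calibrateStainMatrix(h, e, odFloor = odFloor)
  if (!is.null(outPath))
    yaml::write_yaml(list(stains = list(matrix = .configToPlain(m))),
                     outPath)
  m
}

#' Generate and write synthetic scenes
#'
#' Writes, for each scene: the rendered image (PNG), ground-truth focus and
#' vein masks (PNG), nucleus centroids (CSV) and the generating spec (YAML),
#' plus a manifest listing the seeds for regeneration.
#'
#' @param kind "widefield" or "narrowfield".
#' @param seeds integer vector of scene seeds.
#' @param outDir output directory.
#' @param ... further arguments to \code{\link{sceneSpec}}.
#' @return invisible list of the generated \linkS4class{SyntheticScene}s.
#' @export
runSynth <- function(kind, seeds, outDir, ...) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  scenes <- lapply(seeds, function(s) {
    spec <- sceneSpec(kind = kind, seed = s, ...)
    scene <- generateScene(spec)
    base <- file.path(outDir, sprintf("%s_seed%03d", kind, s))
    writeImageFile(sceneImage(scene), paste0(base, "_image.png"))
    writeMaskFile(focusMask(scene), paste0(base, "_focus_mask.png"))
    writeMaskFile(veinMask(scene), paste0(base, "_vein_mask.png"))
    cent <- centroids(scene)
    utils::write.csv(data.frame(nucleus_id = seq_len(nrow(cent)),
                                i = cent[, 1] - 1, j = cent[, 2] - 1,
                                type = scene@nucleusType),
                     paste0(base, "_centroids.csv"), row.names = FALSE)
    sp <- sceneSpecOf(scene)
    sp$stainMatrix <- .configToPlain(sp$stainMatrix)
    sp$degradation <- unclass(sp$degradation)
    yaml::write_yaml(sp, paste0(base, "_spec.yaml"))
    scene
  })
  writeLines(c(sprintf("kind: %s", kind),
               sprintf("seeds: %s", paste(seeds, collapse = " "))),
             file.path(outDir, "manifest.txt"))
  invisible(scenes)
}

# Downscale a ground-truth mask to analysis scale by 2x2 majority.
.downscaleMask <- function(mask) {
  .asIntMask((downscaleQuarter(mask + 0.0) >= 0.5) + 0L)
}

#' Widefield synthetic evaluation suite
#'
#' Generates \code{nScenes} seeded widefield scenes under the default study
#' conditions, runs the full widefield pipeline on each (and on a clean,
#' degradation-free rendering of the same geometry), and scores the
#' inflammation mask against the downscaled ground truth.
#'
#' @param nScenes number of scenes.
#' @param baseSeed scene k uses seed \code{baseSeed + k - 1}.
#' @param config a \code{\link{pipelineConfig}}.
#' @return data frame with one row per scene: pixel scores (m_p, m_n, m),
#'   zone scores (f_a, f_g), the clean-render mislabelling m_clean and
#'   robustness delta_m = |m - m_clean|, and the algorithm/truth inflammatory
#'   area fractions.
#' @export
widefieldSuite <- function(nScenes = 20, baseSeed = 1,
                           config = pipelineConfig()) {
  rows <- lapply(seq_len(nScenes), function(k) {
    spec <- sceneSpec("widefield", seed = baseSeed + k - 1L)
    scene <- generateScene(spec)
    gt <- .downscaleMask(focusMask(scene))
    evalOne <- function(img) {
      res <- widefieldPipeline(img, config, stainMat = spec$stainMatrix,
                               pixelAreaUm2 = spec$pixelSizeUm^2)
      ps <- pixelFractions(pixelScores(inflammationMask(res), gt))
      za <- agreementScores(zoneAgreement(inflammationMask(res), gt))
      c(ps, za, areaAlgo = mean(inflammationMask(res)))
    }
    degraded <- evalOne(sceneImage(scene))
    cleanSpec <- spec
    cleanSpec$degradation <- cleanDegradation()
    clean <- evalOne(sceneImage(generateScene(cleanSpec)))
    data.frame(seed = spec$seed,
               m_p = degraded[["mP"]], m_n = degraded[["mN"]],
               m = degraded[["m"]],
               f_a = degraded[["fA"]], f_g = degraded[["fG"]],
               m_clean = clean[["m"]],
               delta_m = abs(degraded[["m"]] - clean[["m"]]),
               area_algo = degraded[["areaAlgo"]],
               area_truth = mean(gt))
  })
  do.call(rbind, rows)
}

#' Narrowfield synthetic evaluation suite
#'
#' Generates \code{nScenes} seeded narrowfield scenes, runs the narrowfield
#' pipeline, and compares the recovered focus area fraction, nucleus count
#' and nuclear densities with the exact ground truth.
#'
#' @param nScenes number of scenes.
#' @param baseSeed scene k uses seed \code{baseSeed + k - 1}.
#' @param config a \code{\link{pipelineConfig}}.
#' @return data frame with one row per scene: focus area fractions
#'   (algorithm and truth) and their absolute error, nucleus counts
#'   (algorithm and truth) and relative error, and nuclear density inside
#'   the true focus vs outside.
#' @export
narrowfieldSuite <- function(nScenes = 20, baseSeed = 1,
                             config = pipelineConfig()) {
  rows <- lapply(seq_len(nScenes), function(k) {
    spec <- sceneSpec("narrowfield", seed = baseSeed + k - 1L)
    scene <- generateScene(spec)
    cfg <- config
    cfg$narrowfield$params <- narrowfieldParams(
      frameScale = spec$size[2] / 5184)
    res <- narrowfieldPipeline(sceneImage(scene), cfg,
                               pixelAreaUm2 = spec$pixelSizeUm^2)
    ns <- nucleusSet(res)
    focus <- focusContour(res)
    fracAlgo <- if (isEmptyFocus(focus)) NA_real_
                else focusAreaFraction(focus)
    fracTruth <- mean(focusMask(scene))
    nTrue <- nrow(centroids(scene))
    pxA <- spec$pixelSizeUm^2
    inside <- nuclearDensity(ns, focusMask(scene), pxA)
    outside <- nuclearDensity(ns, .asIntMask(1L - focusMask(scene)), pxA)
    data.frame(seed = spec$seed,
               frac_algo = fracAlgo, frac_truth = fracTruth,
               frac_err = abs(fracAlgo - fracTruth),
               n_algo = nucleusCount(ns), n_truth = nTrue,
               count_rel_err = abs(nucleusCount(ns) - nTrue) / nTrue,
               density_inside = inside, density_outside = outside)
  })
  do.call(rbind, rows)
}
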
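#' @import methods
NULL

# Pixel containers are deliberately plain base objects:
#   - a greyscale raster is a numeric matrix in [0,1], indexed [row i, col j];
#   - an RGB raster is a numeric array dim (h, w, 3);
#   - a binary mask is a 0/1 matrix (integer or numeric);
#   - a label map is a non-negative integer matrix, 0 = background.
# S4 classes below hold structured *results*, with validity checks.

#' Stain-concentration image
#'
#' Per-pixel haematoxylin / eosin / unstained (HEU) concentrations obtained by
#' Beer-Lambert colour deconvolution of an RGB image, together with the stain
#' matrix and white reference used.
#'
#' @slot conc numeric array, dim (height, width, 3); channels ordered H, E, U;
#'   concentrations are non-negative (negatives are clipped at deconvolution).
#' @slot stainMatrix 3x3 numeric matrix of unit optical-density row vectors.
#' @slot whiteRef numeric length-3 per-channel white reference intensity.
#' @export
setClass("StainImage",
  representation(conc = "array", stainMatrix = "matrix", whiteRef = "numeric"))

setValidity("StainImage", function(object) {
  d <- dim(object@conc)
  if (length(d) != 3L || d[3] != 3L) return("conc must be an (h, w, 3) array")
  if (any(!is.finite(object@conc))) return("concentrations must be finite")
  if (min(object@conc) < 0) return("concentrations must be non-negative")
  if (!identical(dim(object@stainMatrix), c(3L, 3L)))
    return("stainMatrix must be 3x3")
  if (length(object@whiteRef) != 3L) return("whiteRef must have length 3")
  TRUE
})

#' Pixel-level disagreement scores between two binary masks
#'
#' @slot mP fraction of all pixels white in the algorithm mask only
#'   (false-positive fraction).
#' @slot mN fraction white in the operator mask only (false-negative fraction).
#' @slot m total mislabelled fraction, exactly \code{mP + mN}.
#' @export
setClass("PixelScores",
  representation(mP = "numeric", mN = "numeric", m = "numeric"))

setValidity("PixelScores", function(object) {
  v <- c(object@mP, object@mN, object@m)
  if (length(v) != 3L || any(!is.finite(v)) || any(v < 0) || any(v > 1))
    return("mP, mN, m must be single values in [0, 1]")
  if (abs(object@m - (object@mP + object@mN)) > 1e-12)
    return("m must equal mP + mN")
  TRUE
})

#' Zone-level agreement between algorithm and operator masks
#'
#' Validity (\code{fA}) is the fraction of algorithm zones sharing at least the
#' validity threshold of their pixels with operator zones; recall (\code{fG})
#' is the fraction of operator zones at least the recall threshold covered by
#' the algorithm mask. Either score is \code{NA} when the corresponding mask
#' has no zones (undefined, never coerced to 0 or 1).
#'
#' @slot fA numeric, validity score or NA.
#' @slot fG numeric, recall score or NA.
#' @slot counts named integer: validated, algorithmZones, recalled,
#'   operatorZones.
#' @export
setClass("ZoneAgreement",
  representation(fA = "numeric", fG = "numeric", counts = "integer"))

setValidity("ZoneAgreement", function(object) {
  need <- c("validated", "algorithmZones", "recalled", "operatorZones")
  if (!identical(names(object@counts), need))
    return("counts must be named validated/algorithmZones/recalled/operatorZones")
  ok <- function(f, num, den) {
    if (den == 0L) return(is.na(f))
    isTRUE(all.equal(f, num / den))
  }
  if (!ok(object@fA, object@counts[["validated"]],
          object@counts[["algorithmZones"]]))
    return("fA inconsistent with counts")
  if (!ok(object@fG, object@counts[["recalled"]],
          object@counts[["operatorZones"]]))
    return("fG inconsistent with counts")
  TRUE
})

#' One connected zone of white pixels
#'
#' @slot pixelSet integer matrix (n x 2) of 1-based (i, j) pixel coordinates.
#' @slot areaPx integer pixel count, equal to \code{nrow(pixelSet)}.
#' @export
setClass("Zone", representation(pixelSet = "matrix", areaPx = "integer"))

setValidity("Zone", function(object) {
  if (ncol(object@pixelSet) != 2L) return("pixelSet must be n x 2")
  if (object@areaPx != nrow(object@pixelSet)) return("areaPx must match pixelSet")
  if (object@areaPx < 1L) return("a zone has at least one pixel")
  TRUE
})

#' Widefield segmentation result
#'
#' @slot inflammation binary mask of inflammatory zones (analysis scale).
#' @slot veins binary mask of vein lumina / tissue gaps.
#' @slot zones list of \linkS4class{Zone}, the connected components of the
#'   inflammation mask.
#' @slot scaleFactor per-axis downscale factor applied before analysis.
#' @slot pixelArea area of one analysis-scale pixel in square micrometres.
#' @export
setClass("WidefieldResult",
  representation(inflammation = "matrix", veins = "matrix", zones = "list",
                 scaleFactor = "numeric", pixelArea = "numeric"))

setValidity("WidefieldResult", function(object) {
  if (!identical(dim(object@inflammation), dim(object@veins)))
    return("inflammation and veins masks must share a shape")
  if (!all(object@inflammation %in% c(0, 1)) || !all(object@veins %in% c(0, 1)))
    return("masks must be binary")
  if (!all(vapply(object@zones, is, logical(1), class2 = "Zone")))
    return("zones must be Zone objects")
  TRUE
})

#' Contour of the central inflammatory focus
#'
#' An empty result (no focus found) is represented explicitly with zero
#' vertices and NA areas; see \code{\link{isEmptyFocus}}.
#'
#' @slot vertices numeric matrix (n x 2) of (i, j) coordinates tracing a
#'   closed polygon (first vertex not repeated).
#' @slot areaPx polygon area in pixels (shoelace formula), or NA.
#' @slot areaFraction polygon area divided by total image pixel count, or NA.
#' @slot raster binary mask of the thresholded saliency component the contour
#'   outlines (used for density exclusion).
#' @export
setClass("FocusContour",
  representation(vertices = "matrix", areaPx = "numeric",
                 areaFraction = "numeric", raster = "matrix"))

setValidity("FocusContour", function(object) {
  if (ncol(object@vertices) != 2L && nrow(object@vertices) > 0L)
    return("vertices must be n x 2")
  if (nrow(object@vertices) == 0L) {
    if (!is.na(object@areaPx) || !is.na(object@areaFraction))
      return("empty contour must carry NA areas")
  } else {
    if (nrow(object@vertices) < 3L) return("a polygon needs >= 3 vertices")
    if (!is.finite(object@areaPx) || object@areaPx < 0)
      return("areaPx must be a non-negative number")
    if (!is.finite(object@areaFraction) || object@areaFraction < 0 ||
        object@areaFraction > 1)
      return("areaFraction must lie in [0, 1]")
  }
  TRUE
})

#' Segmented nuclei
#'
#' @slot labels integer label map; 0 background, k > 0 the k-th nucleus.
#' @slot centroids numeric matrix (count x 2) of (i, j) centroids.
#' @slot count number of nuclei.
#' @export
setClass("NucleusSet",
  representation(labels = "matrix", centroids = "matrix", count = "integer"))

setValidity("NucleusSet", function(object) {
  k <- length(setdiff(unique(as.integer(object@labels)), 0L))
  if (object@count != k) return("count must equal the number of nonzero labels")
  if (nrow(object@centroids) != object@count)
    return("one centroid per nucleus required")
  TRUE
})

#' Narrowfield analysis result
#'
#' @slot nuclei binary nucleus mask.
#' @slot focus \linkS4class{FocusContour} of the central inflammatory focus.
#' @slot nucleusSet \linkS4class{NucleusSet} from the watershed separation.
#' @slot pixelArea square micrometres per pixel.
#' @export
setClass("NarrowfieldResult",
  representation(nuclei = "matrix", focus = "FocusContour",
                 nucleusSet = "NucleusSet", pixelArea = "numeric"))

#' Robust regression report
#'
#' @slot slope,intercept Huber M-estimates.
#' @slot r2 squared Pearson correlation of the inputs.
#' @slot ciSlope,ciIntercept percentile bootstrap 95\% intervals (lo, hi).
#' @slot n number of points.
#' @slot bootstrapReps number of bootstrap resamples.
#' @export
setClass("RegressionReport",
  representation(slope = "numeric", intercept = "numeric", r2 = "numeric",
                 ciSlope = "numeric", ciIntercept = "numeric", n = "integer",
                 bootstrapReps = "integer"))

setValidity("RegressionReport", function(object) {
  if (object@n < 3L) return("n must be >= 3")
  if (length(object@ciSlope) != 2L || object@ciSlope[1] > object@ciSlope[2])
    return("ciSlope must be (lo, hi) with lo <= hi")
  TRUE
})

#' Synthetic H&E scene with exact ground truth
#'
#' @slot image RGB array (h, w, 3) in [0, 1], the rendered (and possibly
#'   degraded) scene.
#' @slot focusMask ground-truth binary mask of inflammatory foci.
#' @slot veinMask ground-truth binary mask of vein lumina.
#' @slot centroids numeric matrix (n x 2) of true nucleus centroids (i, j).
#' @slot nucleusType character vector, "hepatocyte" or "immune" per nucleus.
#' @slot spec the generating scene specification (list).
#' @export
setClass("SyntheticScene",
  representation(image = "array", focusMask = "matrix", veinMask = "matrix",
                 centroids = "matrix", nucleusType = "character",
                 spec = "list"))

setValidity("SyntheticScene", function(object) {
  d <- dim(object@image)
  if (length(d) != 3L || d[3] != 3L) return("image must be (h, w, 3)")
  if (!identical(dim(object@focusMask), d[1:2]) ||
      !identical(dim(object@veinMask), d[1:2]))
    return("masks must match the image shape")
  if (nrow(object@centroids) != length(object@nucleusType))
    return("one nucleus type per centroid")
  TRUE
})
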
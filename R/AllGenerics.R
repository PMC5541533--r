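#' Accessors for heseg result classes
#'
#' Small accessor generics so downstream code never touches slots directly.
#'
#' @param x a heseg result object.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("hChannel", function(x) standardGeneric("hChannel"))
#' @rdname accessors
#' @export
setGeneric("eChannel", function(x) standardGeneric("eChannel"))
#' @rdname accessors
#' @export
setGeneric("uChannel", function(x) standardGeneric("uChannel"))
#' @rdname accessors
#' @export
setGeneric("stainMatrixOf", function(x) standardGeneric("stainMatrixOf"))
#' @rdname accessors
#' @export
setGeneric("inflammationMask", function(x) standardGeneric("inflammationMask"))
#' @rdname accessors
#' @export
setGeneric("veinMask", function(x) standardGeneric("veinMask"))
#' @rdname accessors
#' @export
setGeneric("zones", function(x) standardGeneric("zones"))
#' @rdname accessors
#' @export
setGeneric("nucleusMask", function(x) standardGeneric("nucleusMask"))
#' @rdname accessors
#' @export
setGeneric("focusContour", function(x) standardGeneric("focusContour"))
#' @rdname accessors
#' @export
setGeneric("nucleusSet", function(x) standardGeneric("nucleusSet"))
#' @rdname accessors
#' @export
setGeneric("labelMap", function(x) standardGeneric("labelMap"))
#' @rdname accessors
#' @export
setGeneric("centroids", function(x) standardGeneric("centroids"))
#' @rdname accessors
#' @export
setGeneric("nucleusCount", function(x) standardGeneric("nucleusCount"))
#' @rdname accessors
#' @export
setGeneric("sceneImage", function(x) standardGeneric("sceneImage"))
#' @rdname accessors
#' @export
setGeneric("focusMask", function(x) standardGeneric("focusMask"))
#' @rdname accessors
#' @export
setGeneric("sceneSpecOf", function(x) standardGeneric("sceneSpecOf"))

setMethod("hChannel", "StainImage", function(x) x@conc[, , 1])
setMethod("eChannel", "StainImage", function(x) x@conc[, , 2])
setMethod("uChannel", "StainImage", function(x) x@conc[, , 3])
setMethod("stainMatrixOf", "StainImage", function(x) x@stainMatrix)
setMethod("inflammationMask", "WidefieldResult", function(x) x@inflammation)
setMethod("veinMask", "WidefieldResult", function(x) x@veins)
setMethod("veinMask", "SyntheticScene", function(x) x@veinMask)
setMethod("zones", "WidefieldResult", function(x) x@zones)
setMethod("nucleusMask", "NarrowfieldResult", function(x) x@nuclei)
setMethod("focusContour", "NarrowfieldResult", function(x) x@focus)
setMethod("nucleusSet", "NarrowfieldResult", function(x) x@nucleusSet)
setMethod("labelMap", "NucleusSet", function(x) x@labels)
setMethod("centroids", "NucleusSet", function(x) x@centroids)
setMethod("centroids", "SyntheticScene", function(x) x@centroids)
setMethod("nucleusCount", "NucleusSet", function(x) x@count)
setMethod("sceneImage", "SyntheticScene", function(x) x@image)
setMethod("focusMask", "SyntheticScene", function(x) x@focusMask)
setMethod("sceneSpecOf", "SyntheticScene", function(x) x@spec)

#' @rdname accessors
#' @export
setGeneric("pixelFractions", function(x) standardGeneric("pixelFractions"))

#' @describeIn accessors named numeric c(mP, mN, m) from a PixelScores.
setMethod("pixelFractions", "PixelScores", function(x)
  c(mP = x@mP, mN = x@mN, m = x@m))

#' @rdname accessors
#' @export
setGeneric("agreementScores", function(x) standardGeneric("agreementScores"))

#' @describeIn accessors named numeric c(fA, fG) (NA when undefined).
setMethod("agreementScores", "ZoneAgreement", function(x)
  c(fA = x@fA, fG = x@fG))

#' @rdname accessors
#' @export
setGeneric("zoneCounts", function(x) standardGeneric("zoneCounts"))
setMethod("zoneCounts", "ZoneAgreement", function(x) x@counts)

#' @rdname accessors
#' @export
setGeneric("zoneArea", function(x) standardGeneric("zoneArea"))
setMethod("zoneArea", "Zone", function(x) x@areaPx)
#' @rdname accessors
#' @export
setGeneric("zonePixels", function(x) standardGeneric("zonePixels"))
setMethod("zonePixels", "Zone", function(x) x@pixelSet)

#' @rdname accessors
#' @export
setGeneric("contourVertices", function(x) standardGeneric("contourVertices"))
setMethod("contourVertices", "FocusContour", function(x) x@vertices)
#' @rdname accessors
#' @export
setGeneric("focusAreaPx", function(x) standardGeneric("focusAreaPx"))
setMethod("focusAreaPx", "FocusContour", function(x) x@areaPx)
#' @rdname accessors
#' @export
setGeneric("focusAreaFraction", function(x) standardGeneric("focusAreaFraction"))
setMethod("focusAreaFraction", "FocusContour", function(x) x@areaFraction)
#' @rdname accessors
#' @export
setGeneric("focusRaster", function(x) standardGeneric("focusRaster"))
setMethod("focusRaster", "FocusContour", function(x) x@raster)

#' Is a focus-contour result the explicit "no focus found" value?
#'
#' @param x a \linkS4class{FocusContour}.
#' @return logical.
#' @export
isEmptyFocus <- function(x) {
  stopifnot(is(x, "FocusContour"))
  nrow(x@vertices) == 0L
}

#' Coefficients of a robust regression report
#'
#' @param object a \linkS4class{RegressionReport}.
#' @param ... ignored.
#' @return named numeric with slope, intercept, r2 and the 95\% slope CI.
#' @export
setMethod("coef", "RegressionReport", function(object, ...)
  c(slope = object@slope, intercept = object@intercept, r2 = object@r2,
    ciSlopeLo = object@ciSlope[1], ciSlopeHi = object@ciSlope[2]))

setMethod("show", "StainImage", function(object) {
  d <- dim(object@conc)
  cat(sprintf("StainImage %d x %d (H/E/U), mean conc %.3f/%.3f/%.3f\n",
              d[1], d[2], mean(object@conc[, , 1]), mean(object@conc[, , 2]),
              mean(object@conc[, , 3])))
})

setMethod("show", "PixelScores", function(object) {
  cat(sprintf("PixelScores: M_P = %.4f, M_N = %.4f, M = %.4f\n",
              object@mP, object@mN, object@m))
})

setMethod("show", "ZoneAgreement", function(object) {
  cat(sprintf(
    "ZoneAgreement: F_A = %s (%d/%d), F_G = %s (%d/%d)\n",
    ifelse(is.na(object@fA), "NA", sprintf("%.3f", object@fA)),
    object@counts[["validated"]], object@counts[["algorithmZones"]],
    ifelse(is.na(object@fG), "NA", sprintf("%.3f", object@fG)),
    object@counts[["recalled"]], object@counts[["operatorZones"]]))
})

setMethod("show", "WidefieldResult", function(object) {
  cat(sprintf(
    "WidefieldResult %d x %d: %d inflammatory zones (%.1f%% of pixels), veins %.1f%%\n",
    nrow(object@inflammation), ncol(object@inflammation),
    length(object@zones), 100 * mean(object@inflammation),
    100 * mean(object@veins)))
})

setMethod("show", "FocusContour", function(object) {
  if (isEmptyFocus(object)) cat("FocusContour: no focus found\n")
  else cat(sprintf("FocusContour: %d vertices, area %.0f px (%.3f of image)\n",
                   nrow(object@vertices), object@areaPx, object@areaFraction))
})

setMethod("show", "NucleusSet", function(object) {
  cat(sprintf("NucleusSet: %d nuclei\n", object@count))
})

setMethod("show", "NarrowfieldResult", function(object) {
  cat(sprintf("NarrowfieldResult: %d nuclei; focus %s\n", object@nucleusSet@count,
              if (isEmptyFocus(object@focus)) "not found"
              else sprintf("area fraction %.3f", object@focus@areaFraction)))
})

setMethod("show", "RegressionReport", function(object) {
  cat(sprintf(
    "Huber fit (n = %d): slope %.3f [%.3f, %.3f], intercept %.3f, R^2 = %.3f\n",
    object@n, object@slope, object@ciSlope[1], object@ciSlope[2],
    object@intercept, object@r2))
})

setMethod("show", "SyntheticScene", function(object) {
  d <- dim(object@image)
  cat(sprintf(
    "SyntheticScene %d x %d (%s): %d nuclei, focus %.1f%%, veins %.1f%% of pixels\n",
    d[1], d[2], object@spec$kind, nrow(object@centroids),
    100 * mean(object@focusMask), 100 * mean(object@veinMask)))
})
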
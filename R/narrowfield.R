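# Narrowfield pipeline: nuclei binarization, entropy-density focus saliency
# and contour extraction, and watershed separation of overlapping nuclei.

#' Narrowfield parameters
#'
#' Stage parameters for the narrowfield chain, at native narrowfield
#' resolution.
#'
#' @param sigmoidCutoff,sigmoidGain contrast sigmoid on the red channel.
#' @param threshBlock adaptive-threshold neighbourhood (odd, pixels).
#' @param threshOffset adaptive-threshold margin (nuclei must fall this far
#'   below the local mean).
#' @param closeRadius closing disc radius applied to the non-nucleus phase.
#' @param minSize nucleus components of strictly fewer pixels are removed
#'   (components of \code{minSize - 1} or fewer, i.e. "100 or less" for the
#'   default 101).
#' @param entropyRadius disc radius for local entropy (pixels).
#' @param densitySigma Gaussian sigma of the nuclear-density blur (pixels,
#'   at full narrowfield frame size).
#' @param entropySigma Gaussian sigma blurring the entropy map (pixels, at
#'   full frame size).
#' @param combine how density and texture maps are combined: "geomean"
#'   (default), "product" or "min".
#' @param minDistance minimum distance between watershed seed peaks (pixels).
#' @param frameScale ratio of the image width to the full-frame reference
#'   width (5184 px). The two saliency sigmas measure structure at the
#'   focus scale, so they shrink proportionally on reduced fields of view;
#'   nucleus-scale parameters are resolution-native and are not scaled.
#' @return list of class "narrowfieldParams".
#' @export
narrowfieldParams <- function(sigmoidCutoff = 0.5, sigmoidGain = 10,
                              threshBlock = 101, threshOffset = 0.02,
                              closeRadius = 3, minSize = 101,
                              entropyRadius = 3, densitySigma = 61,
                              entropySigma = 75,
                              combine = c("geomean", "product", "min"),
                              minDistance = 7, frameScale = 1) {
  combine <- match.arg(combine)
  densitySigma <- densitySigma * frameScale
  entropySigma <- entropySigma * frameScale
  structure(list(sigmoidCutoff = sigmoidCutoff, sigmoidGain = sigmoidGain,
                 threshBlock = threshBlock, threshOffset = threshOffset,
                 closeRadius = closeRadius, minSize = minSize,
                 entropyRadius = entropyRadius, densitySigma = densitySigma,
                 entropySigma = entropySigma, combine = combine,
                 minDistance = minDistance),
            class = "narrowfieldParams")
}

#' Binarize nuclei in a narrowfield image
#'
#' Keeps only the red channel (haematoxylin-dark nuclei have low red
#' luminosity; cytoplasm, vessels and background are red-bright), boosts
#' contrast with a sigmoid, adaptively thresholds so nuclei are the
#' below-local-mean phase, closes the non-nucleus phase with a small disc to
#' remove pinholes and smooth nucleus outlines, removes remaining small
#' nucleus components, and returns nuclei as white.
#'
#' @param img RGB array (h, w, 3).
#' @param params a \code{\link{narrowfieldParams}}.
#' @return binary mask, white = nuclei.
#' @export
binarizeNuclei <- function(img, params = narrowfieldParams()) {
  if (length(dim(img)) != 3L || dim(img)[3] != 3L)
    stop("binarizeNuclei requires a 3-channel image", call. = FALSE)
  p <- params
  red <- sigmoidContrast(img[, , 1], p$sigmoidCutoff, p$sigmoidGain)
  nuclei <- adaptiveThreshold(red, p$threshBlock, p$threshOffset, "below")
  nonNuclei <- .asIntMask(1L - nuclei)
  nonNuclei <- morphClose(nonNuclei, p$closeRadius)
  nuclei <- .asIntMask(1L - nonNuclei)
  removeSmallComponents(nuclei, p$minSize)
}

#' Entropy-density focus saliency
#'
#' Combines a nuclear-density map (strong Gaussian blur of the nucleus mask)
#' with a texture map (Gaussian-blurred local entropy of the mask, base-2, in
#' a small disc). Each map is min-max normalized and the two are combined
#' nonlinearly (by default their product, which vanishes wherever either cue
#' is absent). Bright saliency marks areas of dense, irregularly packed
#' nuclei - the inflammatory focus.
#'
#' @param nuclei binary nucleus mask from \code{\link{binarizeNuclei}}.
#' @param params a \code{\link{narrowfieldParams}}.
#' @return numeric saliency matrix in [0, 1].
#' @export
focusSaliency <- function(nuclei, params = narrowfieldParams()) {
  .assertMask(nuclei, "nuclei")
  p <- params
  density <- cpp_gaussian_blur(nuclei + 0.0, p$densitySigma,
                               as.integer(ceiling(3 * p$densitySigma)))
  ent <- localEntropy(nuclei + 0.0, radius = p$entropyRadius, levels = 2L)
  texture <- cpp_gaussian_blur(ent, p$entropySigma,
                               as.integer(ceiling(3 * p$entropySigma)))
  d <- .minmax(density); t <- .minmax(texture)
  switch(p$combine,
         product = d * t,
         geomean = sqrt(d * t),
         min = pmin(d, t))
}

# Fill interior holes of a binary mask: background components (4-connected,
# complementary to 8-connected foreground) not touching the border become
# foreground.
.fillHoles <- function(mask) {
  inv <- .asIntMask(1L - mask)
  lab <- cpp_label_components(inv, 4L)
  border <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)]))
  border <- border[border > 0L]
  hole <- lab > 0L & !(lab %in% border)
  out <- mask
  out[hole] <- 1L
  .asIntMask(out)
}

#' Extract the central inflammatory focus contour
#'
#' Thresholds the saliency map with Otsu's method, labels the bright
#' components, and selects the most central and largest object: the component
#' containing the image centre wins; otherwise the component whose centroid
#' is nearest the centre among the three largest. Interior holes are filled
#' and the object's outer boundary is traced by marching squares (on the
#' zero-padded mask, so the contour is closed even when the object touches
#' the image border). When the saliency map is degenerate or empty, an
#' explicit empty \linkS4class{FocusContour} is returned.
#'
#' @param saliency numeric matrix from \code{\link{focusSaliency}}.
#' @return a \linkS4class{FocusContour}.
#' @export
extractFocusContour <- function(saliency) {
  .assertGrey(saliency, "saliency")
  empty <- new("FocusContour", vertices = matrix(numeric(0), 0, 2),
               areaPx = NA_real_, areaFraction = NA_real_,
               raster = matrix(0L, nrow(saliency), ncol(saliency)))
  level <- tryCatch(otsuThreshold(saliency), error = function(e) NULL)
  if (is.null(level)) return(empty)
  bright <- .asIntMask((saliency > level) + 0L)
  lab <- cpp_label_components(bright, 8L)
  k <- max(lab)
  if (k == 0L) return(empty)
  h <- nrow(saliency); w <- ncol(saliency)
  centre <- c((h - 1) / 2, (w - 1) / 2)       # 0-based centre
  compId <- lab[round(centre[1]) + 1L, round(centre[2]) + 1L]
  if (compId == 0L) {
    sizes <- tabulate(lab[lab > 0L], nbins = k)
    top <- order(sizes, decreasing = TRUE)[seq_len(min(3L, k))]
    d2 <- vapply(top, function(z) {
      idx <- which(lab == z)
      ci <- mean((idx - 1L) %% h)             # 0-based centroid
      cj <- mean((idx - 1L) %/% h)
      (ci - centre[1])^2 + (cj - centre[2])^2
    }, numeric(1))
    compId <- top[which.min(d2)]
  }
  raster <- .fillHoles(.asIntMask((lab == compId) + 0L))
  # outer boundary on the padded mask: always one closed contour
  pad <- matrix(0, h + 2L, w + 2L)
  pad[2L:(h + 1L), 2L:(w + 1L)] <- raster
  cts <- marchingSquares(pad, 0.5)
  cts <- Filter(function(ct) isTRUE(attr(ct, "closed")) && nrow(ct) >= 3, cts)
  if (length(cts) == 0L) return(empty)
  areas <- vapply(cts, .polygonArea, numeric(1))
  verts <- cts[[which.max(areas)]] - 1        # undo padding shift
  attr(verts, "closed") <- NULL
  new("FocusContour", vertices = unname(verts),
      areaPx = .polygonArea(verts),
      areaFraction = .polygonArea(verts) / (h * w), raster = raster)
}

#' Watershed separation of overlapping nuclei
#'
#' Computes the Euclidean distance transform of the nucleus mask, seeds one
#' marker per distance peak (minimum peak separation \code{minDistance};
#' components left without a peak receive one marker at their distance
#' maximum), and floods the negated distance surface so touching nuclei are
#' split along their necks. Labels partition the mask exactly.
#'
#' @param nuclei binary nucleus mask.
#' @param minDistance minimum distance between seed peaks in pixels.
#' @return a \linkS4class{NucleusSet}.
#' @export
segmentNuclei <- function(nuclei, minDistance = 7) {
  .assertMask(nuclei, "nuclei")
  if (!any(nuclei == 1))
    return(new("NucleusSet", labels = matrix(0L, nrow(nuclei), ncol(nuclei)),
               centroids = matrix(numeric(0), 0, 2), count = 0L))
  edt <- distanceTransform(nuclei)
  markers <- peakMarkers(edt, minDistance, region = nuclei)
  # guarantee one marker per connected component
  comp <- cpp_label_components(.asIntMask(nuclei), 8L)
  seeded <- unique(comp[markers > 0L])
  missing <- setdiff(seq_len(max(comp)), seeded)
  nextLab <- max(markers)
  for (cmp in missing) {
    idx <- which(comp == cmp)
    best <- idx[which.max(edt[idx])]
    nextLab <- nextLab + 1L
    markers[best] <- nextLab
  }
  labels <- watershedSegment(-edt, markers, nuclei)
  k <- max(labels)
  idx <- which(labels > 0L)
  ii <- (idx - 1L) %% nrow(labels) + 1L
  jj <- (idx - 1L) %/% nrow(labels) + 1L
  lv <- labels[idx]
  cent <- cbind(i = rowsum(ii, lv)[, 1] / tabulate(lv, k),
                j = rowsum(jj, lv)[, 1] / tabulate(lv, k))
  new("NucleusSet", labels = labels, centroids = unname(cent),
      count = as.integer(k))
}

#' Full narrowfield pipeline on an in-memory image
#'
#' Binarizes nuclei, extracts the central focus contour from the
#' entropy-density saliency, and separates overlapping nuclei by watershed.
#'
#' @param img RGB array (h, w, 3) at narrowfield resolution.
#' @param config a \code{\link{pipelineConfig}}.
#' @param pixelAreaUm2 pixel area; NULL derives it from the configured field
#'   of view and the reference sensor size.
#' @return a \linkS4class{NarrowfieldResult}.
#' @export
narrowfieldPipeline <- function(img, config = pipelineConfig(),
                                pixelAreaUm2 = NULL) {
  p <- config$narrowfield$params
  if (is.null(pixelAreaUm2)) {
    fov <- config$narrowfield$fovMm
    pixelAreaUm2 <- pixelAreaFromFov(fov[1], fov[2], 3456, 5184)
  }
  nuclei <- binarizeNuclei(img, p)
  sal <- focusSaliency(nuclei, p)
  focus <- extractFocusContour(sal)
  ns <- segmentNuclei(nuclei, p$minDistance)
  new("NarrowfieldResult", nuclei = nuclei, focus = focus, nucleusSet = ns,
      pixelArea = pixelAreaUm2)
}
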
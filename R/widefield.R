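# Widefield pipeline: global preprocessing, quarter-resolution downscale,
# colour deconvolution, then segmentation of inflammatory zones (from the
# haematoxylin channel) and veins (from the unstained/eosin ratio).

# Vectorized HSV <-> RGB helpers (h, s, v all in [0, 1]).
.rgbToHsv <- function(img) {
  r <- img[, , 1]; g <- img[, , 2]; b <- img[, , 3]
  mx <- pmax(r, g, b); mn <- pmin(r, g, b)
  d <- mx - mn
  hDeg <- matrix(0, nrow(r), ncol(r))
  nz <- d > 0
  isR <- nz & mx == r
  isG <- nz & !isR & mx == g
  isB <- nz & !isR & !isG
  hDeg[isR] <- ((g[isR] - b[isR]) / d[isR]) %% 6
  hDeg[isG] <- (b[isG] - r[isG]) / d[isG] + 2
  hDeg[isB] <- (r[isB] - g[isB]) / d[isB] + 4
  list(h = hDeg / 6, s = ifelse(mx > 0, d / mx, 0), v = mx)
}

.hsvToRgb <- function(h, s, v) {
  h6 <- (h * 6) %% 6
  c1 <- v * s
  x <- c1 * (1 - abs(h6 %% 2 - 1))
  m <- v - c1
  sector <- floor(h6)
  r <- g <- b <- matrix(0, nrow(h), ncol(h))
  set <- function(sel, rr, gg, bb) {
    r[sel] <<- rr[sel]; g[sel] <<- gg[sel]; b[sel] <<- bb[sel]
  }
  set(sector == 0, c1, x, 0 * x)
  set(sector == 1, x, c1, 0 * x)
  set(sector == 2, 0 * x, c1, x)
  set(sector == 3, 0 * x, x, c1)
  set(sector == 4, x, 0 * x, c1)
  set(sector == 5, c1, 0 * x, x)
  array(c(r + m, g + m, b + m), c(nrow(h), ncol(h), 3))
}

#' Global preprocessing parameters
#'
#' Settings for \code{\link{preprocessGlobal}}. A step is skipped when its
#' parameter is at the neutral value, so \code{preprocessParams(identity =
#' TRUE)} leaves images untouched.
#'
#' @param identity if TRUE, return a parameter set with every step disabled.
#' @param sigmoidCutoff,sigmoidGain luminance contrast sigmoid; gain 0
#'   disables.
#' @param saturationGain multiplicative saturation boost (1 disables).
#' @param denoiseSigma Gaussian denoising sigma in pixels (0 disables).
#' @param unsharpAmount,unsharpSigma unsharp-mask strength (0 disables) and
#'   blur sigma.
#' @param warmBrighten,warmDesaturate relative value boost / saturation cut in
#'   the yellow-orange hue band (tissue-background separation).
#' @param coolSaturate,coolDarken relative saturation boost / value cut in the
#'   blue-purple band (nuclei and inflammatory foci emphasis).
#' @return list of class "preprocessParams".
#' @export
preprocessParams <- function(identity = FALSE,
                             sigmoidCutoff = 0.5, sigmoidGain = 5,
                             saturationGain = 1.05, denoiseSigma = 0.8,
                             unsharpAmount = 0.3, unsharpSigma = 2,
                             warmBrighten = 0.05, warmDesaturate = 0.1,
                             coolSaturate = 0.1, coolDarken = 0.05) {
  p <- list(sigmoidCutoff = sigmoidCutoff, sigmoidGain = sigmoidGain,
            saturationGain = saturationGain, denoiseSigma = denoiseSigma,
            unsharpAmount = unsharpAmount, unsharpSigma = unsharpSigma,
            warmBrighten = warmBrighten, warmDesaturate = warmDesaturate,
            coolSaturate = coolSaturate, coolDarken = coolDarken)
  if (identity) {
    p$sigmoidGain <- 0; p$saturationGain <- 1; p$denoiseSigma <- 0
    p$unsharpAmount <- 0
    p$warmBrighten <- p$warmDesaturate <- 0
    p$coolSaturate <- p$coolDarken <- 0
  }
  structure(p, class = "preprocessParams")
}

#' Global image preprocessing
#'
#' Applies, in order: a sigmoid contrast transform on luminance, a colour
#' saturation gain, Gaussian denoising, an unsharp mask, and hue-targeted
#' edits (yellows/oranges brightened and desaturated to separate tissue from
#' background; blues/purples saturated and darkened to emphasize nuclei).
#' Deterministic and non-destructive.
#'
#' @param img RGB array (h, w, 3) in [0, 1].
#' @param params a \code{\link{preprocessParams}}.
#' @return preprocessed RGB array.
#' @export
preprocessGlobal <- function(img, params = preprocessParams()) {
  if (length(dim(img)) != 3L || dim(img)[3] != 3L)
    stop("preprocessGlobal requires a 3-channel image", call. = FALSE)
  p <- params
  active <- function(...) any(...)
  if (p$sigmoidGain > 0 || p$saturationGain != 1) {
    hsv <- .rgbToHsv(img)
    v <- hsv$v; s <- hsv$s
    if (p$sigmoidGain > 0) v <- sigmoidContrast(v, p$sigmoidCutoff,
                                                p$sigmoidGain)
    if (p$saturationGain != 1) s <- pmin(s * p$saturationGain, 1)
    img <- .hsvToRgb(hsv$h, s, v)
  }
  if (p$denoiseSigma > 0)
    for (c in 1:3)
      img[, , c] <- cpp_gaussian_blur(img[, , c], p$denoiseSigma,
                                      as.integer(ceiling(3 * p$denoiseSigma)))
  if (p$unsharpAmount > 0) {
    for (c in 1:3) {
      blur <- cpp_gaussian_blur(img[, , c], p$unsharpSigma,
                                as.integer(ceiling(3 * p$unsharpSigma)))
      img[, , c] <- img[, , c] + p$unsharpAmount * (img[, , c] - blur)
    }
    img[img < 0] <- 0; img[img > 1] <- 1
  }
  if (p$warmBrighten > 0 || p$warmDesaturate > 0 ||
      p$coolSaturate > 0 || p$coolDarken > 0) {
    hsv <- .rgbToHsv(img)
    hDeg <- hsv$h * 360
    warm <- hDeg >= 20 & hDeg < 90
    cool <- hDeg >= 200 & hDeg < 320
    v <- hsv$v; s <- hsv$s
    v[warm] <- pmin(v[warm] * (1 + p$warmBrighten), 1)
    s[warm] <- s[warm] * (1 - p$warmDesaturate)
    s[cool] <- pmin(s[cool] * (1 + p$coolSaturate), 1)
    v[cool] <- v[cool] * (1 - p$coolDarken)
    img <- .hsvToRgb(hsv$h, s, v)
  }
  img
}

#' Downscale to a quarter of the pixel count
#'
#' Area-averaged downscale by a factor of two per axis. Odd trailing rows or
#' columns are trimmed. A \code{"pixelArea"} attribute, when present, is
#' multiplied by four.
#'
#' @param img numeric matrix or (h, w, c) array.
#' @return downscaled image of the same type.
#' @export
downscaleQuarter <- function(img) {
  down2 <- function(m) {
    h <- 2L * (nrow(m) %/% 2L); w <- 2L * (ncol(m) %/% 2L)
    m <- m[seq_len(h), seq_len(w), drop = FALSE]
    (m[seq(1, h, 2), seq(1, w, 2), drop = FALSE] +
     m[seq(2, h, 2), seq(1, w, 2), drop = FALSE] +
     m[seq(1, h, 2), seq(2, w, 2), drop = FALSE] +
     m[seq(2, h, 2), seq(2, w, 2), drop = FALSE]) / 4
  }
  pa <- attr(img, "pixelArea")
  out <- if (length(dim(img)) == 3L) {
    ds <- lapply(seq_len(dim(img)[3]), function(c) down2(img[, , c]))
    array(unlist(ds), c(dim(ds[[1]]), dim(img)[3]))
  } else {
    down2(img)
  }
  if (!is.null(pa)) attr(out, "pixelArea") <- 4 * pa
  out
}

#' Inflammation-segmentation parameters (widefield)
#'
#' Stage parameters for \code{\link{segmentInflammation}}. Pixel-denominated
#' values refer to the quarter-resolution analysis scale.
#'
#' @param claheTile CLAHE tile size in pixels.
#' @param claheLimit CLAHE contrast clip limit.
#' @param blurSigma Gaussian smoothing sigma (pixels).
#' @param sigmoidCutoff,sigmoidGain contrast sigmoid applied before
#'   thresholding.
#' @param threshBlock adaptive-threshold neighbourhood (odd, pixels).
#' @param threshOffset adaptive-threshold margin.
#' @param minSize components strictly smaller than this are removed.
#' @param maxFilterSize maximum-filter window (pixels).
#' @param closeRadius closing disc radius (pixels).
#' @return list of class "inflammationParams".
#' @export
inflammationParams <- function(claheTile = 256, claheLimit = 2,
                               blurSigma = 5, sigmoidCutoff = 0.5,
                               sigmoidGain = 8, threshBlock = 301,
                               threshOffset = 0.07, minSize = 250,
                               maxFilterSize = 11, closeRadius = 15) {
  structure(as.list(environment()), class = "inflammationParams")
}

#' Vein-segmentation parameters (widefield)
#'
#' @param blurSigma Gaussian smoothing sigma (pixels).
#' @param threshBlock adaptive-threshold neighbourhood (odd, pixels).
#' @param threshOffset adaptive-threshold margin.
#' @param closeRadius closing disc radius (pixels).
#' @param maxRemovedSize components of this many pixels or fewer are removed
#'   (strictly larger components survive).
#' @return list of class "veinParams".
#' @export
veinParams <- function(blurSigma = 11, threshBlock = 151,
                       threshOffset = 0.03, closeRadius = 25,
                       maxRemovedSize = 200) {
  structure(as.list(environment()), class = "veinParams")
}

# CLAHE with edge-replicating padding so tile counts always divide the
# padded dimensions (EBImage requires exact divisibility).
.clahePadded <- function(x, tile, limit) {
  h <- nrow(x); w <- ncol(x)
  nx <- max(2L, round(h / tile))
  ny <- max(2L, round(w / tile))
  ph <- ceiling(h / nx) * nx
  pw <- ceiling(w / ny) * ny
  xp <- x[c(seq_len(h), rep(h, ph - h)), c(seq_len(w), rep(w, pw - w)),
          drop = FALSE]
  out <- as.matrix(EBImage::clahe(xp, nx = nx, ny = ny, bins = 256,
                                  limit = limit, keep.range = TRUE))
  out[seq_len(h), seq_len(w), drop = FALSE]
}

# Min-max normalization to [0, 1]; constant input maps to zeros.
.minmax <- function(x) {
  rng <- range(x)
  if (rng[2] - rng[1] <= 0) return(x * 0)
  (x - rng[1]) / (rng[2] - rng[1])
}

#' Segment inflammatory zones from the haematoxylin channel
#'
#' Runs, on the H concentration channel: contrast-limited adaptive histogram
#' equalization, Gaussian smoothing, a contrast sigmoid, adaptive
#' thresholding, removal of components below the minimum size, a maximum
#' filter, and a morphological closing. White output pixels mark inflammatory
#' zones. Fully deterministic.
#'
#' @param stains a \linkS4class{StainImage} at analysis scale.
#' @param params an \code{\link{inflammationParams}}.
#' @return binary mask.
#' @export
segmentInflammation <- function(stains, params = inflammationParams()) {
  stopifnot(is(stains, "StainImage"))
  p <- params
  x <- .minmax(hChannel(stains))
  x <- .clahePadded(x, p$claheTile, p$claheLimit)
  x <- cpp_gaussian_blur(x, p$blurSigma, as.integer(ceiling(3 * p$blurSigma)))
  x <- sigmoidContrast(x, p$sigmoidCutoff, p$sigmoidGain)
  m <- adaptiveThreshold(x, p$threshBlock, p$threshOffset, "above")
  m <- removeSmallComponents(m, p$minSize)
  m <- .asIntMask((cpp_max_filter(m + 0.0, as.integer(p$maxFilterSize)) >
                     0.5) + 0L)
  morphClose(m, p$closeRadius)
}

#' Segment veins from the unstained/eosin ratio
#'
#' Runs, on the \code{\link{unstainedRatio}} image: slight Gaussian
#' smoothing, adaptive thresholding, a morphological closing, then removal of
#' connected components of \code{maxRemovedSize} pixels or fewer (strictly
#' larger survive, so thin tears fall out while vein lumina are kept).
#'
#' @param stains a \linkS4class{StainImage} at analysis scale.
#' @param params a \code{\link{veinParams}}.
#' @return binary mask.
#' @export
segmentVeins <- function(stains, params = veinParams()) {
  stopifnot(is(stains, "StainImage"))
  p <- params
  x <- unstainedRatio(stains)
  x <- cpp_gaussian_blur(x, p$blurSigma, as.integer(ceiling(3 * p$blurSigma)))
  m <- adaptiveThreshold(x, p$threshBlock, p$threshOffset, "above")
  m <- morphClose(m, p$closeRadius)
  removeSmallComponents(m, p$maxRemovedSize + 1L)
}

#' Full widefield pipeline on an in-memory image
#'
#' Preprocesses, downscales to quarter pixel count, colour-deconvolves, and
#' segments inflammatory zones and veins.
#'
#' @param img RGB array (h, w, 3), capture scale.
#' @param config a \code{\link{pipelineConfig}}.
#' @param stainMat stain matrix; NULL uses the config/default matrix.
#' @param whiteRef white reference passed to \code{\link{separateStains}}.
#' @param pixelAreaUm2 capture-scale pixel area; NULL derives it from the
#'   configured field of view and the image size.
#' @return a \linkS4class{WidefieldResult}.
#' @export
widefieldPipeline <- function(img, config = pipelineConfig(),
                              stainMat = NULL, whiteRef = NULL,
                              pixelAreaUm2 = NULL) {
  if (is.null(stainMat)) stainMat <- config$stains$matrix
  if (is.null(pixelAreaUm2)) {
    fov <- config$widefield$fovMm
    pixelAreaUm2 <- pixelAreaFromFov(fov[1], fov[2], 3456, 5184)
  }
  pre <- preprocessGlobal(img, config$widefield$preprocess)
  down <- downscaleQuarter(pre)
  stains <- separateStains(down, stainMat, whiteRef)
  infl <- segmentInflammation(stains, config$widefield$inflammation)
  veins <- segmentVeins(stains, config$widefield$veins)
  zs <- extractZones(infl, config$widefield$connectivity)
  new("WidefieldResult", inflammation = infl, veins = veins, zones = zs,
      scaleFactor = 2, pixelArea = 4 * pixelAreaUm2)
}
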
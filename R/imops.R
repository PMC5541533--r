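#' @useDynLib heseg, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# ---- internal validation helpers ------------------------------------------

.assertGrey <- function(img, what = "img") {
  if (!is.matrix(img) || !is.numeric(img))
    stop(what, " must be a single-channel numeric matrix", call. = FALSE)
  invisible(img)
}

.assertMask <- function(mask, what = "mask") {
  if (!is.matrix(mask))
    stop(what, " must be a matrix", call. = FALSE)
  if (!all(mask == 0 | mask == 1))
    stop(what, " must contain only 0 and 1", call. = FALSE)
  invisible(mask)
}

.asIntMask <- function(mask) {
  storage.mode(mask) <- "integer"
  mask
}

# Run code with a private RNG stream, restoring global state afterwards.
.withSeed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# ---- point operators -------------------------------------------------------

#' Sigmoid contrast transform
#'
#' Maps every intensity x to 1 / (1 + exp(gain * (cutoff - x))): a smooth,
#' strictly increasing contrast curve with midpoint 0.5 at \code{x = cutoff}.
#'
#' @param img numeric matrix or array of intensities in [0, 1].
#' @param cutoff midpoint intensity in [0, 1].
#' @param gain positive steepness; large values approach a step function.
#' @return transformed image, same shape, values in (0, 1).
#' @export
sigmoidContrast <- function(img, cutoff = 0.5, gain = 10) {
  if (!is.numeric(gain) || length(gain) != 1L || gain <= 0)
    stop("gain must be a positive number", call. = FALSE)
  if (cutoff < 0 || cutoff > 1)
    stop("cutoff must lie in [0, 1]", call. = FALSE)
  1 / (1 + exp(gain * (cutoff - img)))
}

#' Adaptive (local-mean) thresholding
#'
#' Compares every pixel with the Gaussian-weighted mean of its
#' \code{blockSize} x \code{blockSize} neighbourhood (sigma =
#' (blockSize - 1) / 6, replicate edges). With \code{polarity = "above"} a
#' pixel is white iff it exceeds the local mean by more than \code{offset};
#' with \code{"below"} iff it falls below it by more than \code{offset}. A
#' positive offset therefore always makes detection stricter, so a constant
#' image yields an all-black mask for any positive offset.
#'
#' @param img single-channel numeric matrix.
#' @param blockSize odd neighbourhood width in pixels, >= 3.
#' @param offset intensity margin added to the local mean.
#' @param polarity "above" (bright objects) or "below" (dark objects).
#' @return binary mask matrix (integer 0/1).
#' @export
adaptiveThreshold <- function(img, blockSize, offset = 0,
                              polarity = c("above", "below")) {
  .assertGrey(img)
  polarity <- match.arg(polarity)
  if (blockSize %% 2 != 1 || blockSize < 3)
    stop("blockSize must be odd and >= 3", call. = FALSE)
  sigma <- (blockSize - 1) / 6
  localMean <- cpp_gaussian_blur(img, sigma, as.integer((blockSize - 1) / 2))
  dev <- img - localMean
  out <- if (polarity == "above") dev > offset else dev < -offset
  .asIntMask(out + 0L)
}

#' Remove small connected components
#'
#' Deletes every connected white component with strictly fewer than
#' \code{minSize} pixels; components of exactly \code{minSize} pixels survive.
#'
#' @param mask binary 0/1 matrix.
#' @param minSize minimum surviving component area in pixels.
#' @param connectivity 4 or 8 (foreground connectivity).
#' @return binary mask, a subset of the input.
#' @export
removeSmallComponents <- function(mask, minSize, connectivity = 8) {
  .assertMask(mask)
  if (!connectivity %in% c(4, 8)) stop("connectivity must be 4 or 8")
  lab <- cpp_label_components(.asIntMask(mask), as.integer(connectivity))
  k <- max(lab)
  if (k == 0L) return(.asIntMask(mask * 0L))
  sizes <- tabulate(lab[lab > 0L], nbins = k)
  keep <- which(sizes >= minSize)
  .asIntMask(matrix((lab %in% keep) + 0L, nrow(mask), ncol(mask)))
}

#' Offsets of a disc structuring element
#'
#' Member offsets are exactly \{(dy, dx) : dy^2 + dx^2 <= radius^2\}.
#'
#' @param radius disc radius in pixels.
#' @return integer matrix (n x 2) of (dy, dx) offsets.
#' @export
discOffsets <- function(radius) {
  r <- floor(radius)
  d <- seq.int(-r, r)
  g <- expand.grid(dy = d, dx = d)
  g <- g[g$dy^2 + g$dx^2 <= radius^2, , drop = FALSE]
  m <- as.matrix(g)
  storage.mode(m) <- "integer"
  dimnames(m) <- NULL
  m
}

#' Morphological closing with a disc
#'
#' Dilation followed by erosion with a disc structuring element. The mask is
#' padded with background by the disc radius before the operation so that the
#' result is extensive (contains the input), idempotent and increasing.
#'
#' @param mask binary 0/1 matrix.
#' @param size disc size parameter.
#' @param sizeIs whether \code{size} is the disc "radius" (default) or
#'   "diameter".
#' @return closed binary mask.
#' @export
morphClose <- function(mask, size, sizeIs = c("radius", "diameter")) {
  .assertMask(mask)
  sizeIs <- match.arg(sizeIs)
  radius <- if (sizeIs == "radius") size else size / 2
  off <- discOffsets(radius)
  r <- as.integer(ceiling(radius))
  h <- nrow(mask); w <- ncol(mask)
  pad <- matrix(0L, h + 2L * r, w + 2L * r)
  pad[(r + 1L):(r + h), (r + 1L):(r + w)] <- mask
  closed <- cpp_binary_erode(cpp_binary_dilate(.asIntMask(pad), off), off)
  .asIntMask(closed[(r + 1L):(r + h), (r + 1L):(r + w), drop = FALSE])
}

#' Maximum filter
#'
#' Replaces every pixel by the maximum over its size x size window; windows
#' are clipped at the image edge. The output dominates the input pixelwise.
#'
#' @param img single-channel numeric matrix.
#' @param size window width in pixels, >= 1.
#' @return filtered matrix.
#' @export
maximumFilter <- function(img, size) {
  .assertGrey(img)
  if (size < 1) stop("size must be >= 1", call. = FALSE)
  cpp_max_filter(img, as.integer(size))
}

#' Euclidean distance transform of a binary mask
#'
#' Every white pixel receives its Euclidean distance to the nearest black
#' pixel minus one, so that white pixels bordering background carry the value
#' zero; black pixels are zero. With \code{normalize = TRUE} values are
#' divided by the image maximum to lie in [0, 1].
#'
#' @param mask binary 0/1 matrix.
#' @param normalize divide by the maximum value (requires at least one black
#'   pixel and one positive distance).
#' @return numeric matrix of distances.
#' @export
distanceTransform <- function(mask, normalize = FALSE) {
  .assertMask(mask)
  if (normalize && all(mask == 1))
    stop("distance undefined: mask has no black pixel", call. = FALSE)
  d <- EBImage::distmap(.asIntMask(mask), metric = "euclidean")
  d <- as.matrix(d)
  d[mask == 1] <- d[mask == 1] - 1
  d[mask == 0] <- 0
  if (normalize) {
    mx <- max(d)
    if (mx > 0) d <- d / mx
  }
  d
}

#' Local Shannon entropy in a disc neighbourhood
#'
#' Per-pixel base-2 entropy of the quantized intensity histogram within a disc
#' of the given radius (neighbourhoods are clipped at the image edge). Binary
#' input is treated as two levels; otherwise intensities in [0, 1] are
#' quantized uniformly into \code{levels} bins.
#'
#' @param img single-channel numeric matrix.
#' @param radius disc radius in pixels.
#' @param levels number of quantization levels; NULL uses 2 for binary input,
#'   256 otherwise.
#' @return numeric matrix of entropies in [0, log2(levels)].
#' @export
localEntropy <- function(img, radius = 3, levels = NULL) {
  .assertGrey(img)
  isBinary <- all(img == 0 | img == 1)
  if (is.null(levels)) levels <- if (isBinary) 2L else 256L
  q <- if (isBinary && levels == 2L) {
    matrix(as.integer(img), nrow(img), ncol(img))
  } else {
    matrix(pmin(as.integer(pmax(img, 0) * levels), levels - 1L),
           nrow(img), ncol(img))
  }
  storage.mode(q) <- "integer"
  cpp_local_entropy(q, discOffsets(radius), as.integer(levels))
}

#' Otsu threshold
#'
#' Exhaustive search for the cut maximizing between-class variance over the
#' image's empirical histogram. Candidate thresholds are midpoints between
#' consecutive distinct values; ties are broken toward the lowest threshold.
#' Depends only on the histogram, never on pixel positions.
#'
#' @param img single-channel numeric matrix with at least two distinct values.
#' @return scalar threshold; pixels strictly above it form the bright class.
#' @export
otsuThreshold <- function(img) {
  .assertGrey(img)
  v <- sort(unique(as.vector(img)))
  if (length(v) < 2L) stop("Otsu threshold undefined for a constant image",
                           call. = FALSE)
  counts <- as.numeric(tabulate(match(as.vector(img), v),
                                nbins = length(v)))
  n <- sum(counts)
  w0 <- cumsum(counts)
  s0 <- cumsum(counts * v)
  tot <- s0[length(s0)]
  k <- seq_len(length(v) - 1L)   # cut after value k
  w1 <- n - w0[k]
  mu0 <- s0[k] / w0[k]
  mu1 <- (tot - s0[k]) / w1
  between <- w0[k] * w1 * (mu0 - mu1)^2
  best <- which.max(between)     # which.max returns the first (lowest) maximum
  (v[best] + v[best + 1L]) / 2
}

#' Iso-level contours by marching squares
#'
#' Extracts sub-pixel iso-level polylines with linear interpolation between
#' pixel centres. Objects not touching the image border yield closed contours.
#'
#' @param img single-channel numeric matrix.
#' @param level iso-level intensity.
#' @return list of contours; each is a numeric matrix (n x 2) of (i, j)
#'   vertices in 0-based pixel-centre coordinates with a logical attribute
#'   \code{"closed"}.
#' @export
marchingSquares <- function(img, level) {
  .assertGrey(img)
  if (min(img) >= level || max(img) < level) return(list())
  cl <- grDevices::contourLines(x = seq_len(nrow(img)) - 1,
                                y = seq_len(ncol(img)) - 1,
                                z = img, levels = level)
  lapply(cl, function(ct) {
    m <- cbind(i = ct$x, j = ct$y)
    n <- nrow(m)
    closed <- n > 2 && sqrt(sum((m[1, ] - m[n, ])^2)) < 1e-8
    if (closed) m <- m[-n, , drop = FALSE]
    attr(m, "closed") <- closed
    m
  })
}

#' Local-maximum markers for watershed seeding
#'
#' Finds local maxima of a surface within a region, then greedily keeps peaks
#' in order of decreasing value (raster order among ties) subject to a
#' minimum pairwise Euclidean distance.
#'
#' @param surface numeric matrix (e.g. a distance transform).
#' @param minDistance minimum distance between accepted markers, >= 1.
#' @param region binary mask restricting the search; NULL means everywhere.
#' @return integer label map with one positive label per marker (labelled in
#'   acceptance order); all-zero when the region is empty.
#' @export
peakMarkers <- function(surface, minDistance = 7, region = NULL) {
  .assertGrey(surface)
  if (minDistance < 1) stop("minDistance must be >= 1", call. = FALSE)
  if (is.null(region)) region <- matrix(1L, nrow(surface), ncol(surface))
  .assertMask(region, "region")
  out <- matrix(0L, nrow(surface), ncol(surface))
  if (!any(region == 1)) return(out)
  win <- 2L * as.integer(ceiling(minDistance)) + 1L
  isMax <- surface >= cpp_max_filter(surface, win) & region == 1
  idx <- which(isMax)
  if (length(idx) == 0L) return(out)
  ii <- (idx - 1L) %% nrow(surface) + 1L
  jj <- (idx - 1L) %/% nrow(surface) + 1L
  ord <- order(-surface[idx], ii, jj)
  ii <- ii[ord]; jj <- jj[ord]
  accI <- numeric(0); accJ <- numeric(0)
  lab <- 0L
  for (k in seq_along(ii)) {
    if (lab > 0L &&
        any((accI - ii[k])^2 + (accJ - jj[k])^2 < minDistance^2)) next
    lab <- lab + 1L
    accI <- c(accI, ii[k]); accJ <- c(accJ, jj[k])
    out[ii[k], jj[k]] <- lab
  }
  out
}

#' Marker-seeded watershed segmentation
#'
#' Floods the region from the markers over the elevation surface (priority
#' flood, 8-connected); every reachable region pixel receives exactly one
#' marker's label, so the labels partition each marker-containing component.
#'
#' @param elevation numeric matrix; lower values are flooded first.
#' @param markers integer label map of seeds; must lie inside \code{region}.
#' @param region binary mask to be partitioned.
#' @return integer label map.
#' @export
watershedSegment <- function(elevation, markers, region) {
  .assertGrey(elevation)
  .assertMask(region, "region")
  if (any(markers > 0 & region == 0))
    stop("markers must lie within the region", call. = FALSE)
  storage.mode(markers) <- "integer"
  cpp_marker_watershed(elevation, markers, .asIntMask(region))
}

#' Extract connected zones from a binary mask
#'
#' A zone is one connected component of white pixels. Components are labelled
#' deterministically in raster order of their first pixel.
#'
#' @param mask binary 0/1 matrix.
#' @param connectivity 4 or 8.
#' @return list of \linkS4class{Zone} objects; empty list for an empty mask.
#' @export
extractZones <- function(mask, connectivity = 8) {
  .assertMask(mask)
  lab <- cpp_label_components(.asIntMask(mask), as.integer(connectivity))
  k <- max(lab)
  if (k == 0L) return(list())
  idx <- which(lab > 0L)
  ii <- (idx - 1L) %% nrow(mask) + 1L
  jj <- (idx - 1L) %/% nrow(mask) + 1L
  lv <- lab[idx]
  lapply(seq_len(k), function(z) {
    sel <- lv == z
    px <- cbind(i = ii[sel], j = jj[sel])
    storage.mode(px) <- "integer"
    new("Zone", pixelSet = px, areaPx = as.integer(sum(sel)))
  })
}

# Shoelace area of a closed polygon given as an n x 2 vertex matrix.
.polygonArea <- function(v) {
  n <- nrow(v)
  if (n < 3) return(0)
  i2 <- c(2:n, 1)
  abs(sum(v[, 1] * v[i2, 2] - v[i2, 1] * v[, 2])) / 2
}

# Ray-casting point-in-polygon test; pt = c(i, j), v = n x 2 vertices.
.pointInPolygon <- function(pt, v) {
  n <- nrow(v)
  j <- n
  inside <- FALSE
  for (k in seq_len(n)) {
    if ((v[k, 2] > pt[2]) != (v[j, 2] > pt[2])) {
      xint <- v[k, 1] + (pt[2] - v[k, 2]) / (v[j, 2] - v[k, 2]) *
        (v[j, 1] - v[k, 1])
      if (pt[1] < xint) inside <- !inside
    }
    j <- k
  }
  inside
}
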
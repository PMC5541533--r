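# Beer-Lambert colour deconvolution of H&E images into
# haematoxylin / eosin / unstained (HEU) concentration channels.

#' Construct and validate a stain matrix
#'
#' Rows are unit optical-density (OD) RGB vectors, one per stain in the order
#' haematoxylin, eosin, unstained/residual. When \code{u} is omitted the third
#' row is the normalized cross product of the first two (the orthogonal
#' residual direction).
#'
#' @param h,e,u numeric length-3 OD vectors (need not be pre-normalized).
#' @return 3x3 numeric matrix with rows H, E, U, each of unit Euclidean norm.
#' @export
stainMatrix <- function(h, e, u = NULL) {
  unit <- function(v) {
    n <- sqrt(sum(v^2))
    if (n < 1e-12) stop("stain vector has zero norm", call. = FALSE)
    v / n
  }
  h <- unit(h); e <- unit(e)
  if (is.null(u)) {
    u <- c(h[2] * e[3] - h[3] * e[2],
           h[3] * e[1] - h[1] * e[3],
           h[1] * e[2] - h[2] * e[1])
    if (sqrt(sum(u^2)) < 1e-6)
      stop("H and E vectors are near-parallel; matrix would be singular",
           call. = FALSE)
  }
  m <- rbind(H = h, E = e, U = unit(u))
  colnames(m) <- c("R", "G", "B")
  if (abs(det(m)) < 1e-8)
    stop("stain matrix is singular", call. = FALSE)
  m
}

#' Default H&E stain matrix
#'
#' Literature OD vectors for haematoxylin and eosin, with a neutral grey
#' unstained row (equal absorption in R, G and B). The grey residual keeps all
#' OD components non-negative, so any non-negative concentration triple maps
#' to a physical transmitted intensity in [0, 1].
#'
#' @return 3x3 stain matrix.
#' @export
defaultStainMatrix <- function() {
  stainMatrix(h = c(0.650, 0.704, 0.286),
              e = c(0.070, 0.990, 0.110),
              u = c(1, 1, 1))
}

# Optical density of an RGB array against a white reference.
.opticalDensity <- function(img, whiteRef, eps = 1e-6) {
  od <- array(0, dim(img))
  for (c in 1:3) od[, , c] <- -log10(pmax(img[, , c], eps) / whiteRef[c])
  od
}

# The unabsorbed illumination per channel. Unstained lumina are the
# brightest legitimate structures, so a trimmed percentile would land inside
# their intensity distribution and clip their optical densities negative;
# the per-channel maximum avoids that (a stray hot pixel only shifts all ODs
# by a constant, which local thresholds ignore).
.estimateWhiteRef <- function(img) {
  vapply(1:3, function(c) max(img[, , c]), numeric(1))
}

#' Calibrate a stain matrix from single-stain images
#'
#' Estimates the H and E optical-density directions as the normalized mean OD
#' vector over stained pixels (pixels whose OD magnitude exceeds
#' \code{odFloor}) of a haematoxylin-only and an eosin-only calibration image;
#' the residual row is their normalized cross product.
#'
#' @param hOnly,eOnly RGB arrays (h, w, 3) in [0, 1] of single-stain slides.
#' @param odFloor minimum OD vector norm for a pixel to count as stained.
#' @param whiteRef per-channel white reference; NULL estimates the
#'   99th-percentile intensity of each calibration image.
#' @return 3x3 stain matrix.
#' @export
calibrateStainMatrix <- function(hOnly, eOnly, odFloor = 0.15,
                                 whiteRef = NULL) {
  meanOd <- function(img) {
    wr <- if (is.null(whiteRef)) .estimateWhiteRef(img) else whiteRef
    od <- .opticalDensity(img, wr)
    odm <- cbind(as.vector(od[, , 1]), as.vector(od[, , 2]),
                 as.vector(od[, , 3]))
    mag <- sqrt(rowSums(odm^2))
    sel <- mag > odFloor
    if (!any(sel))
      stop("calibration image appears blank: no pixel above the OD floor",
           call. = FALSE)
    colMeans(odm[sel, , drop = FALSE])
  }
  stainMatrix(h = meanOd(hOnly), e = meanOd(eOnly))
}

#' Separate an RGB image into stain concentrations
#'
#' Converts intensities to optical densities against the white reference and
#' solves the Beer-Lambert mixing model per pixel: OD = c * M (matrix product) for
#' concentration row-vector c and stain matrix M. Negative concentrations
#' (possible under noise) are clipped to zero.
#'
#' @param img RGB array (h, w, 3) with intensities in [0, 1].
#' @param matrix 3x3 stain matrix (rows H, E, U).
#' @param whiteRef per-channel white reference; NULL estimates the
#'   99th percentile per channel.
#' @return a \linkS4class{StainImage}.
#' @export
separateStains <- function(img, matrix = defaultStainMatrix(),
                           whiteRef = NULL) {
  if (length(dim(img)) != 3L || dim(img)[3] != 3L)
    stop("img must be an RGB (h, w, 3) array", call. = FALSE)
  if (abs(det(matrix)) < 1e-8)
    stop("stain matrix is singular", call. = FALSE)
  wr <- if (is.null(whiteRef)) .estimateWhiteRef(img) else whiteRef
  od <- .opticalDensity(img, wr)
  h <- dim(img)[1]; w <- dim(img)[2]
  odm <- cbind(as.vector(od[, , 1]), as.vector(od[, , 2]),
               as.vector(od[, , 3]))
  conc <- odm %*% solve(matrix)
  conc[conc < 0] <- 0
  new("StainImage",
      conc = array(conc, c(h, w, 3)),
      stainMatrix = matrix, whiteRef = wr)
}

#' Render stain concentrations to RGB (forward Beer-Lambert model)
#'
#' The inverse of \code{\link{separateStains}}: transmitted intensity per
#' channel is the white reference times 10^(-OD), with OD = c times M.
#'
#' @param conc array (h, w, 3) of H, E, U concentrations.
#' @param matrix 3x3 stain matrix.
#' @param whiteRef per-channel white reference intensity.
#' @return RGB array (h, w, 3).
#' @export
stainsToRgb <- function(conc, matrix = defaultStainMatrix(),
                        whiteRef = c(1, 1, 1)) {
  h <- dim(conc)[1]; w <- dim(conc)[2]
  cm <- cbind(as.vector(conc[, , 1]), as.vector(conc[, , 2]),
              as.vector(conc[, , 3]))
  od <- cm %*% matrix
  img <- array(0, c(h, w, 3))
  for (c in 1:3) img[, , c] <- whiteRef[c] * 10^(-od[, c])
  img
}

#' Unstained-to-eosin ratio image
#'
#' Characterizes how unstained each pixel is: U / (E + epsilon), rescaled to
#' [0, 1] by the image maximum. Vein lumina and tissue gaps (high U, little E)
#' appear bright; eosin-rich parenchyma appears dark. The guard epsilon sits
#' on the concentration scale (default 0.02): it bounds the ratio where both
#' stains vanish (glass, tears) so such pixels cannot dominate the
#' normalization.
#'
#' @param stains a \linkS4class{StainImage}.
#' @param epsilon positive guard added to the eosin channel.
#' @return numeric matrix in [0, 1].
#' @export
unstainedRatio <- function(stains, epsilon = 0.02) {
  stopifnot(is(stains, "StainImage"))
  if (epsilon <= 0) stop("epsilon must be positive", call. = FALSE)
  r <- uChannel(stains) / (eChannel(stains) + epsilon)
  mx <- max(r)
  if (mx > 0) r <- r / mx
  r
}
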
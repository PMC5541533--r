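# Pixel- and zone-level agreement statistics between an algorithm mask I and
# an operator mask T, density measures, and the robust regression used to
# compare algorithm against operator across a cohort.

.assertSameShape <- function(a, b) {
  if (!identical(dim(a), dim(b)))
    .stopValidation(sprintf("mask shapes differ: %s vs %s",
                            paste(dim(a), collapse = "x"),
                            paste(dim(b), collapse = "x")))
}

#' Logical conjunction of two binary masks
#'
#' A pixel is white iff it is white in both inputs. Commutative and
#' idempotent.
#'
#' @param a,b binary 0/1 matrices of identical shape.
#' @return binary mask.
#' @export
maskConjunction <- function(a, b) {
  .assertMask(a, "a"); .assertMask(b, "b")
  .assertSameShape(a, b)
  .asIntMask((a == 1 & b == 1) + 0L)
}

#' Pixel-level disagreement scores
#'
#' \code{mP} is the fraction of all pixels white in the algorithm mask but
#' not the operator mask (false positives), \code{mN} the fraction white in
#' the operator mask but not the algorithm mask (false negatives), and
#' \code{m = mP + mN} the total mislabelled fraction. The denominator is the
#' total pixel count.
#'
#' @param iMask algorithm binary mask I.
#' @param tMask operator binary mask T.
#' @return a \linkS4class{PixelScores}.
#' @export
pixelScores <- function(iMask, tMask) {
  .assertMask(iMask, "iMask"); .assertMask(tMask, "tMask")
  .assertSameShape(iMask, tMask)
  S <- length(iMask)
  mP <- sum(iMask == 1 & tMask == 0) / S
  mN <- sum(tMask == 1 & iMask == 0) / S
  new("PixelScores", mP = mP, mN = mN, m = mP + mN)
}

# Per-zone overlap fractions of the zones of `zoneMask` with `otherMask`.
.zoneOverlapFractions <- function(zoneMask, otherMask, connectivity) {
  lab <- cpp_label_components(.asIntMask(zoneMask),
                              as.integer(connectivity))
  k <- max(lab)
  if (k == 0L) return(numeric(0))
  sizes <- tabulate(lab[lab > 0L], nbins = k)
  inter <- tabulate(lab[lab > 0L & otherMask == 1], nbins = k)
  inter / sizes
}

#' Zone validity score F_A
#'
#' The fraction of algorithm zones (connected components of \code{iMask})
#' sharing at least \code{threshold} of their pixels with the operator mask.
#' Undefined (NA) when the algorithm mask has no zones.
#'
#' @param iMask,tMask binary masks of identical shape.
#' @param threshold minimum shared-pixel fraction (default 0.8, "at least
#'   80 percent").
#' @param connectivity zone connectivity, 4 or 8.
#' @return a \linkS4class{ZoneAgreement} with the validity part filled in.
#' @export
zoneValidity <- function(iMask, tMask, threshold = 0.8, connectivity = 8) {
  .assertMask(iMask, "iMask"); .assertMask(tMask, "tMask")
  .assertSameShape(iMask, tMask)
  ov <- .zoneOverlapFractions(iMask, tMask, connectivity)
  nz <- length(ov); nv <- sum(ov >= threshold)
  new("ZoneAgreement",
      fA = if (nz == 0L) NA_real_ else nv / nz,
      fG = NA_real_,
      counts = c(validated = as.integer(nv), algorithmZones = as.integer(nz),
                 recalled = 0L, operatorZones = 0L))
}

#' Zone recall score F_G
#'
#' The fraction of operator zones (connected components of \code{tMask}) at
#' least \code{threshold} covered by the algorithm mask. Undefined (NA) when
#' the operator mask has no zones.
#'
#' @param iMask,tMask binary masks of identical shape.
#' @param threshold minimum coverage (default 0.5, "at least 50 percent";
#'   relaxing to one quarter is a supported variant).
#' @param connectivity zone connectivity, 4 or 8.
#' @return a \linkS4class{ZoneAgreement} with the recall part filled in.
#' @export
zoneRecall <- function(iMask, tMask, threshold = 0.5, connectivity = 8) {
  .assertMask(iMask, "iMask"); .assertMask(tMask, "tMask")
  .assertSameShape(iMask, tMask)
  cov <- .zoneOverlapFractions(tMask, iMask, connectivity)
  nz <- length(cov); nr <- sum(cov >= threshold)
  new("ZoneAgreement",
      fA = NA_real_, fG = if (nz == 0L) NA_real_ else nr / nz,
      counts = c(validated = 0L, algorithmZones = 0L,
                 recalled = as.integer(nr), operatorZones = as.integer(nz)))
}

#' Combined zone agreement (validity and recall)
#'
#' @param iMask,tMask binary masks of identical shape.
#' @param validityThreshold,recallThreshold the F_A and F_G thresholds.
#' @param connectivity zone connectivity, 4 or 8.
#' @return a \linkS4class{ZoneAgreement}.
#' @export
zoneAgreement <- function(iMask, tMask, validityThreshold = 0.8,
                          recallThreshold = 0.5, connectivity = 8) {
  va <- zoneValidity(iMask, tMask, validityThreshold, connectivity)
  rc <- zoneRecall(iMask, tMask, recallThreshold, connectivity)
  cnt <- zoneCounts(va)
  cnt[c("recalled", "operatorZones")] <-
    zoneCounts(rc)[c("recalled", "operatorZones")]
  new("ZoneAgreement", fA = agreementScores(va)[["fA"]],
      fG = agreementScores(rc)[["fG"]], counts = cnt)
}

#' Pixel area from field-of-view and sensor dimensions
#'
#' @param fovHeightMm,fovWidthMm imaged field of view in millimetres.
#' @param rows,cols sensor size in pixels.
#' @return pixel area in square micrometres.
#' @export
pixelAreaFromFov <- function(fovHeightMm, fovWidthMm, rows, cols) {
  vals <- c(fovHeightMm, fovWidthMm, rows, cols)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all field-of-view and sensor dimensions must be positive",
         call. = FALSE)
  (fovHeightMm * fovWidthMm * 1e6) / (rows * cols)
}

#' Nuclear density in a region
#'
#' Counts nucleus centroids falling inside the region and divides by the
#' region's physical area, reported per 1000 square micrometres. To compute
#' the whole-image density excluding the central inflammatory focus, pass
#' \code{region = 1 - focusRaster(focus)}.
#'
#' @param nuclei a \linkS4class{NucleusSet} or an (n x 2) matrix of (i, j)
#'   centroids (1-based pixel coordinates).
#' @param region binary 0/1 matrix; must contain at least one white pixel.
#' @param pixelAreaUm2 pixel area in square micrometres.
#' @return nuclei per 1000 square micrometres.
#' @export
nuclearDensity <- function(nuclei, region, pixelAreaUm2) {
  cent <- if (is(nuclei, "NucleusSet")) centroids(nuclei) else nuclei
  .assertMask(region, "region")
  if (!any(region == 1)) stop("region is empty", call. = FALSE)
  if (nrow(cent) > 0) {
    ii <- pmin(pmax(round(cent[, 1]), 1), nrow(region))
    jj <- pmin(pmax(round(cent[, 2]), 1), ncol(region))
    n <- sum(region[cbind(ii, jj)] == 1)
  } else n <- 0L
  n / (sum(region == 1) * pixelAreaUm2) * 1000
}

#' Robust linear regression with bootstrap confidence intervals
#'
#' Huber M-estimation (tuning constant 1.345) of \code{y} on \code{x},
#' with the coefficient of determination reported as the squared Pearson
#' correlation and 95 percent percentile bootstrap intervals over case
#' resampling. The bootstrap is fully reproducible from \code{seed}.
#'
#' @param x,y numeric vectors of equal length, n >= 3.
#' @param bootstrapReps number of bootstrap resamples.
#' @param seed integer RNG seed (required, for reproducibility).
#' @return a \linkS4class{RegressionReport}.
#' @export
huberFit <- function(x, y, bootstrapReps = 1000, seed) {
  if (length(x) != length(y)) stop("x and y must have equal length",
                                   call. = FALSE)
  n <- length(x)
  if (n < 3) stop("need at least 3 points", call. = FALSE)
  if (stats::var(x) == 0) stop("x is degenerate (zero variance)",
                               call. = FALSE)
  if (missing(seed)) stop("a seed is required", call. = FALSE)
  fitOne <- function(xx, yy) {
    fit <- suppressWarnings(
      MASS::rlm(yy ~ xx, psi = MASS::psi.huber, k = 1.345, maxit = 100))
    stats::coef(fit)
  }
  cf <- fitOne(x, y)
  r2 <- stats::cor(x, y)^2
  boots <- .withSeed(seed, {
    t(vapply(seq_len(bootstrapReps), function(b) {
      idx <- sample.int(n, n, replace = TRUE)
      if (stats::var(x[idx]) == 0) return(c(NA_real_, NA_real_))
      tryCatch(fitOne(x[idx], y[idx]),
               error = function(e) c(NA_real_, NA_real_))
    }, numeric(2)))
  })
  ciI <- stats::quantile(boots[, 1], c(0.025, 0.975), na.rm = TRUE,
                         names = FALSE)
  ciS <- stats::quantile(boots[, 2], c(0.025, 0.975), na.rm = TRUE,
                         names = FALSE)
  new("RegressionReport", slope = unname(cf[2]), intercept = unname(cf[1]),
      r2 = r2, ciSlope = ciS, ciIntercept = ciI, n = as.integer(n),
      bootstrapReps = as.integer(bootstrapReps))
}
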
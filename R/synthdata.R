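# Seeded generator of H&E-like scenes with exact ground truth.
#
# Scenes are rendered at the native pixel resolutions of the two
# magnifications (widefield capture 0.579 um/px, narrowfield 0.231 um/px) but
# over reduced fields of view, so that structure sizes in pixels - and hence
# all pixel-denominated algorithm parameters - match the full-size imagery.

#' Degradation specification
#'
#' Controls the "high-variance" artefacts layered over a clean rendering:
#' a linear luminosity gradient across the frame, per-channel stain-intensity
#' shifts (applied in optical-density space), additive Gaussian sensor noise,
#' thin white tear polylines, and defocus blur. A zero specification leaves
#' the image untouched.
#'
#' @param luminosityGradient peak relative luminosity change across the frame
#'   (0.15 = +/-15 percent).
#' @param stainGainJitter length-2 multiplicative range for per-channel
#'   optical-density gain.
#' @param noiseSd standard deviation of additive intensity noise.
#' @param tearCount number of tear polylines.
#' @param blurSd Gaussian defocus sigma in pixels.
#' @return list of class "degradationSpec".
#' @export
degradationSpec <- function(luminosityGradient = 0.15,
                            stainGainJitter = c(0.9, 1.1),
                            noiseSd = 0.02, tearCount = 0, blurSd = 0.3) {
  stopifnot(luminosityGradient >= 0, length(stainGainJitter) == 2L,
            all(stainGainJitter > 0), noiseSd >= 0, tearCount >= 0,
            blurSd >= 0)
  structure(list(luminosityGradient = luminosityGradient,
                 stainGainJitter = sort(stainGainJitter),
                 noiseSd = noiseSd, tearCount = as.integer(tearCount),
                 blurSd = blurSd),
            class = "degradationSpec")
}

#' Clean (identity) degradation
#' @return a zero \code{\link{degradationSpec}}.
#' @export
cleanDegradation <- function() {
  degradationSpec(luminosityGradient = 0, stainGainJitter = c(1, 1),
                  noiseSd = 0, tearCount = 0, blurSd = 0)
}

#' Scene specification
#'
#' Defaults emulate the imaged tissue: eosin-pink parenchyma, sparse
#' hepatocyte nuclei, dense clusters of smaller immune nuclei (inflammatory
#' foci; immune cells have a higher nucleus-to-cytoplasm ratio), unstained
#' vein lumina, and the default degradation. The widefield kind is rendered
#' at capture resolution (to be downscaled by the pipeline); the narrowfield
#' kind at its native resolution with the focus centred in the frame.
#'
#' @param kind "widefield" or "narrowfield".
#' @param seed integer; fixes the scene byte-exactly.
#' @param size c(height, width) in pixels.
#' @param pixelSizeUm pixel side length in micrometres.
#' @param nFoci number of inflammatory foci.
#' @param focusRadiiUm range of focus radii in micrometres.
#' @param backgroundNucleusRate hepatocyte nuclei per 1000 square micrometres.
#' @param focusDensityMultiplier immune-nucleus rate multiplier inside foci.
#' @param nVeins number of vein lumina.
#' @param veinRadiiUm range of vein semi-major radii in micrometres.
#' @param hepatocyteRadiusUm hepatocyte nucleus radius; immune nuclei are
#'   half this size.
#' @param maxOverlapFrac maximum allowed pairwise nucleus overlap depth as a
#'   fraction of the sum of radii.
#' @param stainMatrix 3x3 stain matrix used for Beer-Lambert rendering.
#' @param degradation a \code{\link{degradationSpec}}.
#' @return list of class "sceneSpec".
#' @export
sceneSpec <- function(kind = c("widefield", "narrowfield"), seed = 1L,
                      size = NULL, pixelSizeUm = NULL,
                      nFoci = NULL, focusRadiiUm = NULL,
                      backgroundNucleusRate = 1.5,
                      focusDensityMultiplier = 18,
                      nVeins = NULL, veinRadiiUm = NULL,
                      hepatocyteRadiusUm = 4.5, maxOverlapFrac = 0.15,
                      stainMatrix = defaultStainMatrix(),
                      degradation = NULL) {
  kind <- match.arg(kind)
  if (kind == "widefield") {
    if (is.null(size)) size <- c(768L, 1152L)
    if (is.null(pixelSizeUm)) pixelSizeUm <- 2000 / 3456   # capture scale
    if (is.null(nFoci)) nFoci <- 2L
    if (is.null(focusRadiiUm)) focusRadiiUm <- c(40, 70)
    if (is.null(nVeins)) nVeins <- 2L
    if (is.null(veinRadiiUm)) veinRadiiUm <- c(25, 55)
    if (is.null(degradation)) degradation <- degradationSpec(tearCount = 1)
  } else {
    if (is.null(size)) size <- c(512L, 768L)
    if (is.null(pixelSizeUm)) pixelSizeUm <- 800 / 3456    # native scale
    if (is.null(nFoci)) nFoci <- 1L
    if (is.null(focusRadiiUm)) focusRadiiUm <- c(28, 42)
    if (is.null(nVeins)) nVeins <- 0L
    if (is.null(veinRadiiUm)) veinRadiiUm <- c(10, 20)
    if (is.null(degradation)) degradation <- degradationSpec(tearCount = 0)
  }
  stopifnot(all(size >= 32), pixelSizeUm > 0, nFoci >= 0,
            all(focusRadiiUm > 0), backgroundNucleusRate > 0,
            focusDensityMultiplier >= 1, nVeins >= 0, hepatocyteRadiusUm > 0,
            maxOverlapFrac >= 0, maxOverlapFrac < 1)
  structure(list(kind = kind, seed = as.integer(seed),
                 size = as.integer(size), pixelSizeUm = pixelSizeUm,
                 nFoci = as.integer(nFoci), focusRadiiUm = focusRadiiUm,
                 backgroundNucleusRate = backgroundNucleusRate,
                 focusDensityMultiplier = focusDensityMultiplier,
                 nVeins = as.integer(nVeins), veinRadiiUm = veinRadiiUm,
                 hepatocyteRadiusUm = hepatocyteRadiusUm,
                 maxOverlapFrac = maxOverlapFrac, stainMatrix = stainMatrix,
                 degradation = degradation),
            class = "sceneSpec")
}

# Smooth spatial noise field: blurred white noise scaled to a given sd.
.smoothNoise <- function(h, w, sigma, sd) {
  n <- matrix(stats::rnorm(h * w), h, w)
  n <- cpp_gaussian_blur(n, sigma, as.integer(ceiling(3 * sigma)))
  s <- stats::sd(n)
  if (s > 0) n <- n * (sd / s)
  n
}

# Fill an ellipse into a mask; returns linear pixel indices.
.ellipseIndices <- function(h, w, ci, cj, a, b, theta) {
  r <- ceiling(max(a, b))
  i0 <- max(1, floor(ci - r)); i1 <- min(h, ceiling(ci + r))
  j0 <- max(1, floor(cj - r)); j1 <- min(w, ceiling(cj + r))
  if (i0 > i1 || j0 > j1) return(integer(0))
  ii <- i0:i1; jj <- j0:j1
  di <- outer(ii - ci, rep(1, length(jj)))
  dj <- outer(rep(1, length(ii)), jj - cj)
  u <- (di * cos(theta) + dj * sin(theta)) / a
  v <- (-di * sin(theta) + dj * cos(theta)) / b
  sel <- which(u^2 + v^2 <= 1, arr.ind = TRUE)
  if (nrow(sel) == 0) return(integer(0))
  (jj[sel[, 2]] - 1L) * h + ii[sel[, 1]]
}

#' Degrade a rendered image
#'
#' Applies, in order: luminosity gradient, per-channel stain-gain jitter (a
#' power law in intensity, i.e. a linear gain in optical density), additive
#' Gaussian noise, white tear polylines, and defocus blur; the result is
#' clipped to [0, 1]. A zero specification returns the input unchanged.
#'
#' @param img RGB array (h, w, 3) in [0, 1].
#' @param spec a \code{\link{degradationSpec}}.
#' @param seed integer RNG seed.
#' @return degraded RGB array.
#' @export
degradeImage <- function(img, spec, seed) {
  stopifnot(inherits(spec, "degradationSpec"))
  h <- dim(img)[1]; w <- dim(img)[2]
  .withSeed(seed, {
    if (spec$luminosityGradient > 0) {
      ang <- stats::runif(1, 0, 2 * pi)
      ic <- (seq_len(h) - (h + 1) / 2) / (h / 2)
      jc <- (seq_len(w) - (w + 1) / 2) / (w / 2)
      t <- outer(ic * cos(ang), rep(1, w)) + outer(rep(1, h), jc * sin(ang))
      t <- t / max(abs(t))
      grad <- 1 + spec$luminosityGradient * t
      for (c in 1:3) img[, , c] <- img[, , c] * grad
    }
    if (!all(spec$stainGainJitter == 1)) {
      g <- stats::runif(3, spec$stainGainJitter[1], spec$stainGainJitter[2])
      for (c in 1:3) img[, , c] <- pmin(img[, , c], 1)^g[c]
    }
    if (spec$noiseSd > 0)
      img <- img + array(stats::rnorm(length(img), 0, spec$noiseSd), dim(img))
    if (spec$tearCount > 0) {
      tear <- matrix(0L, h, w)
      for (k in seq_len(spec$tearCount)) {
        pi0 <- stats::runif(1, 0.2 * h, 0.8 * h)
        pj0 <- stats::runif(1, 0.2 * w, 0.8 * w)
        ang <- stats::runif(1, 0, 2 * pi)
        len <- stats::runif(1, 0.25, 0.45) * min(h, w)
        halfw <- stats::runif(1, 1, 1.6)
        steps <- seq(0, len, by = 1)
        wander <- cumsum(stats::rnorm(length(steps), 0, 0.03))
        for (s in seq_along(steps)) {
          a2 <- ang + wander[s]
          ci <- pi0 + steps[s] * sin(a2)
          cj <- pj0 + steps[s] * cos(a2)
          tear[.ellipseIndices(h, w, ci, cj, halfw, halfw, 0)] <- 1L
        }
      }
      for (c in 1:3) {
        ch <- img[, , c]
        ch[tear == 1L] <- 0.99
        img[, , c] <- ch
      }
    }
    if (spec$blurSd > 0)
      for (c in 1:3)
        img[, , c] <- cpp_gaussian_blur(img[, , c], spec$blurSd,
                                        as.integer(ceiling(3 * spec$blurSd)))
  })
  img[img < 0] <- 0
  img[img > 1] <- 1
  img
}

#' Generate a synthetic H&E scene with exact ground truth
#'
#' Places vein ellipses and focus discs, scatters hepatocyte nuclei as a
#' spatial Poisson process over the tissue (excluded from vein lumina) and
#' smaller immune nuclei at \code{focusDensityMultiplier} times the background
#' rate inside each focus, renders stain-concentration maps to RGB through
#' the Beer-Lambert model, then applies the degradation. All randomness is
#' drawn from one generator seeded by \code{spec$seed}; the same spec yields
#' a byte-identical scene. Ground-truth masks reflect the generated geometry
#' and are untouched by degradation.
#'
#' @param spec a \code{\link{sceneSpec}}.
#' @return a \linkS4class{SyntheticScene}.
#' @export
generateScene <- function(spec) {
  stopifnot(inherits(spec, "sceneSpec"))
  h <- spec$size[1]; w <- spec$size[2]
  px <- spec$pixelSizeUm
  pxArea <- px^2
  rHep <- spec$hepatocyteRadiusUm / px
  rImm <- rHep / 2
  out <- .withSeed(spec$seed, {
    # concentration fields
    eConc <- pmax(0.55 + .smoothNoise(h, w, 8, 0.05), 0)
    hConc <- pmax(0.05 + .smoothNoise(h, w, 8, 0.01), 0)
    uConc <- pmax(0.04 + .smoothNoise(h, w, 8, 0.008), 0)

    # veins
    veinMask <- matrix(0L, h, w)
    veinPars <- matrix(0, 0, 3)  # ci, cj, rmax
    for (k in seq_len(spec$nVeins)) {
      a <- stats::runif(1, spec$veinRadiiUm[1], spec$veinRadiiUm[2]) / px
      b <- a * stats::runif(1, 0.55, 0.95)
      theta <- stats::runif(1, 0, pi)
      placed <- FALSE
      for (try in 1:200) {
        ci <- stats::runif(1, a + 5, h - a - 5)
        cj <- stats::runif(1, a + 5, w - a - 5)
        if (nrow(veinPars) == 0 ||
            all(sqrt((veinPars[, 1] - ci)^2 + (veinPars[, 2] - cj)^2) >
                veinPars[, 3] + a + 10)) {
          placed <- TRUE; break
        }
      }
      if (!placed) next
      idx <- .ellipseIndices(h, w, ci, cj, a, b, theta)
      veinMask[idx] <- 1L
      veinPars <- rbind(veinPars, c(ci, cj, a))
    }
    eConc[veinMask == 1L] <- eConc[veinMask == 1L] * 0.05
    hConc[veinMask == 1L] <- hConc[veinMask == 1L] * 0.15
    uConc[veinMask == 1L] <- 0.22

    # foci
    focusMask <- matrix(0L, h, w)
    fociPars <- matrix(0, 0, 3)  # ci, cj, r (placement radius, px)
    for (k in seq_len(spec$nFoci)) {
      r <- stats::runif(1, spec$focusRadiiUm[1], spec$focusRadiiUm[2]) / px
      margin <- r + rImm + 5
      if (2 * margin >= min(h, w))
        stop("geometric infeasibility: focus cannot fit in the frame",
             call. = FALSE)
      placed <- FALSE
      for (try in 1:200) {
        if (spec$kind == "narrowfield" && k == 1L) {
          ci <- (h + 1) / 2 + stats::runif(1, -8, 8)
          cj <- (w + 1) / 2 + stats::runif(1, -8, 8)
        } else {
          ci <- stats::runif(1, margin, h - margin)
          cj <- stats::runif(1, margin, w - margin)
        }
        okVein <- nrow(veinPars) == 0 ||
          all(sqrt((veinPars[, 1] - ci)^2 + (veinPars[, 2] - cj)^2) >
              veinPars[, 3] + r + 10)
        okFoci <- nrow(fociPars) == 0 ||
          all(sqrt((fociPars[, 1] - ci)^2 + (fociPars[, 2] - cj)^2) >
              fociPars[, 3] + r + 20)
        if (okVein && okFoci) { placed <- TRUE; break }
      }
      if (!placed)
        stop("geometric infeasibility: could not place all foci",
             call. = FALSE)
      fociPars <- rbind(fociPars, c(ci, cj, r))
      # ground truth includes the nuclear material extending past the
      # centre-placement disc
      focusMask[.ellipseIndices(h, w, ci, cj, r + rImm, r + rImm, 0)] <- 1L
    }

    # nuclei: background hepatocytes (Poisson over tissue), immune in foci
    accI <- numeric(0); accJ <- numeric(0); accR <- numeric(0)
    accType <- character(0)
    tryPlace <- function(ci, cj, r) {
      if (ci < 1 || ci > h || cj < 1 || cj > w) return(FALSE)
      if (veinMask[round(ci), round(cj)] == 1L) return(FALSE)
      if (length(accI) > 0) {
        d2 <- (accI - ci)^2 + (accJ - cj)^2
        lim <- ((1 - spec$maxOverlapFrac) * (accR + r))^2
        if (any(d2 < lim)) return(FALSE)
      }
      TRUE
    }
    areaUm2 <- h * w * pxArea
    nBg <- stats::rpois(1, spec$backgroundNucleusRate * areaUm2 / 1000)
    for (k in seq_len(nBg)) {
      for (try in 1:40) {
        ci <- stats::runif(1, 1, h); cj <- stats::runif(1, 1, w)
        if (tryPlace(ci, cj, rHep)) {
          accI <- c(accI, ci); accJ <- c(accJ, cj); accR <- c(accR, rHep)
          accType <- c(accType, "hepatocyte")
          break
        }
      }
    }
    for (f in seq_len(nrow(fociPars))) {
      ci0 <- fociPars[f, 1]; cj0 <- fociPars[f, 2]; r0 <- fociPars[f, 3]
      focArea <- pi * r0^2 * pxArea
      nImm <- stats::rpois(1, spec$backgroundNucleusRate *
                              spec$focusDensityMultiplier * focArea / 1000)
      for (k in seq_len(nImm)) {
        for (try in 1:80) {
          rad <- r0 * sqrt(stats::runif(1))
          ang <- stats::runif(1, 0, 2 * pi)
          ci <- ci0 + rad * sin(ang); cj <- cj0 + rad * cos(ang)
          if (tryPlace(ci, cj, rImm)) {
            accI <- c(accI, ci); accJ <- c(accJ, cj); accR <- c(accR, rImm)
            accType <- c(accType, "immune")
            break
          }
        }
      }
    }

    # render nuclei as ellipses
    for (k in seq_along(accI)) {
      q <- sqrt(stats::runif(1, 0.75, 1))
      theta <- stats::runif(1, 0, pi)
      conc <- if (accType[k] == "immune") 0.75 + stats::runif(1, 0, 0.15)
              else 0.5 + stats::runif(1, 0, 0.15)
      idx <- .ellipseIndices(h, w, accI[k], accJ[k],
                             accR[k] * q, accR[k] / q, theta)
      hConc[idx] <- hConc[idx] + conc
      eConc[idx] <- eConc[idx] * 0.7
    }

    concArr <- array(c(hConc, eConc, uConc), c(h, w, 3))
    img <- stainsToRgb(concArr, spec$stainMatrix, whiteRef = c(1, 1, 1))
    list(img = img, focusMask = focusMask, veinMask = veinMask,
         centroids = cbind(i = accI, j = accJ), type = accType)
  })
  img <- degradeImage(out$img, spec$degradation,
                      seed = spec$seed + 1000003L)
  new("SyntheticScene", image = img, focusMask = out$focusMask,
      veinMask = out$veinMask, centroids = out$centroids,
      nucleusType = out$type, spec = unclass(spec))
}
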
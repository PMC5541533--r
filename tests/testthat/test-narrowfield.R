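test_that("nucleus binarization hits true centroids and rejects specks", {
  scene <- cachedScene("nf1", smallNarrowfieldSpec(seed = 2))
  nuc <- binarizeNuclei(sceneImage(scene), smallNarrowfieldParams())
  cent <- centroids(scene)
  idx <- cbind(pmin(pmax(round(cent[, 1]), 1), nrow(nuc)),
               pmin(pmax(round(cent[, 2]), 1), ncol(nuc)))
  expect_gte(mean(nuc[idx] == 1), 0.95)
  # a 50-px dark speck is removed by the 100-px-or-less rule
  conc <- array(0, c(128, 128, 3))
  conc[, , 2] <- 0.5
  speck <- discMask(128, 128, 64, 64, 4)       # ~49 px
  expect_lte(sum(speck), 100)
  conc[, , 1][speck == 1] <- 1.2
  img <- stainsToRgb(conc, whiteRef = c(1, 1, 1))
  expect_equal(sum(binarizeNuclei(img, smallNarrowfieldParams())), 0L)
  # nucleus-free tissue
  blank <- stainsToRgb(array(rep(c(0, 0.5, 0.03), each = 128 * 128),
                             c(128, 128, 3)), whiteRef = c(1, 1, 1))
  expect_equal(sum(binarizeNuclei(blank, smallNarrowfieldParams())), 0L)
})

test_that("focus saliency orders focus above background and shifts with the mask", {
  expect_true(all(focusSaliency(matrix(0L, 64, 64),
                                smallNarrowfieldParams()) == 0))
  scene <- cachedScene("nf1", smallNarrowfieldSpec(seed = 2))
  nuc <- binarizeNuclei(sceneImage(scene), smallNarrowfieldParams())
  sal <- focusSaliency(nuc, smallNarrowfieldParams())
  gt <- focusMask(scene)
  expect_gt(mean(sal[gt == 1]), mean(sal[gt == 0]))
  expect_true(all(sal >= 0 & sal <= 1))
  # translation equivariance away from borders
  p <- smallNarrowfieldParams()
  blob <- matrix(0L, 300, 300)
  blob[discMask(300, 300, 140, 140, 18) == 1] <- 1L
  s1 <- focusSaliency(blob, p)
  blob2 <- matrix(0L, 300, 300)
  blob2[discMask(300, 300, 160, 160, 18) == 1] <- 1L
  s2 <- focusSaliency(blob2, p)
  expect_equal(s1[120:160, 120:160], s2[140:180, 140:180], tolerance = 1e-6)
})

test_that("focus contour recovers the central focus area fraction", {
  scene <- cachedScene("nf1", smallNarrowfieldSpec(seed = 2))
  nuc <- binarizeNuclei(sceneImage(scene), smallNarrowfieldParams())
  fc <- extractFocusContour(focusSaliency(nuc, smallNarrowfieldParams()))
  expect_false(isEmptyFocus(fc))
  expect_lte(abs(focusAreaFraction(fc) - mean(focusMask(scene))), 0.05)
  # polygon area and raster footprint agree within 2%
  expect_lte(abs(focusAreaPx(fc) - sum(focusRaster(fc))) / focusAreaPx(fc),
             0.02)
})

test_that("contour selection prefers the centre-enclosing object", {
  # two bumps: large off-centre, small enclosing the centre
  sal <- matrix(0.02, 120, 160)
  big <- discMask(120, 160, 30, 40, 25)
  small <- discMask(120, 160, 60, 80, 12)
  sal[big == 1] <- 0.9
  sal[small == 1] <- 0.9
  fc <- extractFocusContour(sal)
  cent <- colMeans(contourVertices(fc))
  expect_lt(sqrt(sum((cent - c(59.5, 79.5))^2)), 4)
  expect_lt(focusAreaPx(fc), sum(big))
  # uniform saliency -> explicit empty result
  expect_true(isEmptyFocus(extractFocusContour(matrix(0.4, 50, 50))))
})

test_that("watershed nucleus counting splits twins and matches disjoint k", {
  # twin peaks: two fused discs count as two nuclei
  two <- matrix(as.integer(discMask(60, 60, 30, 24, 9) |
                             discMask(60, 60, 30, 38, 9)), 60, 60)
  ns2 <- segmentNuclei(two, minDistance = 7)
  expect_equal(nucleusCount(ns2), 2L)
  # k disjoint discs
  k5 <- matrix(0L, 80, 80)
  for (c in list(c(15, 15), c(15, 60), c(45, 30), c(65, 60), c(65, 12)))
    k5[discMask(80, 80, c[1], c[2], 7) == 1] <- 1L
  ns5 <- segmentNuclei(k5, minDistance = 7)
  expect_equal(nucleusCount(ns5), 5L)
  # labels partition the mask exactly
  expect_equal(sum(labelMap(ns5) > 0), sum(k5))
  expect_equal(nrow(centroids(ns5)), 5L)
  # centroids inside their own label's footprint
  for (k in seq_len(5)) {
    ci <- round(centroids(ns5)[k, ])
    expect_equal(labelMap(ns5)[ci[1], ci[2]], k)
  }
  # empty mask
  ns0 <- segmentNuclei(matrix(0L, 10, 10))
  expect_equal(nucleusCount(ns0), 0L)
})

test_that("scene-level nucleus recovery stays within 10% at limited overlap", {
  scene <- cachedScene("nf1", smallNarrowfieldSpec(seed = 2))
  nuc <- binarizeNuclei(sceneImage(scene), smallNarrowfieldParams())
  ns <- segmentNuclei(nuc, minDistance = 7)
  nTrue <- nrow(centroids(scene))
  expect_lte(abs(nucleusCount(ns) - nTrue) / nTrue, 0.10)
  expect_equal(sum(labelMap(ns) > 0), sum(nuc))
})

test_that("the narrowfield pipeline bundles consistent results", {
  scene <- cachedScene("nf1", smallNarrowfieldSpec(seed = 2))
  cfg <- pipelineConfig()
  cfg$narrowfield$params <- smallNarrowfieldParams()
  res <- narrowfieldPipeline(sceneImage(scene), cfg,
                             pixelAreaUm2 = sceneSpecOf(scene)$pixelSizeUm^2)
  expect_s4_class(res, "NarrowfieldResult")
  ns <- nucleusSet(res)
  expect_equal(sum(labelMap(ns) > 0), sum(nucleusMask(res)))
  # density inside the focus exceeds the outside density
  pxA <- sceneSpecOf(scene)$pixelSizeUm^2
  dIn <- nuclearDensity(ns, focusMask(scene), pxA)
  dOut <- nuclearDensity(ns, matrix(1L - focusMask(scene),
                                    nrow(focusMask(scene))), pxA)
  expect_gt(dIn, dOut)
})
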
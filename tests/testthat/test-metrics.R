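test_that("mask conjunction is a logical AND with its algebra", {
  set.seed(1)
  a <- randomMask(8, 8); b <- randomMask(8, 8)
  expect_equal(maskConjunction(a, b), matrix(as.integer(a & b), 8, 8))
  expect_equal(maskConjunction(a, a), a)
  expect_true(all(maskConjunction(a, a * 0L) == 0))
  expect_equal(maskConjunction(a, b), maskConjunction(b, a))
  expect_error(maskConjunction(a, randomMask(8, 9)), "shapes")
})

test_that("pixel scores follow the disagreement-fraction definitions", {
  t4 <- matrix(0L, 4, 4); t4[2:3, 2:3] <- 1L
  i4 <- t4; i4[1, 1] <- 1L; i4[4, 4] <- 1L
  s <- pixelFractions(pixelScores(i4, t4))
  expect_equal(unname(s), c(2 / 16, 0, 2 / 16))
  expect_equal(unname(pixelFractions(pixelScores(t4, t4))), c(0, 0, 0))
  allW <- matrix(1L, 4, 4); allB <- matrix(0L, 4, 4)
  expect_equal(unname(pixelFractions(pixelScores(allW, allB))), c(1, 0, 1))
  # swap symmetry and exact conservation on random pairs
  set.seed(2)
  for (k in 1:25) {
    a <- randomMask(12, 12, runif(1)); b <- randomMask(12, 12, runif(1))
    sa <- pixelFractions(pixelScores(a, b))
    sb <- pixelFractions(pixelScores(b, a))
    expect_identical(sa[["m"]], sa[["mP"]] + sa[["mN"]])
    expect_equal(sa[["mP"]], sb[["mN"]])
    expect_equal(unname(sa), unname(oraclePixelScores(a, b)))
  }
})

test_that("zone validity and recall enumerate per-zone overlaps", {
  # two algorithm zones: one fully inside truth, one fully outside
  i <- matrix(0L, 10, 20); i[2:4, 2:4] <- 1L; i[7:9, 12:16] <- 1L
  t <- matrix(0L, 10, 20); t[1:5, 1:5] <- 1L
  za <- zoneValidity(i, t)
  expect_equal(agreementScores(za)[["fA"]], 0.5)
  # exactly 80% overlap validates (>= threshold)
  i2 <- matrix(0L, 6, 10); i2[1, 1:5] <- 1L
  t2 <- matrix(0L, 6, 10); t2[1, 1:4] <- 1L
  expect_equal(agreementScores(zoneValidity(i2, t2))[["fA"]], 1)
  expect_equal(agreementScores(zoneValidity(i2, t2, threshold = 0.8 + 1e-9))[["fA"]], 0)
  # operator zone exactly half covered is recalled
  t3 <- matrix(0L, 6, 10); t3[2, 1:4] <- 1L
  i3 <- matrix(0L, 6, 10); i3[2, 1:2] <- 1L
  expect_equal(agreementScores(zoneRecall(i3, t3))[["fG"]], 1)
  # coverages 0.9 / 0.4 / 0.6 -> 2 of 3 recalled
  t5 <- matrix(0L, 12, 30)
  t5[2, 1:10] <- 1L; t5[6, 1:10] <- 1L; t5[10, 1:10] <- 1L
  i5 <- matrix(0L, 12, 30)
  i5[2, 1:9] <- 1L; i5[6, 1:4] <- 1L; i5[10, 1:6] <- 1L
  expect_equal(agreementScores(zoneRecall(i5, t5))[["fG"]], 2 / 3)
  # undefined scores stay NA
  empty <- matrix(0L, 5, 5)
  expect_true(is.na(agreementScores(zoneValidity(empty, t2[1:5, 1:5]))[["fA"]]))
  expect_true(is.na(agreementScores(zoneRecall(i2[1:5, 1:5], empty))[["fG"]]))
})

test_that("zone agreement matches brute-force enumeration on random pairs", {
  set.seed(6)
  for (k in 1:40) {
    i <- randomMask(24, 24, runif(1, 0.1, 0.7))
    t <- randomMask(24, 24, runif(1, 0.1, 0.7))
    za <- zoneAgreement(i, t)
    want <- oracleZoneScores(i, t)
    got <- agreementScores(za)
    expect_equal(unname(got[["fA"]]), unname(want[["fa"]]))
    expect_equal(unname(got[["fG"]]), unname(want[["fg"]]))
    # boundary thresholds
    if (any(i == 1) && any(t == 1)) {
      z0 <- zoneAgreement(i, t, validityThreshold = 0, recallThreshold = 0)
      expect_equal(unname(agreementScores(z0)), c(1, 1))
      z2 <- zoneAgreement(i, t, validityThreshold = 1.01,
                          recallThreshold = 1.01)
      expect_equal(unname(agreementScores(z2)), c(0, 0))
    }
  }
})

test_that("pixel area follows the field-of-view arithmetic", {
  expect_equal(round(pixelAreaFromFov(2, 3, 3456, 5184), 2), 0.33)
  # 0.05358...: agrees with the printed 0.053 to within a unit in the last
  # printed digit (the printed value truncates rather than rounds)
  expect_lt(abs(pixelAreaFromFov(0.8, 1.2, 3456, 5184) - 0.053), 1e-3)
  expect_equal(pixelAreaFromFov(1, 1, 1000, 1000), 1)
  expect_error(pixelAreaFromFov(0, 3, 10, 10), "positive")
})

test_that("nuclear density counts centroids per physical area", {
  region <- matrix(0L, 100, 100); region[1:100, 1:100] <- 1L
  cent <- cbind(runif(10, 1, 100), runif(10, 1, 100))
  expect_equal(nuclearDensity(cent, region, 0.1), 10 / (10000 * 0.1) * 1000)
  # additivity over disjoint halves
  left <- region; left[, 51:100] <- 0L
  right <- region; right[, 1:50] <- 0L
  nL <- nuclearDensity(cent, left, 0.1) * sum(left) * 0.1 / 1000
  nR <- nuclearDensity(cent, right, 0.1) * sum(right) * 0.1 / 1000
  expect_equal(nL + nR, 10)
  expect_error(nuclearDensity(cent, region * 0L, 0.1), "empty")
})

test_that("Huber fit recovers lines, resists outliers, and bootstraps deterministically", {
  x <- seq(0, 1, length.out = 25)
  fit <- huberFit(x, 2 * x + 1, bootstrapReps = 50, seed = 1)
  cf <- coef(fit)
  expect_equal(cf[["slope"]], 2, tolerance = 1e-8)
  expect_equal(cf[["intercept"]], 1, tolerance = 1e-8)
  expect_equal(cf[["r2"]], 1, tolerance = 1e-12)
  # 10% gross outliers: Huber slope beats OLS slope
  set.seed(8)
  y <- x + rnorm(25, 0, 0.01)
  out <- sample(25, 3)
  y[out] <- y[out] + 10
  hub <- coef(huberFit(x, y, bootstrapReps = 50, seed = 2))[["slope"]]
  ols <- unname(coef(lm(y ~ x))[2])
  expect_lt(abs(hub - 1), abs(ols - 1))
  # seed-fixed bootstrap reproducibility
  f1 <- huberFit(x, y, bootstrapReps = 200, seed = 99)
  f2 <- huberFit(x, y, bootstrapReps = 200, seed = 99)
  expect_identical(coef(f1), coef(f2))
  expect_identical(f1@ciSlope, f2@ciSlope)
  expect_lte(f1@ciSlope[1], f1@ciSlope[2])
  expect_error(huberFit(rep(0.5, 10), runif(10), seed = 1), "degenerate")
  expect_error(huberFit(1:2, 1:2, seed = 1), "3")
})
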
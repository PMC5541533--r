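test_that("sigmoid contrast follows its closed form and is strictly monotone", {
  # scalar evaluations of the mapping
  expect_equal(sigmoidContrast(matrix(0.5), 0.5, 7)[1, 1], 0.5)
  expect_equal(sigmoidContrast(matrix(0.6), 0.5, 10)[1, 1],
               1 / (1 + exp(-1)), tolerance = 1e-12)
  # step limit at large gain
  big <- sigmoidContrast(matrix(c(0.4, 0.6), 1), 0.5, 500)
  expect_lt(big[1, 1], 1e-10)
  expect_gt(big[1, 2], 1 - 1e-10)
  # order preservation on random pairs
  set.seed(11)
  x <- matrix(runif(200), 10)
  y <- sigmoidContrast(x, 0.35, 6)
  ord <- order(x)
  expect_true(all(diff(y[ord]) > 0))
  expect_true(all(y > 0 & y < 1))
  expect_error(sigmoidContrast(x, 0.5, 0), "gain")
})

test_that("adaptive threshold honours offset polarity conventions", {
  const <- matrix(0.5, 20, 20)
  expect_true(all(adaptiveThreshold(const, 5, offset = 0.01) == 0))
  expect_true(all(adaptiveThreshold(const, 5, offset = 0.01,
                                    polarity = "below") == 0))
  # bright disc on dark ground: white pixels confined to disc + halo
  img <- matrix(0.1, 32, 32)
  disc <- discMask(32, 32, 16, 16, 6)
  img[disc == 1] <- 0.9
  m <- adaptiveThreshold(img, 9, 0)
  halo <- oracleMaxFilter(disc + 0, 2 * 9 + 1) > 0
  expect_true(all(m[!halo] == 0))
  expect_equal(m[16, 16], 1L)
  # complement symmetry at offset 0 (continuous image, no ties)
  set.seed(7)
  r <- matrix(runif(400), 20)
  up <- adaptiveThreshold(r, 7, 0, "above")
  dn <- adaptiveThreshold(r, 7, 0, "below")
  expect_true(all(up + dn == 1))
  expect_error(adaptiveThreshold(r, 8), "odd")
})

test_that("small-component removal is strict and matches the labelling oracle", {
  m <- matrix(0L, 20, 30)
  m[2:3, 2:3] <- 1L                 # 4 px
  m[10:16, 5:20] <- 1L              # 112 px
  out <- removeSmallComponents(m, 5)
  expect_equal(sum(out), 112L)
  # exactly min_size survives ("strictly less than" removal)
  m2 <- matrix(0L, 10, 10); m2[1:5, 1] <- 1L
  expect_equal(removeSmallComponents(m2, 5), m2)
  expect_true(all(removeSmallComponents(m2, 6) == 0))
  expect_true(all(removeSmallComponents(m * 0L, 10) == 0))
  set.seed(21)
  for (k in 1:20) {
    r <- randomMask(16, 16, runif(1, 0.2, 0.6))
    for (conn in c(4, 8))
      expect_equal(removeSmallComponents(r, 4, conn),
                   oracleRemoveSmall(r, 4, conn))
  }
})

test_that("disc closing matches set-algebra oracle and its lattice laws", {
  two <- matrix(0L, 20, 20)
  two[5:9, 3:8] <- 1L; two[5:9, 11:16] <- 1L    # 2-px gap
  closed <- morphClose(two, 3)
  expect_equal(max(oracleLabel(closed)), 1L)     # merged
  expect_equal(closed, oracleClose(two, 3))
  # convex solid unchanged
  rect <- matrix(0L, 15, 15); rect[4:12, 3:13] <- 1L
  expect_equal(morphClose(rect, 3), rect)
  set.seed(33)
  for (k in 1:10) {
    r <- randomMask(16, 16, 0.45)
    c1 <- morphClose(r, 2)
    expect_equal(c1, oracleClose(r, 2))
    expect_true(all(c1 >= r))                    # extensive
    expect_equal(morphClose(c1, 2), c1)          # idempotent
    r2 <- r; r2[r2 == 0][1] <- 1L                # r2 >= r
    expect_true(all(morphClose(r2, 2) >= c1))    # increasing
  }
})

test_that("maximum filter matches window enumeration and dominates input", {
  one <- matrix(0, 32, 32); one[16, 16] <- 1
  mx <- maximumFilter(one, 11)
  expect_equal(sum(mx), 121)
  expect_true(all(mx[11:21, 11:21] == 1))
  expect_equal(maximumFilter(one, 1), one)
  const <- matrix(0.3, 8, 8)
  expect_equal(maximumFilter(const, 5), const)
  set.seed(5)
  for (k in 1:10) {
    img <- matrix(runif(256), 16)
    out <- maximumFilter(img, 5)
    expect_equal(out, oracleMaxFilter(img, 5))
    expect_true(all(out >= img))
  }
})

test_that("distance transform uses the edge-zero convention exactly", {
  sq <- matrix(0L, 11, 11); sq[3:9, 3:9] <- 1L   # 7x7 square
  d <- distanceTransform(sq)
  expect_equal(d[6, 6], 3)   # centre of 7x7: distance 4 to black, minus 1
  expect_true(all(d[sq == 0] == 0))
  single <- matrix(0L, 5, 5); single[3, 3] <- 1L
  expect_equal(distanceTransform(single)[3, 3], 0)  # border white is zero
  expect_true(all(distanceTransform(matrix(0L, 6, 6)) == 0))
  expect_error(distanceTransform(matrix(1L, 4, 4), normalize = TRUE),
               "black")
  set.seed(9)
  for (k in 1:10) {
    r <- randomMask(16, 16, 0.5)
    if (all(r == 1)) r[1, 1] <- 0L
    expect_equal(distanceTransform(r), oracleEdt(r), tolerance = 1e-12)
  }
  # normalization bounds values by 1 without moving the argmax
  blob <- discMask(21, 21, 11, 11, 7)
  dn <- distanceTransform(blob, normalize = TRUE)
  expect_equal(max(dn), 1)
  expect_equal(which.max(dn), which.max(distanceTransform(blob)))
})

test_that("local entropy reproduces histogram entropy in a disc", {
  expect_equal(nrow(discOffsets(3)), 29L)
  const <- matrix(1, 10, 10)
  expect_true(all(localEntropy(const, 3) == 0))
  # half/half neighbourhood reaches 1 bit
  stripes <- matrix(rep(c(0, 1), 50), 10, 10)
  expect_equal(max(localEntropy(stripes, 3)), 1, tolerance = 1e-9)
  # 10 white / 19 black in a full radius-3 disc
  m <- matrix(0, 9, 9)
  off <- discOffsets(3)
  m[cbind(5 + off[1:10, 1], 5 + off[1:10, 2])] <- 1
  want <- -(10 / 29) * log2(10 / 29) - (19 / 29) * log2(19 / 29)
  expect_equal(localEntropy(m, 3)[5, 5], want, tolerance = 1e-12)
  set.seed(13)
  for (k in 1:10) {
    r <- randomMask(16, 16, 0.4)
    expect_equal(localEntropy(r + 0.0, 3), oracleEntropy(r, 3),
                 tolerance = 1e-12)
  }
})

test_that("Otsu threshold equals the exhaustive variance scan", {
  twoVal <- matrix(c(0.2, 0.8), 4, 4)
  t2 <- otsuThreshold(twoVal)
  expect_gt(t2, 0.2); expect_lt(t2, 0.8)
  set.seed(17)
  mix <- matrix(pmin(pmax(c(rnorm(300, 0.25, 0.05),
                            rnorm(212, 0.75, 0.05)), 0), 1), 32, 16)
  tm <- otsuThreshold(mix)
  expect_gt(tm, 0.4); expect_lt(tm, 0.6)
  expect_equal(tm, oracleOtsu(mix), tolerance = 1e-12)
  # histogram-permutation invariance
  perm <- matrix(sample(as.vector(mix)), 32, 16)
  expect_equal(otsuThreshold(perm), tm)
  expect_error(otsuThreshold(matrix(0.5, 3, 3)), "constant")
  for (k in 1:10) {
    r <- matrix(sample(seq(0, 1, 0.05), 64, replace = TRUE), 8)
    if (length(unique(as.vector(r))) < 2) next
    expect_equal(otsuThreshold(r), oracleOtsu(r), tolerance = 1e-12)
  }
})

test_that("marching squares produces closed contours with correct areas", {
  expect_length(marchingSquares(matrix(0.2, 10, 10), 0.5), 0L)
  img <- matrix(0, 40, 40)
  img[discMask(40, 40, 20, 20, 9) == 1] <- 1
  cts <- marchingSquares(img, 0.5)
  closed <- Filter(function(ct) attr(ct, "closed"), cts)
  expect_length(closed, 1L)
  area <- abs(sum(closed[[1]][, 1] *
                    closed[[1]][c(2:nrow(closed[[1]]), 1), 2] -
                    closed[[1]][c(2:nrow(closed[[1]]), 1), 1] *
                    closed[[1]][, 2]) / 2)
  expect_lt(abs(area - sum(img)) / sum(img), 0.05)
  # two disjoint discs -> two closed contours
  img2 <- img
  img2[discMask(40, 40, 8, 32, 5) == 1] <- 1
  closed2 <- Filter(function(ct) attr(ct, "closed"),
                    marchingSquares(img2, 0.5))
  expect_length(closed2, 2L)
})

test_that("peak markers deduplicate within min distance and break ties in raster order", {
  # single smooth peak
  g <- outer(1:21, 1:21, function(i, j) exp(-((i - 11)^2 + (j - 11)^2) / 20))
  mk <- peakMarkers(g, 5)
  expect_equal(max(mk), 1L)
  expect_equal(which(mk == 1L), which.max(g))
  # twin peaks from two fused discs
  two <- discMask(30, 40, 15, 13, 7) | discMask(30, 40, 15, 25, 7)
  two <- matrix(as.integer(two), 30, 40)
  edt <- distanceTransform(two)
  expect_equal(max(peakMarkers(edt, 5, two)), 2L)
  # plateau -> exactly one marker
  plat <- matrix(0, 15, 15); plat[7:9, 7:9] <- 1
  mk3 <- peakMarkers(plat, 6)
  expect_equal(max(mk3), 1L)
  expect_equal(which(mk3 == 1L), which(plat == 1)[1])  # raster-first
  # exhaustive neighbourhood-comparison oracle: every marker is a window max
  set.seed(29)
  surf <- maximumFilter(matrix(runif(900), 30), 3) + matrix(runif(900), 30) / 10
  mk4 <- peakMarkers(surf, 4)
  pos <- which(mk4 > 0, arr.ind = TRUE)
  for (r in seq_len(nrow(pos))) {
    ii <- max(1, pos[r, 1] - 4):min(30, pos[r, 1] + 4)
    jj <- max(1, pos[r, 2] - 4):min(30, pos[r, 2] + 4)
    expect_equal(surf[pos[r, 1], pos[r, 2]], max(surf[ii, jj]))
  }
  expect_equal(max(peakMarkers(g, 3, region = matrix(0L, 21, 21))), 0L)
})

test_that("marker watershed partitions the region and conserves labels", {
  reg <- discMask(20, 20, 10, 10, 7)
  mk <- matrix(0L, 20, 20); mk[10, 10] <- 1L
  lab <- watershedSegment(-distanceTransform(reg), mk, reg)
  expect_true(all(lab[reg == 1] == 1L))
  expect_true(all(lab[reg == 0] == 0L))
  # two fused discs, one marker per EDT peak; boundary crosses the neck
  two <- matrix(as.integer(discMask(40, 40, 20, 14, 8) |
                             discMask(40, 40, 20, 26, 8)), 40, 40)
  edt <- distanceTransform(two)
  mk2 <- peakMarkers(edt, 6, two)
  lab2 <- watershedSegment(-edt, mk2, two)
  expect_equal(sort(unique(as.vector(lab2[two == 1]))), c(1L, 2L))
  expect_equal(sum(lab2 > 0), sum(two))          # area conservation
  expect_true(lab2[20, 14] != lab2[20, 26])
  # nearest-marker geodesic oracle away from the ambiguous midline
  pos <- which(mk2 > 0, arr.ind = TRUE)
  px <- which(two == 1, arr.ind = TRUE)
  d1 <- sqrt((px[, 1] - pos[1, 1])^2 + (px[, 2] - pos[1, 2])^2)
  d2 <- sqrt((px[, 1] - pos[2, 1])^2 + (px[, 2] - pos[2, 2])^2)
  clear <- abs(d1 - d2) > 1.5
  want <- ifelse(d1 < d2, mk2[pos[1, 1], pos[1, 2]], mk2[pos[2, 1], pos[2, 2]])
  expect_true(all(lab2[cbind(px[clear, 1], px[clear, 2])] == want[clear]))
  bad <- matrix(0L, 20, 20); bad[1, 1] <- 1L
  expect_error(watershedSegment(-distanceTransform(reg), bad, reg), "region")
})

test_that("zone extraction respects connectivity and partitions white pixels", {
  expect_length(extractZones(matrix(0L, 5, 5)), 0L)
  diag2 <- matrix(0L, 4, 4); diag2[1, 1] <- 1L; diag2[2, 2] <- 1L
  expect_length(extractZones(diag2, 8), 1L)
  expect_length(extractZones(diag2, 4), 2L)
  set.seed(41)
  r <- randomMask(16, 16, 0.5)
  zs <- extractZones(r, 8)
  expect_equal(sum(vapply(zs, zoneArea, integer(1))), sum(r))
  expect_equal(length(zs), max(oracleLabel(r, 8)))
})
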
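test_that("region growing equals brute-force flood fill on random grids", {
  set.seed(20)
  for (conn in c(6L, 26L)) {
    for (trial in 1:25) {
      a <- array(sample(0:9, 8^3, replace = TRUE), c(8, 8, 8))
      v <- ScanVolume(a)
      inr <- a >= 3 & a <= 7
      if (!any(inr)) next
      seed <- which(inr, arr.ind = TRUE)[1, ] - 1L
      got <- regionGrow(v, rgtParams(seed, 3, 7, conn))
      expect_identical(voxelData(got), bfFlood(inr, seed, conn))
    }
  }
})

test_that("region growing saturates, separates blobs and rejects bad seeds", {
  v <- ScanVolume(array(5, c(5, 5, 5)))
  m <- regionGrow(v, rgtParams(c(2, 2, 2), 0, 10))
  expect_identical(voxelCount(m), 125L)

  a <- array(0, c(9, 5, 5))
  a[1:3, , ] <- 5     # blob A
  a[7:9, , ] <- 5     # blob B, separated by out-of-range voxels
  vb <- ScanVolume(a)
  mA <- regionGrow(vb, rgtParams(c(1, 2, 2), 4, 6))
  expect_identical(voxelCount(mA), 75L)
  expect_true(all(which(voxelData(mA), arr.ind = TRUE)[, 1] <= 3))

  expect_error(regionGrow(vb, rgtParams(c(4, 2, 2), 4, 6)), "seed rejected")
  expect_error(regionGrow(vb, rgtParams(c(20, 2, 2), 4, 6)), "outside")
})

test_that("Chan-Vese recovers a two-phase piecewise-constant image exactly", {
  ball <- voxelData(ballMask(24, 6))
  I <- array(100, c(24, 24, 24))
  I[ball] <- 200
  res <- chanVese(ScanVolume(I), initBoxLevelSet(c(24, 24, 24), 2),
                  cvParams(nIter = 600))
  expect_identical(voxelData(res$mask), ball)
  expect_equal(res$muIn, 200)
  expect_equal(res$muOut, 100)
})

test_that("Chan-Vese is symmetric under intensity swap and sign flip", {
  set.seed(31)
  ball <- voxelData(ballMask(16, 4.5))
  I <- array(100, c(16, 16, 16))
  I[ball] <- 200
  phi0 <- sphereField(16, 6)
  phi0@phi <- phi0@phi + 0.1   # avoid exact zeros so the partition is clean
  p <- cvParams(nIter = 200)
  a <- chanVese(ScanVolume(I), phi0, p)
  neg <- new("LevelSetField", phi = -voxelData(phi0), iteration = 0L,
             spacing = c(1, 1, 1), origin = c(0, 0, 0))
  b <- chanVese(ScanVolume(300 - I), neg, p)
  expect_identical(voxelData(b$mask), !voxelData(a$mask))
})

test_that("Chan-Vese on a constant image with alpha = 0 does not move", {
  v <- ScanVolume(array(7, c(12, 12, 12)))
  phi0 <- initBoxLevelSet(c(12, 12, 12), 3)
  # both region terms vanish on a constant image; with no curvature weight
  # the speed is identically zero
  res <- chanVese(v, phi0, cvParams(beta = 0, nIter = 60))
  expect_identical(voxelData(res$mask), voxelData(maskFromLevelSet(phi0)))
})

test_that("the boundary map is the reciprocal-quadratic edge stopper", {
  v <- ScanVolume(array(42, c(8, 8, 8)))
  expect_true(all(boundaryMap(v, c = 0.5, smoothSigma = 0) == 1))

  # linear ramp of slope sqrt(2): |grad I|^2 = 2 everywhere in the interior
  ramp <- ScanVolume(array(rep(sqrt(2) * (0:11), each = 1), c(12, 12, 12)))
  g <- boundaryMap(ramp, c = 0.5, smoothSigma = 0)
  expect_equal(g[6, 6, 6], 0.5)

  set.seed(4)
  noisy <- ScanVolume(array(rnorm(12^3, 100, 20), c(12, 12, 12)))
  g1 <- boundaryMap(noisy, c = 0.2, smoothSigma = 0)
  g2 <- boundaryMap(noisy, c = 0.7, smoothSigma = 0)
  grad0 <- g1 == 1
  expect_true(all(g2[!grad0] < g1[!grad0]))
  expect_true(all(g1 > 0 & g1 <= 1))
})

test_that("the TLS speed combines region and geodesic terms as stated", {
  n <- 16
  flat <- new("LevelSetField",
              phi = array(rep(0:(n - 1) - 7.5, each = n * n), c(n, n, n)),
              iteration = 0L, spacing = c(1, 1, 1), origin = c(0, 0, 0))
  p <- tlsParams()

  # I == T with a planar field and constant g: both terms vanish
  vT <- ScanVolume(array(130, c(n, n, n)))
  g1 <- array(1, c(n, n, n))
  F0 <- tlsSpeed(vT, flat, T = 130, g = g1, p)
  expect_lt(max(abs(F0)), 1e-9)

  # I - T = +1 with constant g = 1 and a plane: F = alpha
  v1 <- ScanVolume(array(131, c(n, n, n)))
  F1 <- tlsSpeed(v1, flat, T = 130, g = g1, p)
  expect_equal(max(abs(F1 - p@alpha)), 0, tolerance = 1e-9)

  # beta = 0: the sign of F is the region-growing lower-threshold criterion
  set.seed(8)
  vr <- ScanVolume(array(rnorm(n^3, 130, 25), c(n, n, n)))
  pb0 <- tlsParams(beta = 0)
  Fb <- tlsSpeed(vr, sphereField(n, 5), T = 130, g = boundaryMap(vr), pb0)
  expect_identical(sign(Fb), sign(voxelData(vr) - 130))
})

test_that("with alpha = 0 the evolution is a geodesic active contour run", {
  n <- 20
  set.seed(12)
  v <- ScanVolume(gaussianSmooth(array(rnorm(n^3, 120, 30), c(n, n, n)), 1))
  g <- boundaryMap(v, c = 0.5)
  p0 <- tlsParams(alpha = 0, beta = 3)
  fTls <- sphereField(n, 6)
  fGac <- sphereField(n, 6)
  for (s in 1:12) {
    Ftls <- tlsSpeed(v, fTls, T = 120, g = g, p0)
    Fgac <- p0@beta * rGeodesicTerm(voxelData(fGac), g)
    expect_lt(max(abs(Ftls - Fgac)), 1e-9)
    dt <- stableTimeStep(Ftls, p0@beta)
    fTls <- levelSetStep(fTls, Ftls, dt)
    fGac <- levelSetStep(fGac, Fgac, dt)
    expect_lt(max(abs(voxelData(fTls) - voxelData(fGac))), 1e-9)
  }
})

test_that("automatic TLS segments separable and noisy phantoms", {
  # noise-free two-constant phantom: exact up to a 1-voxel surface band
  ph0 <- makePhantom(phantomConfig(shape = c(32, 32, 32), tubeRadius = 4,
                                   sacRadius = 6, noiseSd = 0, blurSd = 0))
  suppressWarnings(r0 <- segmentTLS(ph0$volume))
  diffs <- voxelData(r0$mask) != voxelData(ph0$mask)
  if (any(diffs)) {
    expect_lte(max(abs(voxelData(sdfFromMask(ph0$mask))[diffs])), 1)
  }

  # straight-tube noisy phantom, ROI protocol: Jaccard >= 90%
  ph <- makePhantom(phantomConfig(seed = 5))
  r <- autoRoi(ph$mask, 6)
  res <- segmentTLS(crop(ph$volume, r))
  jm <- jaccardMeasure(crop(ph$mask, r), res$mask)
  expect_gte(jm, 90)
  expect_true(res$threshold@converged)
})

test_that("TLS-seeded region growing matches TLS up to a surface band", {
  ph <- makePhantom(phantomConfig(seed = 5))
  r <- autoRoi(ph$mask, 6)
  vR <- crop(ph$volume, r)
  res <- segmentTLS(vR)
  ctr <- round(dim(vR) / 2)
  rgt <- segmentRGTAuto(vR, ctr, res$threshold@T)
  # the flood-fill oracle reproduces the RGT mask
  inr <- voxelData(vR) >= res$threshold@T
  expect_identical(voxelData(rgt), bfFlood(inr, ctr, 26L))
  # TLS and RGT disagree only within one voxel of the RGT surface
  disagree <- voxelData(rgt) != voxelData(res$mask)
  if (any(disagree)) {
    expect_lte(max(abs(voxelData(sdfFromMask(rgt))[disagree])), 1.5)
  }
  expect_error(segmentRGTAuto(vR, ctr, max(voxelData(vR)) + 1), "seed")
})
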
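test_that("Chebyshev bounds take their closed forms and hold empirically", {
  expect_equal(chebyshevBounds(1)$oneSided, 0.5)
  expect_equal(chebyshevBounds(2)$twoSided, 0.25)
  expect_equal(chebyshevBounds(2)$oneSided, 0.2)
  expect_error(chebyshevBounds(0), "positive")
  expect_error(chebyshevBounds(-1), "positive")

  set.seed(101)
  draws <- list(normal = rnorm(1e5, 5, 2),
                uniform = runif(1e5, -1, 1))
  for (x in draws) {
    mu <- mean(x)
    sg <- sd(x)
    for (k in c(1.5, 2, 3)) {
      b <- chebyshevBounds(k)
      expect_lte(mean(abs(x - mu) >= k * sg), b$twoSided)
      expect_lte(mean(x - mu >= k * sg), b$oneSided)
    }
  }
})

test_that("k estimation follows the balance relation in both modes", {
  s <- new("RegionStats", muA = 200, sigmaA = 30, muB = 100, sigmaB = 10,
           nFg = 10L, nBg = 10L)
  expect_equal(estimateK(s), 2.5)
  expect_equal(estimateK(s, mode = "as-printed"), 5)

  eq <- new("RegionStats", muA = 200, sigmaA = 20, muB = 100, sigmaB = 20,
            nFg = 10L, nBg = 10L)
  expect_error(estimateK(eq, mode = "as-printed"), "degenerate")
  expect_equal(estimateK(eq), 2.5)  # balanced mode is never singular

  swapped <- new("RegionStats", muA = 100, sigmaA = 10, muB = 200,
                 sigmaB = 10, nFg = 10L, nBg = 10L)
  expect_error(estimateK(swapped), "assumption")
})

test_that("the balanced threshold satisfies muA - k sigmaA = muB + k sigmaB", {
  s <- new("RegionStats", muA = 200, sigmaA = 30, muB = 100, sigmaB = 10,
           nFg = 10L, nBg = 10L)
  k <- estimateK(s)
  expect_equal(thresholdFromStats(s, k), 125)
  expect_equal(s@muB + k * s@sigmaB, 125)

  set.seed(42)
  for (i in 1:25) {
    muB <- runif(1, 0, 150)
    muA <- muB + runif(1, 5, 300)
    st <- new("RegionStats", muA = muA, sigmaA = runif(1, 0.1, 50),
              muB = muB, sigmaB = runif(1, 0.1, 50),
              nFg = 5L, nBg = 5L)
    k <- estimateK(st)
    T <- thresholdFromStats(st, k)
    expect_equal(st@muA - k * st@sigmaA, st@muB + k * st@sigmaB)
    expect_gt(T, st@muB)
    expect_lt(T, st@muA)
  }

  degenerate <- new("RegionStats", muA = 200, sigmaA = 0, muB = 100,
                    sigmaB = 10, nFg = 10L, nBg = 10L)
  expect_warning(T0 <- thresholdFromStats(degenerate, 2), "zero-variance")
  expect_equal(T0, 200)
  wide <- new("RegionStats", muA = 200, sigmaA = 60, muB = 100, sigmaB = 5,
              nFg = 10L, nBg = 10L)
  expect_warning(Tc <- thresholdFromStats(wide, 2), "clamped")
  expect_equal(Tc, 100 + 0.05 * 100)
})

test_that("region statistics are the sample moments under each mask", {
  a <- array(100, c(6, 6, 6))
  a[, , 1:3] <- 200   # first half in array order
  v <- ScanVolume(a)
  fg <- VoxelMask(array(rep(c(TRUE, FALSE), each = 108), c(6, 6, 6)))
  bg <- VoxelMask(!voxelData(fg))
  st <- statsFromMask(v, fg, bg)
  expect_equal(st@muA, 200)
  expect_equal(st@sigmaA, 0)
  expect_equal(st@muB, 100)
  expect_equal(st@sigmaB, 0)

  b <- array(0, c(4, 4, 4))
  b[1:3] <- c(190, 200, 210)
  fg3 <- array(FALSE, c(4, 4, 4))
  fg3[1:3] <- TRUE
  st3 <- statsFromMask(ScanVolume(b), VoxelMask(fg3), VoxelMask(!fg3))
  expect_equal(st3@muA, 200)
  expect_equal(st3@sigmaA, 10)

  set.seed(5)
  n <- 22    # ~1e4 voxels
  g <- ScanVolume(array(rnorm(n^3, 200, 20), c(n, n, n)))
  half <- array(rep(c(TRUE, FALSE), length.out = n^3), c(n, n, n))
  stG <- statsFromMask(g, VoxelMask(half), VoxelMask(!half))
  expect_equal(stG@muA, 200, tolerance = 1 / 200)
  expect_equal(stG@sigmaA, 20, tolerance = 1 / 20)

  expect_error(statsFromMask(v, fg, fg), "disjoint")
  empty <- VoxelMask(array(FALSE, c(6, 6, 6)))
  expect_error(statsFromMask(v, empty, bg), "degenerate")
})

test_that("threshold iteration converges on separable and noisy phantoms", {
  # noise-free two-constant phantom: midpoint threshold in <= 3 iterations,
  # mask equals the thresholded truth
  ph <- makePhantom(phantomConfig(shape = c(32, 32, 32), tubeRadius = 4,
                                  sacRadius = 6, noiseSd = 0, blurSd = 0))
  pre <- VoxelMask(voxelData(ph$volume) > 150)
  suppressWarnings(
    res <- iterateThreshold(ph$volume, pre, tlsParams(maxOuter = 10L)))
  expect_true(res$estimate@converged)
  expect_lte(nrow(res$estimate@history), 3)
  expect_equal(res$estimate@T, 150)
  expect_identical(voxelData(res$mask), voxelData(ph$mask))

  # noisy standard phantom: |T_i - T_{i-1}| < 0.5 HU within 30 iterations
  phn <- makePhantom(phantomConfig(shape = c(40, 40, 40), tubeRadius = 4,
                                   sacRadius = 7, seed = 2))
  pren <- VoxelMask(gaussianSmooth(voxelData(phn$volume), 1) > 150)
  resn <- iterateThreshold(phn$volume, pren, tlsParams())
  expect_true(resn$estimate@converged)
  h <- resn$estimate@history
  expect_lte(nrow(h), 30)
  last <- nrow(h)
  expect_gt(resn$estimate@T, h$muB[last])
  expect_lt(resn$estimate@T, h$muA[last])

  # determinism: identical inputs give identical traces
  resn2 <- iterateThreshold(phn$volume, pren, tlsParams())
  expect_identical(resn2$estimate@history, resn$estimate@history)
  expect_identical(voxelData(resn2$mask), voxelData(resn$mask))

  # degenerate initial mask covering everything
  full <- VoxelMask(array(TRUE, c(32, 32, 32)))
  expect_error(iterateThreshold(ph$volume, full, tlsParams()), "both phases")
})

test_that("threshold history exports as a convergence CSV", {
  est <- new("ThresholdEstimate", k = 2, T = 150,
             history = data.frame(iteration = 1:2, T = c(140, 150),
                                  k = c(1.8, 2), muA = c(195, 198),
                                  sigmaA = c(12, 11), muB = c(99, 100),
                                  sigmaB = c(10, 10)),
             converged = TRUE)
  path <- file.path(withr::local_tempdir(), "hist.csv")
  writeThresholdHistory(est, path)
  back <- read.csv(path)
  expect_equal(back$T, c(140, 150))
  expect_named(back, c("iteration", "T", "k", "muA", "sigmaA", "muB",
                       "sigmaB"))
})
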
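test_that("box initialization is a signed distance to the inset box", {
  ls <- initBoxLevelSet(c(10, 10, 10), inset = 2)
  phi <- voxelData(ls)
  expect_lt(phi[6, 6, 6], 0)          # centre is inside
  expect_gt(phi[1, 1, 1], 0)          # corner is outside
  # voxels adjacent to a face plane sit within half a voxel of the surface
  expect_lt(abs(phi[3, 6, 6]), 0.71)
  expect_lt(abs(phi[8, 6, 6]), 0.71)
  # interior volume equals the analytic box volume
  expect_identical(sum(phi < 0), 216L)
  ls2 <- initBoxLevelSet(c(12, 9, 15), inset = 3)
  expect_identical(sum(voxelData(ls2) < 0), 6L * 3L * 9L)
  expect_error(initBoxLevelSet(c(6, 6, 6), inset = 3), "degenerate")
})

test_that("curvature matches 2/R on a sphere, vanishes on planes", {
  f <- sphereField(32, 8)
  kap <- levelSetCurvature(f)
  band <- abs(voxelData(f)) < 1.5
  expect_equal(mean(kap[band]), 2 / 8, tolerance = 0.15)
  expect_true(all(kap[band] > 0))   # negative-inside sphere: positive kappa

  plane <- new("LevelSetField",
               phi = aperm(array(rep(0:(16 - 1) - 7.5, each = 256),
                                 c(16, 16, 16)), c(3, 2, 1)),
               iteration = 0L, spacing = c(1, 1, 1), origin = c(0, 0, 0))
  kp <- levelSetCurvature(plane)
  interior <- kp[3:14, 3:14, 3:14]
  expect_lt(max(abs(interior)), 1e-6)
})

test_that("stepping obeys zero-speed, uniform expansion and locality", {
  f <- sphereField(32, 8)
  still <- levelSetStep(f, array(0, dim(f)), dt = 0.3)
  expect_equal(voxelData(still), voxelData(f))
  expect_identical(still@iteration, 1L)

  grown <- f
  for (i in 1:8) grown <- levelSetStep(grown, array(1, dim(f)), dt = 0.25)
  expect_equal(volumeRadius(grown), 8 + 2, tolerance = 0.05)
  expect_gte(sum(voxelData(grown) < 0), sum(voxelData(f) < 0))

  # locality: a speed perturbation at one voxel cannot reach beyond the
  # stencil radius in a single step
  s0 <- array(1, dim(f))
  s1 <- s0
  s1[16, 16, 16] <- -5
  a <- voxelData(levelSetStep(f, s0, dt = 0.05))
  b <- voxelData(levelSetStep(f, s1, dt = 0.05))
  changed <- which(a != b, arr.ind = TRUE)
  expect_true(all(abs(changed - 16) <= 1))

  expect_error(levelSetStep(f, array(NaN, dim(f))), "non-finite")
})

test_that("a sphere under pure curvature speed follows R(t)^2 = R0^2 - 4 beta t", {
  beta <- 0.3
  f <- sphereField(32, 10)
  t <- 0
  while (t < 30) {
    sp <- -beta * levelSetCurvature(f)
    dt <- stableTimeStep(sp, beta)
    f <- levelSetStep(f, dt = dt, curvatureSpeed = sp)
    t <- t + dt
    if (f@iteration %% 20 == 0) f <- reinitializeLevelSet(f)
  }
  expect_equal(volumeRadius(f), sqrt(10^2 - 4 * beta * t), tolerance = 0.05)
})

test_that("reinitialization preserves the interface and restores |grad phi|", {
  f <- sphereField(24, 7)
  r1 <- reinitializeLevelSet(f)
  expect_identical(voxelData(maskFromLevelSet(r1)),
                   voxelData(maskFromLevelSet(f)))
  band <- abs(voxelData(f)) < 3
  expect_lt(max(abs(voxelData(r1)[band] - voxelData(f)[band])), 0.3)

  scaled <- new("LevelSetField", phi = 5 * voxelData(f), iteration = 0L,
                spacing = c(1, 1, 1), origin = c(0, 0, 0))
  r5 <- reinitializeLevelSet(scaled, iterations = 15)
  expect_lt(max(abs(voxelData(r5)[band] - voxelData(f)[band])), 0.8)

  # odd sign-preserving distortion: the voxel partition must not move
  cubed <- new("LevelSetField", phi = voxelData(f)^3, iteration = 0L,
               spacing = c(1, 1, 1), origin = c(0, 0, 0))
  rc <- reinitializeLevelSet(cubed)
  expect_identical(voxelData(maskFromLevelSet(rc)),
                   voxelData(maskFromLevelSet(f)))

  # near-interface gradient close to 1 after reinitialization
  gm <- array(aneuseg:::cpp_gradmag(as.numeric(voxelData(r1)),
                                    dim(r1)), dim(r1))
  nearBand <- abs(voxelData(r1)) < 3 & abs(voxelData(r1)) > 0.7
  expect_gte(mean(gm[nearBand] > 0.5 & gm[nearBand] < 1.5), 0.95)

  flat <- new("LevelSetField", phi = array(1, c(8, 8, 8)), iteration = 0L,
              spacing = c(1, 1, 1), origin = c(0, 0, 0))
  expect_error(reinitializeLevelSet(flat), "degenerate")
})

test_that("mask extraction and signed distance construction are inverses", {
  box <- initBoxLevelSet(c(12, 12, 12), 3)
  expect_identical(sum(voxelData(maskFromLevelSet(box))), 216L)
  allPos <- new("LevelSetField", phi = array(2, c(8, 8, 8)), iteration = 0L,
                spacing = c(1, 1, 1), origin = c(0, 0, 0))
  expect_identical(voxelCount(maskFromLevelSet(allPos)), 0L)

  for (s in 1:5) {
    m <- randomBlobMask(10, seed = s)
    expect_identical(voxelData(maskFromLevelSet(sdfFromMask(m))),
                     voxelData(m))
  }
})

test_that("sdfFromMask gives exact signed Euclidean distances", {
  single <- array(FALSE, c(7, 7, 7))
  single[4, 4, 4] <- TRUE
  phi <- voxelData(sdfFromMask(VoxelMask(single)))
  expect_lt(phi[4, 4, 4], 0)
  expect_true(all(phi[-4, , ] >= 0) && all(phi[4, 4, 5] >= 0))

  cube <- array(FALSE, c(16, 16, 16))
  cube[6:11, 6:11, 6:11] <- TRUE
  phiC <- voxelData(sdfFromMask(VoxelMask(cube)))
  expect_equal(phiC[8, 8, 8], -3, tolerance = 0.6)

  m <- randomBlobMask(10, seed = 9)
  comp <- VoxelMask(!voxelData(m))
  expect_equal(voxelData(sdfFromMask(comp)), -voxelData(sdfFromMask(m)))

  expect_error(sdfFromMask(VoxelMask(array(TRUE, c(5, 5, 5)))), "degenerate")
})
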
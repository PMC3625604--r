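cubeMask <- function(n, lo, hi) {
  a <- array(FALSE, c(n, n, n))
  a[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- TRUE
  VoxelMask(a)
}

test_that("overlap metrics follow their set-count definitions", {
  n <- 10
  g100 <- cubeMask(n, c(1, 1, 1), c(4, 5, 5))   # 100 voxels
  t110 <- cubeMask(n, c(1, 1, 1), c(4, 5, 5))
  extra <- voxelData(t110)
  extra[6, 1:2, 1:5] <- TRUE                     # +10 voxels
  t110 <- VoxelMask(extra)
  expect_equal(volumeDifference(g100, t110), 10)
  expect_equal(volumeDifference(g100, g100), 0)

  g200 <- cubeMask(n, c(1, 1, 1), c(8, 5, 5))
  t150 <- cubeMask(n, c(1, 1, 1), c(6, 5, 5))
  expect_equal(volumeDifference(g200, t150), 25)

  expect_equal(jaccardMeasure(g100, g100), 100)
  expect_equal(jaccardMeasure(g100, g100, mode = "dice"), 100)
  disj <- cubeMask(n, c(6, 6, 6), c(9, 9, 9))
  expect_equal(jaccardMeasure(g100, disj), 0)

  # |S1| = 100, |S2| = 100, overlap 80
  s2 <- cubeMask(n, c(1, 1, 1), c(4, 5, 5))
  d <- voxelData(s2)
  d[1, 1:4, 1:5] <- FALSE          # drop 20
  d[6, 1:4, 1:5] <- TRUE           # add 20 elsewhere
  s2 <- VoxelMask(d)
  expect_equal(jaccardMeasure(g100, s2), 80 / 120 * 100, tolerance = 1e-10)
  expect_equal(jaccardMeasure(g100, s2, mode = "dice"), 80)

  expect_equal(falsePositiveRatio(g100, t110), 10)
  expect_equal(falsePositiveRatio(g100, g100), 0)
  expect_equal(falseNegativeRatio(g100, s2), 20)
  expect_equal(falseNegativeRatio(g200, g200), 0)

  empty <- VoxelMask(array(FALSE, c(n, n, n)))
  expect_error(volumeDifference(empty, g100), "empty")
  expect_error(jaccardMeasure(empty, empty), "empty")
})

test_that("rfp/rfn satisfy their algebraic identities on random masks", {
  for (s in 1:10) {
    a <- randomBlobMask(9, seed = s)
    b <- randomBlobMask(9, seed = s + 100)
    expect_equal(falsePositiveRatio(a, b),
                 falseNegativeRatio(b, a) * voxelCount(b) / voxelCount(a))
    inter <- sum(voxelData(a) & voxelData(b))
    expect_equal(falseNegativeRatio(a, b) + inter / voxelCount(a) * 100, 100)
  }
})

test_that("surface voxels are the 6-connected shell", {
  single <- array(FALSE, c(5, 5, 5))
  single[3, 3, 3] <- TRUE
  expect_equal(surfaceVoxels(VoxelMask(single)),
               matrix(c(2L, 2L, 2L), 1), ignore_attr = TRUE)

  cube4 <- cubeMask(8, c(3, 3, 3), c(6, 6, 6))
  expect_identical(nrow(surfaceVoxels(cube4)), 56L)   # 4^3 - 2^3

  # brute-force neighbour scan oracle
  for (s in 1:5) {
    m <- randomBlobMask(8, seed = s)
    a <- voxelData(m)
    n <- dim(a)
    surf <- array(FALSE, n)
    for (i in 1:n[1]) for (j in 1:n[2]) for (k in 1:n[3]) {
      if (!a[i, j, k]) next
      nb <- c(if (i > 1) a[i - 1, j, k] else FALSE,
              if (i < n[1]) a[i + 1, j, k] else FALSE,
              if (j > 1) a[i, j - 1, k] else FALSE,
              if (j < n[2]) a[i, j + 1, k] else FALSE,
              if (k > 1) a[i, j, k - 1] else FALSE,
              if (k < n[3]) a[i, j, k + 1] else FALSE)
      surf[i, j, k] <- !all(nb)
    }
    expect_identical(surfaceVoxels(m), which(surf, arr.ind = TRUE) - 1L,
                     label = paste("blob", s))
  }
})

test_that("surface distances match the all-pairs brute force", {
  a <- array(FALSE, c(6, 6, 6))
  a[1, 1, 1] <- TRUE
  b <- array(FALSE, c(6, 6, 6))
  b[4, 5, 1] <- TRUE
  expect_equal(hausdorffDistance(VoxelMask(a), VoxelMask(b)), 5)
  expect_equal(meanSurfaceDistance(VoxelMask(a), VoxelMask(b)), 5)

  for (s in 1:20) {
    m1 <- randomBlobMask(10, seed = s)
    m2 <- randomBlobMask(10, seed = s + 500)
    expect_equal(hausdorffDistance(m1, m2), bfHausdorff(m1, m2),
                 tolerance = 1e-9)
    expect_equal(meanSurfaceDistance(m1, m2), bfMasd(m1, m2),
                 tolerance = 1e-9)
    expect_gte(hausdorffDistance(m1, m2), meanSurfaceDistance(m1, m2))
  }

  cube <- cubeMask(12, c(4, 4, 4), c(8, 8, 8))
  dil <- morphDilate(cube, 1)
  expect_gte(meanSurfaceDistance(cube, dil), 0)
  expect_lte(meanSurfaceDistance(cube, dil), 1)
  expect_gte(hausdorffDistance(cube, dil), meanSurfaceDistance(cube, dil))
})

test_that("the full report matches its parts and is translation invariant", {
  m <- randomBlobMask(10, seed = 77)
  idRep <- segmentationReport(m, m)
  expect_equal(c(idRep@VD, idRep@JM, idRep@rfp, idRep@rfn, idRep@HD,
                 idRep@MASD), c(0, 100, 0, 0, 0, 0))

  g <- cubeMask(12, c(2, 2, 2), c(5, 5, 5))
  t <- cubeMask(12, c(8, 8, 8), c(11, 11, 11))   # disjoint, equal size
  r <- segmentationReport(g, t)
  expect_equal(c(r@VD, r@JM, r@rfp, r@rfn), c(0, 0, 100, 100))

  # constructed offset cubes against hand-computed values
  g2 <- cubeMask(12, c(3, 3, 3), c(6, 6, 6))         # 64 voxels
  t2 <- cubeMask(12, c(4, 3, 3), c(7, 6, 6))         # shifted +1 in x
  r2 <- segmentationReport(g2, t2)
  expect_equal(r2@VD, 0)
  expect_equal(r2@JM, 48 / 80 * 100)
  expect_equal(r2@rfp, 16 / 64 * 100)
  expect_equal(r2@rfn, 16 / 64 * 100)
  expect_equal(r2@HD, bfHausdorff(g2, t2))
  expect_equal(r2@MASD, bfMasd(g2, t2))

  # translating both masks together leaves every metric unchanged
  g3 <- cubeMask(12, c(5, 5, 5), c(8, 8, 8))
  t3 <- cubeMask(12, c(6, 5, 5), c(9, 8, 8))
  r3 <- segmentationReport(g3, t3)
  for (slot in c("VD", "JM", "JMdice", "rfp", "rfn", "HD", "MASD"))
    expect_equal(methods::slot(r3, slot), methods::slot(r2, slot),
                 label = slot)

  # Jaccard never exceeds Dice for overlapping non-identical pairs
  for (s in 1:8) {
    m1 <- randomBlobMask(9, seed = s + 30)
    m2 <- morphDilate(m1, 1)
    expect_lte(jaccardMeasure(m1, m2), jaccardMeasure(m1, m2, mode = "dice"))
  }
})
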
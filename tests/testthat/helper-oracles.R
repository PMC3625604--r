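# Independent brute-force oracles and small fixture builders used across the
# suite. The oracles deliberately avoid the package's compiled code paths.

# shift a 3D array by d along axis ax with replicated boundary
shiftArr <- function(a, d, ax) {
  n <- dim(a)
  idx <- list(seq_len(n[1]), seq_len(n[2]), seq_len(n[3]))
  idx[[ax]] <- pmin(pmax(idx[[ax]] + d, 1L), n[ax])
  a[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
}

# brute-force flood fill: fixed point of neighbourhood dilation intersected
# with the in-range set
bfFlood <- function(inrange, seed, connectivity) {
  n <- dim(inrange)
  comp <- array(FALSE, n)
  if (!inrange[seed[1] + 1, seed[2] + 1, seed[3] + 1]) return(comp)
  comp[seed[1] + 1, seed[2] + 1, seed[3] + 1] <- TRUE
  offs <- expand.grid(di = -1:1, dj = -1:1, dk = -1:1)
  offs <- offs[!(offs$di == 0 & offs$dj == 0 & offs$dk == 0), ]
  if (connectivity == 6)
    offs <- offs[abs(offs$di) + abs(offs$dj) + abs(offs$dk) == 1, ]
  repeat {
    grown <- comp
    for (r in seq_len(nrow(offs))) {
      s <- comp
      if (offs$di[r] != 0) s <- shiftArr(s, -offs$di[r], 1)
      if (offs$dj[r] != 0) s <- shiftArr(s, -offs$dj[r], 2)
      if (offs$dk[r] != 0) s <- shiftArr(s, -offs$dk[r], 3)
      grown <- grown | s
    }
    grown <- grown & inrange
    if (identical(grown, comp)) break
    comp <- grown
  }
  comp
}

# all-pairs directed surface distances (rows of 0-based coordinates)
bfDirectedDists <- function(from, to) {
  d2 <- outer(rowSums(from^2), rowSums(to^2), "+") - 2 * from %*% t(to)
  sqrt(pmax(apply(d2, 1, min), 0))
}

bfHausdorff <- function(gt, test) {
  s1 <- surfaceVoxels(gt)
  s2 <- surfaceVoxels(test)
  max(max(bfDirectedDists(s1, s2)), max(bfDirectedDists(s2, s1)))
}

bfMasd <- function(gt, test) {
  s1 <- surfaceVoxels(gt)
  s2 <- surfaceVoxels(test)
  (mean(bfDirectedDists(s1, s2)) + mean(bfDirectedDists(s2, s1))) / 2
}

# signed distance field of a sphere, as a LevelSetField
sphereField <- function(n, R, ctr = rep((n - 1) / 2, 3)) {
  g <- expand.grid(x = 0:(n - 1), y = 0:(n - 1), z = 0:(n - 1))
  r <- sqrt((g$x - ctr[1])^2 + (g$y - ctr[2])^2 + (g$z - ctr[3])^2)
  new("LevelSetField", phi = array(r - R, c(n, n, n)), iteration = 0L,
      spacing = c(1, 1, 1), origin = c(0, 0, 0))
}

ballMask <- function(n, R, ctr = rep((n - 1) / 2, 3)) {
  VoxelMask(sphereField(n, R, ctr)@phi < 0)
}

# random blobby nonempty mask: thresholded smoothed noise
randomBlobMask <- function(n, seed) {
  set.seed(seed)
  a <- gaussianSmooth(array(rnorm(n^3), c(n, n, n)), 1.2)
  m <- a > stats::quantile(a, 0.8)
  if (!any(m)) m[n %/% 2, n %/% 2, n %/% 2] <- TRUE
  VoxelMask(m)
}

# radius of the inside region measured from its voxel volume
volumeRadius <- function(field) {
  (3 * sum(field@phi < 0) / (4 * pi))^(1 / 3)
}

# voxel-centre coordinate grids (0-based) for geometric checks
.coordGridsTest <- function(shape) {
  g <- expand.grid(x = 0:(shape[1] - 1), y = 0:(shape[2] - 1),
                   z = 0:(shape[3] - 1))
  list(x = array(g$x, shape), y = array(g$y, shape), z = array(g$z, shape))
}

# central-difference GAC term implemented independently in R (same scheme as
# the engine: clamped-index central differences, eps regularization,
# curvature clamped to +/-1)
rGeodesicTerm <- function(phi, g, eps = 1e-8, kclamp = 1) {
  ctr <- function(a, ax) (shiftArr(a, 1, ax) - shiftArr(a, -1, ax)) / 2
  sec <- function(a, ax) shiftArr(a, 1, ax) - 2 * a + shiftArr(a, -1, ax)
  crossd <- function(a, ax1, ax2) {
    (shiftArr(shiftArr(a, 1, ax1), 1, ax2) -
       shiftArr(shiftArr(a, 1, ax1), -1, ax2) -
       shiftArr(shiftArr(a, -1, ax1), 1, ax2) +
       shiftArr(shiftArr(a, -1, ax1), -1, ax2)) / 4
  }
  px <- ctr(phi, 1); py <- ctr(phi, 2); pz <- ctr(phi, 3)
  pxx <- sec(phi, 1); pyy <- sec(phi, 2); pzz <- sec(phi, 3)
  pxy <- crossd(phi, 1, 2); pxz <- crossd(phi, 1, 3); pyz <- crossd(phi, 2, 3)
  g2 <- px^2 + py^2 + pz^2
  gm <- sqrt(g2)
  kap <- ifelse(gm > eps,
                (pxx * (py^2 + pz^2) + pyy * (px^2 + pz^2) +
                   pzz * (px^2 + py^2) -
                   2 * (px * py * pxy + px * pz * pxz + py * pz * pyz)) /
                  (g2 * gm + eps),
                0)
  kap <- pmin(pmax(kap, -kclamp), kclamp)
  gx <- ctr(g, 1); gy <- ctr(g, 2); gz <- ctr(g, 3)
  dot <- ifelse(gm > eps, (gx * px + gy * py + gz * pz) / gm, 0)
  g * kap + dot
}
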
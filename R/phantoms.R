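## Synthetic 3D vessel + aneurysm phantoms with exact ground truth: a tubular
## parent artery (straight or curved), a saccular aneurysm sphere, and an
## optional bleb, rendered as a bright lumen on a dark background with
## partial-volume blur and additive Gaussian noise.

#' Phantom configuration
#'
#' Defaults emulate cropped contrast-CTA around an intracranial aneurysm at
#' roughly half-millimetre voxels: a parent artery of radius 5 voxels, a
#' saccular aneurysm of radius 10 voxels, lumen 200 HU on a 100 HU
#' background, 0.8-voxel partial-volume blur and 10 HU noise.
#'
#' @param shape integer(3) grid dimensions.
#' @param tubeRadius parent-artery radius (voxels); 0 with
#'   \code{tubePath = "none"} removes the artery.
#' @param tubePath "straight" (along x, centred in y/z), "curved" (circular
#'   arc bowing in z) or "none".
#' @param sacCenter numeric(3) sac centre in 0-based voxel coordinates, or
#'   NULL to place it adjacent to the tube at the grid centre ("auto"), or
#'   NA to omit the sac.
#' @param sacRadius sac radius (voxels).
#' @param blebCenter optional numeric(3) bleb centre, or NULL for none.
#' @param blebRadius bleb radius (voxels).
#' @param iFg,iBg foreground/background mean intensity (HU-scale).
#' @param noiseSd additive Gaussian noise SD (HU).
#' @param blurSd Gaussian PSF SD (voxels) applied to the shape indicator
#'   before the noise (partial-volume emulation).
#' @param seed RNG seed for the noise.
#' @return a \linkS4class{PhantomConfig}
#' @export
phantomConfig <- function(shape = c(64, 64, 64), tubeRadius = 5,
                          tubePath = "straight", sacCenter = NULL,
                          sacRadius = 10, blebCenter = NULL, blebRadius = 0,
                          iFg = 200, iBg = 100, noiseSd = 10, blurSd = 0.8,
                          seed = 1L) {
  shape <- as.integer(shape)
  if (is.null(sacCenter) && sacRadius > 0) {
    # sac sits on top (in z) of the tube midpoint
    ctr <- (shape - 1) / 2
    sacCenter <- c(ctr[1], ctr[2], ctr[3] + tubeRadius + sacRadius - 2)
  }
  if (length(sacCenter) == 1L && is.na(sacCenter)) sacCenter <- NULL
  new("PhantomConfig", shape = shape, tubeRadius = tubeRadius,
      tubePath = tubePath,
      sacCenter = if (is.null(sacCenter)) numeric(0) else as.numeric(sacCenter),
      sacRadius = sacRadius,
      blebCenter = if (is.null(blebCenter)) numeric(0)
                   else as.numeric(blebCenter),
      blebRadius = blebRadius, iFg = iFg, iBg = iBg,
      noiseSd = noiseSd, blurSd = blurSd, seed = as.integer(seed))
}

# voxel-centre coordinate grids (0-based)
.coordGrids <- function(shape) {
  ix <- array(rep(seq_len(shape[1]) - 1, times = shape[2] * shape[3]), shape)
  iy <- aperm(array(rep(seq_len(shape[2]) - 1,
                        times = shape[1] * shape[3]),
                    shape[c(2, 1, 3)]), c(2, 1, 3))
  iz <- aperm(array(rep(seq_len(shape[3]) - 1,
                        times = shape[1] * shape[2]),
                    shape[c(3, 1, 2)]), c(2, 3, 1))
  list(x = ix, y = iy, z = iz)
}

# squared distance from every voxel centre to a polyline (piecewise segments)
.distToPolyline <- function(g, pts) {
  d2 <- array(Inf, dim(g$x))
  for (s in seq_len(nrow(pts) - 1)) {
    a <- pts[s, ]
    b <- pts[s + 1, ]
    ab <- b - a
    len2 <- sum(ab^2)
    if (len2 == 0) next
    t <- ((g$x - a[1]) * ab[1] + (g$y - a[2]) * ab[2] +
            (g$z - a[3]) * ab[3]) / len2
    t <- pmin(pmax(t, 0), 1)
    d2 <- pmin(d2, (g$x - (a[1] + t * ab[1]))^2 +
                 (g$y - (a[2] + t * ab[2]))^2 +
                 (g$z - (a[3] + t * ab[3]))^2)
  }
  d2
}

#' Generate a phantom volume and its exact ground-truth mask
#'
#' The ground truth is the union of tube, sac and bleb, voxelized by the
#' centre-inside rule. The volume is
#' \code{iBg + (iFg - iBg) * blur(indicator) + noise}: blur first (emulating
#' CT partial volume at the boundary), then voxel-independent Gaussian noise.
#' Deterministic for a given config (the caller's RNG state is preserved).
#'
#' @param cfg a \linkS4class{PhantomConfig}
#' @return list with \code{volume} (\linkS4class{ScanVolume}), \code{mask}
#'   (\linkS4class{VoxelMask}) and \code{config}
#' @examples
#' ph <- makePhantom(phantomConfig(shape = c(32, 32, 32), tubeRadius = 4,
#'                                 sacRadius = 6, noiseSd = 0, blurSd = 0))
#' sort(unique(as.vector(voxelData(ph$volume)))) # exactly two intensities
#' @export
makePhantom <- function(cfg) {
  stopifnot(is(cfg, "PhantomConfig"))
  shape <- cfg@shape
  g <- .coordGrids(shape)
  gt <- array(FALSE, shape)
  ctr <- (shape - 1) / 2
  if (cfg@tubePath != "none" && cfg@tubeRadius > 0) {
    if (cfg@tubePath == "straight") {
      d2 <- (g$y - ctr[2])^2 + (g$z - ctr[3])^2
    } else {
      # circular arc in the x-z plane: ends at the x faces, bowing toward +z
      bow <- shape[3] * 0.22
      t <- seq(0, 1, length.out = 65)
      pts <- cbind(t * (shape[1] - 1),
                   rep(ctr[2], length(t)),
                   ctr[3] - bow / 2 + bow * sin(pi * t))
      d2 <- .distToPolyline(g, pts)
    }
    gt <- gt | (d2 <= cfg@tubeRadius^2)
  }
  if (length(cfg@sacCenter) == 3L && cfg@sacRadius > 0) {
    sc <- cfg@sacCenter
    if (any(sc - cfg@sacRadius < -0.5) || any(sc + cfg@sacRadius > shape - 0.5))
      stop("sac extends outside the grid")
    gt <- gt | ((g$x - sc[1])^2 + (g$y - sc[2])^2 +
                  (g$z - sc[3])^2 <= cfg@sacRadius^2)
  }
  if (length(cfg@blebCenter) == 3L && cfg@blebRadius > 0) {
    bc <- cfg@blebCenter
    if (any(bc - cfg@blebRadius < -0.5) || any(bc + cfg@blebRadius > shape - 0.5))
      stop("bleb extends outside the grid")
    gt <- gt | ((g$x - bc[1])^2 + (g$y - bc[2])^2 +
                  (g$z - bc[3])^2 <= cfg@blebRadius^2)
  }
  if (!any(gt)) stop("phantom geometry produced an empty mask")
  ind <- gaussianSmooth(array(as.numeric(gt), shape), cfg@blurSd)
  vol <- cfg@iBg + (cfg@iFg - cfg@iBg) * ind
  if (cfg@noiseSd > 0) {
    hadSeed <- exists(".Random.seed", envir = globalenv())
    if (hadSeed) oldSeed <- get(".Random.seed", envir = globalenv())
    set.seed(cfg@seed)
    vol <- vol + array(rnorm(prod(shape), 0, cfg@noiseSd), shape)
    if (hadSeed) assign(".Random.seed", oldSeed, envir = globalenv())
    else rm(".Random.seed", envir = globalenv())
  }
  list(volume = ScanVolume(vol), mask = VoxelMask(gt), config = cfg)
}

#' Fixed battery of validation phantoms
#'
#' A desk-scale analogue of a multi-case clinical validation: four 64-cubed
#' phantoms covering the anatomies that stress segmentation methods —
#' a straight parent artery with a saccular aneurysm; a curved artery with a
#' large sac; an aneurysm carrying a small bleb; and a small low-contrast
#' sac. Foreground/background separation is at least 3 pooled noise SDs in
#' every case.
#'
#' @param seed base RNG seed; case i uses \code{seed + i - 1}.
#' @return named list of phantoms, each as returned by
#'   \code{\link{makePhantom}}
#' @export
caseSuite <- function(seed = 1L) {
  seed <- as.integer(seed)
  n <- c(64L, 64L, 64L)
  ctr <- (n - 1) / 2
  sacTop <- function(tubeR, sacR) c(ctr[1], ctr[2], ctr[3] + tubeR + sacR - 2)
  cfgs <- list(
    `straight-sac` = phantomConfig(shape = n, tubeRadius = 5,
                                   tubePath = "straight", sacRadius = 10,
                                   seed = seed),
    `curved-large-sac` = phantomConfig(shape = n, tubeRadius = 5,
                                       tubePath = "curved",
                                       sacCenter = c(ctr[1], ctr[2],
                                                     ctr[3] + 12),
                                       sacRadius = 12, seed = seed + 1L),
    `bleb` = phantomConfig(shape = n, tubeRadius = 5, tubePath = "straight",
                           sacCenter = sacTop(5, 9), sacRadius = 9,
                           blebCenter = sacTop(5, 9) + c(0, 0, 9 + 2),
                           blebRadius = 4, seed = seed + 2L),
    `small-low-contrast` = phantomConfig(shape = n, tubeRadius = 4,
                                         tubePath = "straight",
                                         sacCenter = sacTop(4, 5),
                                         sacRadius = 5, iFg = 160,
                                         seed = seed + 3L))
  lapply(cfgs, makePhantom)
}
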
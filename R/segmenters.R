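## The three segmentation algorithms: region growing with intensity
## thresholds (RGT), the Chan-Vese model (CV), and the threshold-based level
## set (TLS).

#' Region-growing parameters
#'
#' @param seed integer(3), 0-based voxel index of the seed point.
#' @param T1,T2 low and high intensity thresholds (HU).
#' @param connectivity 6 or 26 (default 26).
#' @return an \linkS4class{RGTParams}
#' @export
rgtParams <- function(seed, T1, T2, connectivity = 26L) {
  new("RGTParams", seed = as.integer(seed), T1 = as.numeric(T1),
      T2 = as.numeric(T2), connectivity = as.integer(connectivity))
}

#' Chan-Vese parameters
#'
#' Defaults are the fixed setting used for vascular segmentation:
#' \code{lambda1 = lambda2 = 0.001}, \code{alpha = 0}, \code{beta = 0.3}.
#'
#' @param lambda1,lambda2 region-fit weights.
#' @param alpha area/propagation constant (enters the speed as -alpha).
#' @param beta curvature weight.
#' @param nIter step budget.
#' @param smoothSigma optional Gaussian pre-smoothing of the intensities the
#'   evolution sees (0 = raw).
#' @return a \linkS4class{CVParams}
#' @export
cvParams <- function(lambda1 = 0.001, lambda2 = 0.001, alpha = 0,
                     beta = 0.3, nIter = 2500L, smoothSigma = 0) {
  new("CVParams", lambda1 = lambda1, lambda2 = lambda2, alpha = alpha,
      beta = beta, nIter = as.integer(nIter), smoothSigma = smoothSigma)
}

#' Threshold-based level-set parameters
#'
#' Defaults are the fixed setting \code{alpha = 10}, \code{beta = 3} with the
#' boundary-function slope \code{c = 0.5} (the lower end of the recommended
#' stable range 0.5-0.7) and a box initial surface inset 2 voxels from the
#' ROI faces.
#'
#' @param alpha propagation constant of the region term.
#' @param beta curvature weight of the geodesic term.
#' @param c boundary-function slope constant.
#' @param inset initial box inset (voxels).
#' @param kMode "balanced" or "as-printed" (see \code{\link{estimateK}}).
#' @param tolT threshold stopping tolerance (HU).
#' @param maxOuter maximum outer threshold iterations.
#' @param innerSteps PDE steps per outer iteration.
#' @param smoothSigma Gaussian pre-smoothing (voxels) of the volume used for
#'   the gradient map.
#' @param cv Chan-Vese parameters for the pre-segmentation.
#' @return a \linkS4class{TLSParams}
#' @export
tlsParams <- function(alpha = 10, beta = 3, c = 0.5, inset = 2L,
                      kMode = c("balanced", "as-printed"), tolT = 0.5,
                      maxOuter = 30L, innerSteps = 25L, smoothSigma = 0.5,
                      cv = cvParams(smoothSigma = 1)) {
  kMode <- match.arg(kMode)
  new("TLSParams", alpha = alpha, beta = beta, c = c, inset = as.integer(inset),
      kMode = kMode, tolT = tolT, maxOuter = as.integer(maxOuter),
      innerSteps = as.integer(innerSteps), smoothSigma = smoothSigma, cv = cv)
}

#' Region growing between two intensity thresholds
#'
#' Starting from a seed voxel, accepts every connected neighbour whose
#' intensity lies in \code{[T1, T2]}; the result is the maximal connected
#' component of the in-range set containing the seed, under the chosen
#' connectivity. Deterministic.
#'
#' @param v a \linkS4class{ScanVolume}
#' @param p an \linkS4class{RGTParams}; the seed intensity must itself be in
#'   range.
#' @return a \linkS4class{VoxelMask}
#' @export
regionGrow <- function(v, p) {
  stopifnot(is(v, "ScanVolume"), is(p, "RGTParams"))
  d <- dim(v@data)
  if (any(p@seed < 0L) || any(p@seed >= d))
    stop("seed outside the volume")
  sval <- v@data[p@seed[1] + 1, p@seed[2] + 1, p@seed[3] + 1]
  if (sval < p@T1 || sval > p@T2)
    stop(sprintf("seed rejected: intensity %.6g outside [%.6g, %.6g]",
                 sval, p@T1, p@T2))
  inrange <- v@data >= p@T1 & v@data <= p@T2
  out <- cpp_flood(as.logical(inrange), as.integer(d), p@seed,
                   p@connectivity)
  VoxelMask(array(out, d), v@spacing, v@origin)
}

# shared inner loop: evolve under a speed closure with periodic
# reinitialization and an interface-change stopping rule; the far field is
# clamped after every reinitialization cycle (only a band around the
# interface is restored to a distance function, and the untouched far field
# would otherwise steepen without bound under a nonzero speed)
.evolve <- function(field, speedFun, nIter, betaEff, reinitEvery = 20L,
                    changeTol = 0.001, farClamp = 6, label = "evolution") {
  prevCycle <- field
  steps <- 0L
  while (steps < nIter) {
    block <- min(reinitEvery, nIter - steps)
    for (s in seq_len(block)) {
      F <- speedFun(field)    # list(adv = ..., curv = ...)
      dt <- stableTimeStep(abs(F$adv) + abs(F$curv), betaEff)
      field <- levelSetStep(field, F$adv, dt = dt, curvatureSpeed = F$curv)
    }
    steps <- steps + block
    nin <- sum(field@phi < 0)
    if (nin == 0L || nin == length(field@phi))
      stop(label, " collapse: interface vanished after ", steps, " steps")
    field <- reinitializeLevelSet(field)
    field@phi <- pmin(pmax(field@phi, -farClamp), farClamp)
    if (.interfaceChange(field, prevCycle) < changeTol) break
    prevCycle <- field
  }
  field
}

#' Chan-Vese segmentation
#'
#' Evolves the region-competition PDE
#' \deqn{\phi_t = |\nabla\phi| [\lambda_2 (I-\mu_{out})^2 - \lambda_1
#'  (I-\mu_{in})^2 - \alpha + \beta \kappa]}
#' with \eqn{\mu_{in}, \mu_{out}} recomputed from the current hard partition
#' \eqn{\{\phi<0\} / \{\phi\ge 0\}} at every step. Runs until the step budget
#' is exhausted or the interface changes by less than 0.1\% of the voxels
#' between reinitialization cycles.
#'
#' @param v a \linkS4class{ScanVolume}
#' @param phi0 initial \linkS4class{LevelSetField} with both signs present.
#' @param p a \linkS4class{CVParams}
#' @return list with \code{mask}, \code{field}, \code{muIn}, \code{muOut}
#' @export
chanVese <- function(v, phi0, p = cvParams()) {
  stopifnot(is(v, "ScanVolume"), is(phi0, "LevelSetField"),
            identical(dim(v), dim(phi0)))
  if (all(phi0@phi >= 0) || all(phi0@phi <= 0))
    stop("phi0 must have both signs")
  I <- gaussianSmooth(v@data, p@smoothSigma)
  speedFun <- function(field) {
    inside <- field@phi < 0
    nin <- sum(inside)
    if (nin == 0L || nin == length(I))
      stop("Chan-Vese collapse: a phase became empty")
    muIn <- mean(I[inside])
    muOut <- mean(I[!inside])
    list(adv = p@lambda2 * (I - muOut)^2 - p@lambda1 * (I - muIn)^2 - p@alpha,
         curv = p@beta * levelSetCurvature(field))
  }
  field <- .evolve(phi0, speedFun, p@nIter, betaEff = p@beta,
                   label = "Chan-Vese")
  inside <- field@phi < 0
  list(mask = maskFromLevelSet(field), field = field,
       muIn = mean(I[inside]), muOut = mean(I[!inside]))
}

#' Edge-stopping boundary map
#'
#' \eqn{g(|\nabla I|) = 1/(1 + c |\nabla I|^2)} with the gradient magnitude by
#' central differences, optionally after Gaussian pre-smoothing of the
#' volume. Values lie in (0, 1]: close to 1 in homogeneous regions, small on
#' strong edges, so the geodesic term slows the surface at vascular
#' boundaries.
#'
#' @param v a \linkS4class{ScanVolume}
#' @param c slope constant (> 0); larger c makes g fall off faster.
#' @param smoothSigma pre-smoothing SD in voxels (0 disables).
#' @return 3D numeric array
#' @export
boundaryMap <- function(v, c = 0.5, smoothSigma = 0.5) {
  stopifnot(is(v, "ScanVolume"))
  if (c <= 0) stop("c must be > 0")
  I <- gaussianSmooth(v@data, smoothSigma)
  gm <- array(cpp_gradmag(as.numeric(I), .dims(I)), dim(I))
  1 / (1 + c * gm^2)
}

#' TLS speed field
#'
#' \eqn{F = \alpha (I - T) + \beta\,\mathrm{div}(g \nabla\phi/|\nabla\phi|)}.
#' The region term expands the surface wherever the intensity exceeds the
#' threshold and contracts it elsewhere; the geodesic term regularizes the
#' surface and anchors it to image edges. With \eqn{\beta = 0} the sign of F
#' is the region-growing lower-threshold criterion; with \eqn{\alpha = 0} the
#' speed is the geodesic active contour term.
#'
#' @param v a \linkS4class{ScanVolume}
#' @param ls the current \linkS4class{LevelSetField}
#' @param T intensity threshold (HU).
#' @param g boundary map from \code{\link{boundaryMap}}.
#' @param p a \linkS4class{TLSParams}
#' @return 3D numeric array of speeds
#' @export
tlsSpeed <- function(v, ls, T, g, p = tlsParams()) {
  stopifnot(identical(dim(v), dim(ls)), identical(dim(v@data), dim(g)))
  p@alpha * (v@data - T) + p@beta * geodesicDivergence(ls, g)
}

# fixed block of TLS steps (used by the outer threshold iteration); region
# term upwinded, geodesic term differenced centrally
.tlsEvolve <- function(v, field, T, g, p, nSteps) {
  region <- p@alpha * (v@data - T)
  speedFun <- function(f) list(adv = region,
                               curv = p@beta * geodesicDivergence(f, g))
  .evolve(field, speedFun, nSteps, betaEff = p@beta * max(g),
          changeTol = 0, label = "TLS")
}

#' Fully automatic threshold-based level-set segmentation
#'
#' The complete TLS pipeline on a cropped ROI volume; no seed point or manual
#' threshold is required. (1) The level set is initialized as a box inset
#' \code{p@inset} voxels from the ROI faces; (2) a Chan-Vese run provides the
#' pre-segmentation from which the initial statistics are taken; (3) the
#' threshold is refined iteratively while the TLS PDE evolves the surface
#' (\code{\link{iterateThreshold}}).
#'
#' @param v a \linkS4class{ScanVolume} containing both vessel and background.
#' @param p a \linkS4class{TLSParams}
#' @return list with \code{mask} (\linkS4class{VoxelMask}), \code{threshold}
#'   (\linkS4class{ThresholdEstimate}) and \code{field}
#' @export
segmentTLS <- function(v, p = tlsParams()) {
  stopifnot(is(v, "ScanVolume"))
  phi0 <- initBoxLevelSet(dim(v), inset = p@inset, spacing = v@spacing,
                          origin = v@origin)
  pre <- tryCatch(chanVese(v, phi0, p@cv),
                  error = function(e) stop("pre-segmentation stage: ",
                                           conditionMessage(e)))
  g <- boundaryMap(v, c = p@c, smoothSigma = p@smoothSigma)
  res <- tryCatch(iterateThreshold(v, pre$mask, p, g = g, field = pre$field),
                  error = function(e) stop("threshold iteration stage: ",
                                           conditionMessage(e)))
  list(mask = res$mask, threshold = res$estimate, field = res$field)
}

#' Region growing seeded from a TLS threshold
#'
#' The region-growing baseline configured as in the validation protocol: the
#' low threshold is the converged TLS threshold, the high threshold the
#' maximum intensity of the volume.
#'
#' @param v a \linkS4class{ScanVolume}
#' @param seed integer(3) seed voxel (0-based).
#' @param tlsT converged TLS threshold (HU).
#' @param connectivity 6 or 26.
#' @return a \linkS4class{VoxelMask}
#' @export
segmentRGTAuto <- function(v, seed, tlsT, connectivity = 26L) {
  T2 <- max(v@data, tlsT)   # a threshold above the maximum rejects the seed
  regionGrow(v, rgtParams(seed = seed, T1 = tlsT, T2 = T2,
                          connectivity = connectivity))
}
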
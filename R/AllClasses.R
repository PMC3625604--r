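## Central S4 data model: volumes, masks, level-set fields, region statistics,
## threshold estimates, metric reports, parameter bundles.

#' ScanVolume: a 3D scalar intensity grid
#'
#' Holds the image to be segmented: a 3D array of intensities (HU-scale for
#' CTA-like data) together with per-axis voxel spacing (mm) and a physical
#' origin offset (mm). The internal axis order is always (x, y, z); readers
#' normalize the on-disk layout to this convention.
#'
#' @slot data 3D numeric array of intensities.
#' @slot spacing numeric(3), per-axis voxel size, all > 0.
#' @slot origin numeric(3), physical offset of voxel (0,0,0).
#' @export
setClass("ScanVolume",
  representation(data = "array", spacing = "numeric", origin = "numeric"),
  validity = function(object) {
    d <- dim(object@data)
    if (length(d) != 3L) return("data must be a 3D array")
    if (any(d < 3L)) return("all three dimensions must be >= 3")
    if (length(object@spacing) != 3L || any(!is.finite(object@spacing)) ||
        any(object@spacing <= 0))
      return("spacing must be three finite positive values")
    if (length(object@origin) != 3L || any(!is.finite(object@origin)))
      return("origin must be three finite values")
    if (any(!is.finite(object@data)))
      return("intensities must be finite")
    TRUE
  })

#' VoxelMask: a binary voxel set aligned with a ScanVolume
#'
#' @slot data 3D logical array (TRUE = foreground).
#' @slot spacing numeric(3), per-axis voxel size of the source volume.
#' @slot origin numeric(3), physical offset.
#' @export
setClass("VoxelMask",
  representation(data = "array", spacing = "numeric", origin = "numeric"),
  validity = function(object) {
    d <- dim(object@data)
    if (length(d) != 3L) return("data must be a 3D array")
    if (!is.logical(object@data)) return("mask data must be logical")
    if (anyNA(object@data)) return("mask data must not contain NA")
    if (length(object@spacing) != 3L || any(object@spacing <= 0))
      return("spacing must be three positive values")
    TRUE
  })

#' LevelSetField: scalar field whose zero level set is the evolving surface
#'
#' By convention \eqn{\phi < 0} inside the segmented region. After
#' (re)initialization the field is approximately a signed distance function
#' near the interface.
#'
#' @slot phi 3D numeric array.
#' @slot iteration non-negative integer, number of PDE steps taken.
#' @slot spacing,origin geometry inherited from the source volume.
#' @export
setClass("LevelSetField",
  representation(phi = "array", iteration = "integer",
                 spacing = "numeric", origin = "numeric"),
  validity = function(object) {
    if (length(dim(object@phi)) != 3L) return("phi must be a 3D array")
    if (any(!is.finite(object@phi))) return("phi must be finite everywhere")
    if (length(object@iteration) != 1L || object@iteration < 0L)
      return("iteration must be a single non-negative integer")
    TRUE
  })

#' VolumeROI: an axis-aligned region of interest
#'
#' Half-open voxel index box \code{[lower, upper)}, 0-based, used to crop a
#' volume to the neighbourhood of the target anatomy.
#'
#' @slot lower integer(3), inclusive start indices (0-based).
#' @slot upper integer(3), exclusive end indices.
#' @export
setClass("VolumeROI",
  representation(lower = "integer", upper = "integer"),
  validity = function(object) {
    if (length(object@lower) != 3L || length(object@upper) != 3L)
      return("lower and upper must each have three components")
    if (any(object@lower < 0L)) return("lower must be non-negative")
    if (any(object@lower >= object@upper))
      return("lower must be strictly below upper on every axis")
    TRUE
  })

#' RegionStats: foreground/background intensity statistics
#'
#' Sample means and standard deviations (denominator n-1) of the image
#' intensity under a foreground mask and a background mask. The threshold
#' model assumes the segmented object is brighter than its background
#' (muA > muB); that assumption is checked where it is consumed
#' (\code{\link{estimateK}}).
#'
#' @slot muA,sigmaA foreground mean and SD (HU).
#' @slot muB,sigmaB background mean and SD (HU).
#' @slot nFg,nBg voxel counts of the two regions.
#' @export
setClass("RegionStats",
  representation(muA = "numeric", sigmaA = "numeric",
                 muB = "numeric", sigmaB = "numeric",
                 nFg = "integer", nBg = "integer"),
  validity = function(object) {
    if (object@sigmaA < 0 || object@sigmaB < 0)
      return("standard deviations must be non-negative")
    if (object@nFg < 2L || object@nBg < 2L)
      return("each region needs at least 2 voxels for an SD")
    TRUE
  })

#' ThresholdEstimate: the automatic threshold and its convergence trace
#'
#' @slot k confidence multiplier (dimensionless; NA when degenerate).
#' @slot T final intensity threshold (HU).
#' @slot history data.frame with one row per outer iteration
#'   (iteration, T, k, muA, sigmaA, muB, sigmaB).
#' @slot converged logical, whether |T_i - T_{i-1}| fell below the tolerance.
#' @export
setClass("ThresholdEstimate",
  representation(k = "numeric", T = "numeric", history = "data.frame",
                 converged = "logical"))

#' MetricsReport: the six validation metrics for a mask pair
#'
#' Percent volume difference (VD), percent Jaccard overlap (JM, with the Dice
#' variant also recorded), percent false positive and false negative ratios
#' (both against the ground-truth volume), and the Hausdorff (HD) and mean
#' absolute surface distance (MASD) in voxel units.
#'
#' @slot VD,JM,JMdice,rfp,rfn,HD,MASD the metric values.
#' @slot V1,V2 voxel counts of ground truth and test mask.
#' @export
setClass("MetricsReport",
  representation(VD = "numeric", JM = "numeric", JMdice = "numeric",
                 rfp = "numeric", rfn = "numeric",
                 HD = "numeric", MASD = "numeric",
                 V1 = "integer", V2 = "integer"))

#' RGTParams: region-growing threshold parameters
#'
#' @slot seed integer(3), 0-based voxel index of the seed point.
#' @slot T1,T2 low and high intensity thresholds (HU), T1 <= T2.
#' @slot connectivity 6 or 26.
#' @export
setClass("RGTParams",
  representation(seed = "integer", T1 = "numeric", T2 = "numeric",
                 connectivity = "integer"),
  validity = function(object) {
    if (length(object@seed) != 3L) return("seed must be a voxel index (i,j,k)")
    if (object@T1 > object@T2) return("T1 must be <= T2")
    if (!object@connectivity %in% c(6L, 26L))
      return("connectivity must be 6 or 26")
    TRUE
  })

#' CVParams: Chan-Vese evolution parameters
#'
#' @slot lambda1,lambda2 region-fit weights (>= 0).
#' @slot alpha area/propagation constant (sign as in the evolution PDE,
#'   entering the speed as -alpha).
#' @slot beta curvature weight.
#' @slot nIter step budget.
#' @slot smoothSigma optional Gaussian pre-smoothing (voxels) of the volume
#'   the region means are computed from; 0 (the default) evolves on the raw
#'   intensities.
#' @export
setClass("CVParams",
  representation(lambda1 = "numeric", lambda2 = "numeric",
                 alpha = "numeric", beta = "numeric", nIter = "integer",
                 smoothSigma = "numeric"),
  prototype(lambda1 = 0.001, lambda2 = 0.001, alpha = 0, beta = 0.3,
            nIter = 2500L, smoothSigma = 0),
  validity = function(object) {
    if (object@lambda1 < 0 || object@lambda2 < 0)
      return("lambda1 and lambda2 must be >= 0")
    if (object@nIter < 1L) return("nIter must be >= 1")
    if (object@smoothSigma < 0) return("smoothSigma must be >= 0")
    TRUE
  })

#' TLSParams: threshold-based level-set parameters
#'
#' @slot alpha propagation constant weighting the region term (>= 0; with 0
#'   the speed reduces to the geodesic active contour term).
#' @slot beta curvature weight of the geodesic boundary term (>= 0).
#' @slot c slope constant of the boundary detect function (> 0).
#' @slot inset initial box inset in voxels.
#' @slot kMode "balanced" (k = (muA-muB)/(sigmaA+sigmaB), derivation-consistent)
#'   or "as-printed" (denominator sigmaA - sigmaB).
#' @slot tolT stopping tolerance on the threshold (HU).
#' @slot maxOuter maximum outer threshold iterations.
#' @slot innerSteps PDE steps per outer iteration.
#' @slot smoothSigma Gaussian pre-smoothing (voxels) for the gradient map.
#' @slot cv Chan-Vese parameters for the pre-segmentation.
#' @export
setClass("TLSParams",
  representation(alpha = "numeric", beta = "numeric", c = "numeric",
                 inset = "integer", kMode = "character", tolT = "numeric",
                 maxOuter = "integer", innerSteps = "integer",
                 smoothSigma = "numeric", cv = "CVParams"),
  prototype(alpha = 10, beta = 3, c = 0.5, inset = 2L, kMode = "balanced",
            tolT = 0.5, maxOuter = 30L, innerSteps = 25L, smoothSigma = 0.5),
  validity = function(object) {
    if (object@alpha < 0) return("alpha must be >= 0")
    if (object@beta < 0) return("beta must be >= 0")
    if (object@c <= 0) return("c must be > 0")
    if (object@inset < 1L) return("inset must be >= 1")
    if (!object@kMode %in% c("balanced", "as-printed"))
      return("kMode must be 'balanced' or 'as-printed'")
    TRUE
  })

#' PhantomConfig: synthetic vessel + aneurysm phantom description
#'
#' @slot shape integer(3) grid dimensions.
#' @slot tubeRadius parent-artery radius (voxels).
#' @slot tubePath "straight" or "curved".
#' @slot sacCenter numeric(3) aneurysm sphere centre (0-based voxel coords),
#'   or numeric(0) for no sac.
#' @slot sacRadius aneurysm sphere radius (voxels).
#' @slot blebCenter,blebRadius optional secondary bulge (numeric(0) disables).
#' @slot iFg,iBg mean foreground/background intensity (HU-scale), iFg > iBg.
#' @slot noiseSd additive Gaussian noise SD (HU).
#' @slot blurSd Gaussian PSF SD (voxels) applied to the shape indicator.
#' @slot seed RNG seed for the noise.
#' @export
setClass("PhantomConfig",
  representation(shape = "integer", tubeRadius = "numeric",
                 tubePath = "character", sacCenter = "numeric",
                 sacRadius = "numeric", blebCenter = "numeric",
                 blebRadius = "numeric", iFg = "numeric", iBg = "numeric",
                 noiseSd = "numeric", blurSd = "numeric", seed = "integer"),
  validity = function(object) {
    if (length(object@shape) != 3L || any(object@shape < 8L))
      return("shape must be three dimensions, each >= 8")
    if (object@iFg <= object@iBg)
      return("iFg must exceed iBg (bright object on dark background)")
    if (object@tubeRadius <= 0 && length(object@sacCenter) == 0L)
      return("phantom needs a tube or a sac")
    if (!object@tubePath %in% c("straight", "curved", "none"))
      return("tubePath must be 'straight', 'curved' or 'none'")
    if (object@noiseSd < 0 || object@blurSd < 0)
      return("noiseSd and blurSd must be >= 0")
    TRUE
  })
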
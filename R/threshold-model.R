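## Automatic intensity-threshold estimation: Chebyshev confidence bounds, the
## k estimator linking aneurysm and background statistics, and the iterative
## threshold refinement that drives the TLS evolution.

#' Chebyshev confidence bounds for a multiplier k
#'
#' Distribution-free tail bounds: the two-sided inequality
#' \eqn{P(|X-\mu| \ge k\sigma) \le 1/k^2} and the one-tailed version
#' \eqn{P(X-\mu \ge k\sigma) \le 1/(1+k^2)}. At \eqn{k = 1} the one-sided
#' bound is 0.5: at least half the population lies below one standard
#' deviation above the mean.
#'
#' @param k positive confidence multiplier.
#' @return list with elements \code{twoSided} and \code{oneSided}
#' @examples
#' chebyshevBounds(2) # twoSided 0.25, oneSided 0.2
#' @export
chebyshevBounds <- function(k) {
  if (!is.numeric(k) || length(k) != 1L || !is.finite(k) || k <= 0)
    stop("k must be a single positive number")
  list(twoSided = 1 / k^2, oneSided = 1 / (1 + k^2))
}

#' Compute region statistics under a foreground and a background mask
#'
#' Sample means and SDs (denominator n-1) of the volume intensities inside
#' each mask. The masks must be nonempty and disjoint.
#'
#' @param v a \linkS4class{ScanVolume}
#' @param m foreground \linkS4class{VoxelMask}
#' @param background background \linkS4class{VoxelMask}
#' @return a \linkS4class{RegionStats}
#' @export
statsFromMask <- function(v, m, background) {
  stopifnot(identical(dim(v), dim(m)), identical(dim(v), dim(background)))
  if (any(m@data & background@data))
    stop("foreground and background masks must be disjoint")
  a <- v@data[m@data]
  b <- v@data[background@data]
  if (length(a) < 2L || length(b) < 2L)
    stop("degenerate statistics: each region needs at least 2 voxels")
  new("RegionStats", muA = mean(a), sigmaA = sd(a),
      muB = mean(b), sigmaB = sd(b),
      nFg = length(a), nBg = length(b))
}

setMethod("show", "RegionStats", function(object) {
  cat(sprintf(
    "RegionStats: fg %.2f +/- %.2f (n=%d) | bg %.2f +/- %.2f (n=%d)\n",
    object@muA, object@sigmaA, object@nFg,
    object@muB, object@sigmaB, object@nBg))
})

#' Estimate the confidence multiplier k from region statistics
#'
#' The threshold model equates the lower intensity bound of the bright object
#' with the upper bound of its background, \eqn{\mu_a - k\sigma_a = \mu_b +
#' k\sigma_b} with a common k, giving \eqn{k = (\mu_a-\mu_b)/(\sigma_a+
#' \sigma_b)} (mode \code{"balanced"}, the default: always positive for a
#' bright object, never singular). Mode \code{"as-printed"} uses the
#' denominator \eqn{\sigma_a-\sigma_b} instead, which is singular when the two
#' SDs coincide; it is provided for comparison with the published formula.
#'
#' @param stats a \linkS4class{RegionStats} with \code{muA > muB}.
#' @param mode "balanced" or "as-printed".
#' @return the multiplier k
#' @examples
#' s <- new("RegionStats", muA = 200, sigmaA = 30, muB = 100, sigmaB = 10,
#'          nFg = 10L, nBg = 10L)
#' estimateK(s)                     # 2.5
#' estimateK(s, mode = "as-printed") # 5
#' @export
estimateK <- function(stats, mode = c("balanced", "as-printed")) {
  mode <- match.arg(mode)
  if (stats@muA <= stats@muB)
    stop("assumption violation: foreground mean must exceed background mean")
  denom <- if (mode == "balanced") stats@sigmaA + stats@sigmaB
           else stats@sigmaA - stats@sigmaB
  if (abs(denom) < .Machine$double.eps^0.5)
    stop("degenerate statistics: zero denominator in k estimator")
  (stats@muA - stats@muB) / denom
}

#' Intensity threshold from region statistics and a multiplier
#'
#' \eqn{T = \mu_a - k \sigma_a}, the lower confidence bound of the foreground
#' intensity. With the balanced-mode k this equals \eqn{\mu_b + k\sigma_b}
#' exactly. A threshold falling outside the open interval
#' \eqn{(\mu_b, \mu_a)} is clamped 5\% inside the nearer end, with a warning,
#' to keep the region speed sign-informative on degenerate statistics.
#'
#' @param stats a \linkS4class{RegionStats}
#' @param k positive multiplier.
#' @return the threshold T (HU)
#' @export
thresholdFromStats <- function(stats, k) {
  if (k <= 0) stop("k must be > 0")
  T <- stats@muA - k * stats@sigmaA
  if (stats@sigmaA == 0) {
    warning("zero-variance foreground: threshold degenerates to the foreground mean")
    return(T)
  }
  span <- stats@muA - stats@muB
  if (span > 0) {
    if (T <= stats@muB) {
      warning("threshold below background mean; clamped into (muB, muA)")
      T <- stats@muB + 0.05 * span
    } else if (T >= stats@muA) {
      warning("threshold above foreground mean; clamped into (muB, muA)")
      T <- stats@muA - 0.05 * span
    }
  }
  T
}

# erode a logical array by one voxel (6-connectivity); used to strip the
# partial-volume band off both statistics regions
.erode1 <- function(m) {
  n <- dim(m)
  out <- m
  shift <- function(a, d, ax) {
    idx <- list(seq_len(n[1]), seq_len(n[2]), seq_len(n[3]))
    idx[[ax]] <- pmin(pmax(idx[[ax]] + d, 1L), n[ax])
    a[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
  }
  for (ax in 1:3) for (d in c(-1L, 1L)) out <- out & shift(m, d, ax)
  out
}

# statistics regions for the threshold update: the 1-voxel interface band is
# excluded from both sides, because partial-volume voxels belong to neither
# intensity population and bias the balance threshold downward
.bandedStats <- function(v, maskData) {
  fg <- .erode1(maskData)
  bg <- .erode1(!maskData)
  if (sum(fg) < 2L) fg <- maskData        # mask too thin to erode
  if (sum(bg) < 2L) bg <- !maskData
  statsFromMask(v, VoxelMask(fg, v@spacing, v@origin),
                VoxelMask(bg, v@spacing, v@origin))
}

#' Iteratively refine the threshold while evolving the TLS surface
#'
#' The outer loop of the threshold-based level set: from the current mask,
#' (a) compute foreground/background statistics (excluding a one-voxel
#' partial-volume band on both sides of the interface), (b) estimate k,
#' (c) derive the threshold \eqn{T_i}, (d) advance the TLS evolution by a
#' fixed block of PDE steps with \eqn{T_i}, (e) re-extract the mask. The loop
#' stops when \eqn{|T_i - T_{i-1}|} falls below \code{tolT} or after
#' \code{maxOuter} iterations. When both region SDs vanish (noise-free data)
#' the threshold is the midpoint \eqn{(\mu_a+\mu_b)/2}.
#'
#' @param v a \linkS4class{ScanVolume} (the cropped ROI).
#' @param initialMask starting \linkS4class{VoxelMask}, normally a Chan-Vese
#'   pre-segmentation; both phases must be present.
#' @param params a \linkS4class{TLSParams}.
#' @param g optional precomputed boundary map (recomputed if NULL).
#' @param field optional starting \linkS4class{LevelSetField}; defaults to
#'   the signed distance field of \code{initialMask}.
#' @return list with elements \code{estimate} (a
#'   \linkS4class{ThresholdEstimate}), \code{mask} and \code{field}
#' @export
iterateThreshold <- function(v, initialMask, params = tlsParams(), g = NULL,
                             field = NULL) {
  stopifnot(is(v, "ScanVolume"), is(initialMask, "VoxelMask"))
  n <- voxelCount(initialMask)
  if (n == 0L || n == length(initialMask@data))
    stop("initial mask must contain both phases")
  if (is.null(g)) g <- boundaryMap(v, c = params@c,
                                   smoothSigma = params@smoothSigma)
  if (is.null(field)) field <- sdfFromMask(initialMask)
  mask <- initialMask
  hist <- list()
  Tprev <- Inf
  converged <- FALSE
  k <- NA_real_
  T <- NA_real_
  for (i in seq_len(params@maxOuter)) {
    st <- .bandedStats(v, mask@data)
    if (st@sigmaA + st@sigmaB < 1e-9) {
      k <- NA_real_
      T <- (st@muA + st@muB) / 2   # noise-free: midpoint-balanced value
    } else {
      k <- estimateK(st, mode = params@kMode)
      T <- thresholdFromStats(st, k)
    }
    hist[[i]] <- data.frame(iteration = i, T = T, k = k,
                            muA = st@muA, sigmaA = st@sigmaA,
                            muB = st@muB, sigmaB = st@sigmaB)
    field <- .tlsEvolve(v, field, T, g, params, params@innerSteps)
    mask <- maskFromLevelSet(field)
    nf <- voxelCount(mask)
    if (nf == 0L || nf == length(mask@data))
      stop("evolution collapse at outer iteration ", i,
           ": mask became ", if (nf == 0L) "empty" else "full")
    if (abs(T - Tprev) < params@tolT) {
      converged <- TRUE
      break
    }
    Tprev <- T
  }
  est <- new("ThresholdEstimate", k = k, T = T,
             history = do.call(rbind, hist), converged = converged)
  list(estimate = est, mask = mask, field = field)
}

setMethod("show", "ThresholdEstimate", function(object) {
  cat(sprintf(
    "ThresholdEstimate: T = %.2f HU (k = %.3f) after %d iterations%s\n",
    object@T, object@k, nrow(object@history),
    if (object@converged) ", converged" else ", budget exhausted"))
})

#' Export a threshold convergence trace as CSV
#'
#' Writes the per-iteration record (iteration, T, k, muA, sigmaA, muB,
#' sigmaB) used to reproduce the threshold convergence plot.
#'
#' @param est a \linkS4class{ThresholdEstimate}
#' @param path output CSV path.
#' @return invisibly, \code{path}
#' @export
writeThresholdHistory <- function(est, path) {
  write.csv(est@history, path, row.names = FALSE)
  invisible(path)
}
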
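## The six validation metrics comparing a segmentation S2 against a ground
## truth S1: volume difference, Jaccard overlap, false positive/negative
## ratios, Hausdorff and mean absolute surface distance. Distances are
## Euclidean between surface-voxel centres, in voxel units (multiply by the
## spacing for physical units on isotropic grids).

.checkPair <- function(gt, test) {
  stopifnot(is(gt, "VoxelMask"), is(test, "VoxelMask"))
  if (!identical(dim(gt), dim(test)))
    stop("mask shapes differ: ", paste(dim(gt), collapse = "x"), " vs ",
         paste(dim(test), collapse = "x"))
}

#' Percent volume difference
#'
#' \eqn{VD = |V_2 - V_1| / V_1 \times 100} where \eqn{V_1} is the
#' ground-truth voxel count and \eqn{V_2} the test-mask count.
#'
#' @param gt ground-truth \linkS4class{VoxelMask} (nonempty).
#' @param test test \linkS4class{VoxelMask}.
#' @return percent
#' @export
volumeDifference <- function(gt, test) {
  .checkPair(gt, test)
  v1 <- voxelCount(gt)
  if (v1 == 0L) stop("undefined metric: empty ground truth")
  abs(voxelCount(test) - v1) / v1 * 100
}

#' Percent volume overlap (Jaccard, with a Dice variant)
#'
#' Default is the standard Jaccard measure
#' \eqn{|S_1 \cap S_2| / |S_1 \cup S_2| \times 100} (100 for identical
#' masks); \code{mode = "dice"} returns
#' \eqn{2|S_1 \cap S_2| / (|S_1| + |S_2|) \times 100}.
#'
#' @param gt,test the mask pair; the union must be nonempty.
#' @param mode "jaccard" or "dice".
#' @return percent
#' @export
jaccardMeasure <- function(gt, test, mode = c("jaccard", "dice")) {
  mode <- match.arg(mode)
  .checkPair(gt, test)
  i <- sum(gt@data & test@data)
  u <- sum(gt@data | test@data)
  if (u == 0L) stop("undefined metric: both masks empty")
  if (mode == "jaccard") i / u * 100
  else 2 * i / (voxelCount(gt) + voxelCount(test)) * 100
}

#' Percent false positive ratio
#'
#' \eqn{r_{fp} = (|S_2| - |S_1 \cap S_2|) / |S_1| \times 100}: the excess
#' voxels of the segmentation outside the ground truth, relative to the
#' ground-truth volume. Zero iff the test mask is contained in the truth.
#'
#' @inheritParams volumeDifference
#' @return percent
#' @export
falsePositiveRatio <- function(gt, test) {
  .checkPair(gt, test)
  v1 <- voxelCount(gt)
  if (v1 == 0L) stop("undefined metric: empty ground truth")
  (voxelCount(test) - sum(gt@data & test@data)) / v1 * 100
}

#' Percent false negative ratio
#'
#' \eqn{r_{fn} = (|S_1| - |S_1 \cap S_2|) / |S_1| \times 100}: the
#' ground-truth voxels missed by the segmentation.
#'
#' @inheritParams volumeDifference
#' @return percent
#' @export
falseNegativeRatio <- function(gt, test) {
  .checkPair(gt, test)
  v1 <- voxelCount(gt)
  if (v1 == 0L) stop("undefined metric: empty ground truth")
  (v1 - sum(gt@data & test@data)) / v1 * 100
}

#' Surface voxels of a mask
#'
#' Foreground voxels with at least one six-connected background neighbour;
#' grid faces count as background, so a mask touching the boundary still has
#' a closed surface.
#'
#' @param m a nonempty \linkS4class{VoxelMask}
#' @return integer matrix, one 0-based (i, j, k) row per surface voxel
#' @export
surfaceVoxels <- function(m) {
  stopifnot(is(m, "VoxelMask"))
  if (voxelCount(m) == 0L) stop("undefined metric: empty mask")
  a <- m@data
  n <- dim(a)
  # pad with background so grid faces count as background
  p <- array(FALSE, n + 2L)
  p[2:(n[1] + 1), 2:(n[2] + 1), 2:(n[3] + 1)] <- a
  interior <- p[2:(n[1] + 1), 2:(n[2] + 1), 2:(n[3] + 1)] &
    p[1:n[1], 2:(n[2] + 1), 2:(n[3] + 1)] &
    p[3:(n[1] + 2), 2:(n[2] + 1), 2:(n[3] + 1)] &
    p[2:(n[1] + 1), 1:n[2], 2:(n[3] + 1)] &
    p[2:(n[1] + 1), 3:(n[2] + 2), 2:(n[3] + 1)] &
    p[2:(n[1] + 1), 2:(n[2] + 1), 1:n[3]] &
    p[2:(n[1] + 1), 2:(n[2] + 1), 3:(n[3] + 2)]
  surf <- a & !interior
  which(surf, arr.ind = TRUE) - 1L
}

# directed surface distances from every surface voxel of `fromMask` to the
# nearest surface voxel of `toMask`, via the exact EDT of the target surface
.surfaceDistances <- function(fromMask, toMask) {
  n <- dim(fromMask@data)
  sFrom <- surfaceVoxels(fromMask)
  sTo <- surfaceVoxels(toMask)
  toArr <- array(FALSE, n)
  toArr[sTo + 1L] <- TRUE
  d <- array(cpp_edt(as.logical(toArr), as.integer(n)), n)
  d[sFrom + 1L]
}

#' Hausdorff distance between two mask surfaces
#'
#' The symmetric Hausdorff distance: the larger of the two directed maxima of
#' the nearest-surface distance, in voxel units.
#'
#' @param gt,test nonempty \linkS4class{VoxelMask}s of equal shape.
#' @return distance in voxels
#' @export
hausdorffDistance <- function(gt, test) {
  .checkPair(gt, test)
  max(max(.surfaceDistances(gt, test)), max(.surfaceDistances(test, gt)))
}

#' Mean absolute surface distance
#'
#' The average of the two directed mean nearest-surface distances, in voxel
#' units; size-independent, unlike the Hausdorff distance it is insensitive
#' to single outliers.
#'
#' @inheritParams hausdorffDistance
#' @return distance in voxels
#' @export
meanSurfaceDistance <- function(gt, test) {
  .checkPair(gt, test)
  (mean(.surfaceDistances(gt, test)) + mean(.surfaceDistances(test, gt))) / 2
}

#' Full six-metric validation report for a mask pair
#'
#' @param gt ground-truth \linkS4class{VoxelMask} (nonempty).
#' @param test test \linkS4class{VoxelMask}.
#' @return a \linkS4class{MetricsReport}
#' @examples
#' m <- VoxelMask(array(c(rep(TRUE, 32), rep(FALSE, 32)), c(4, 4, 4)))
#' segmentationReport(m, m) # identity: VD 0, JM 100, rfp 0, rfn 0, HD 0, MASD 0
#' @export
segmentationReport <- function(gt, test) {
  .checkPair(gt, test)
  new("MetricsReport",
      VD = volumeDifference(gt, test),
      JM = jaccardMeasure(gt, test, "jaccard"),
      JMdice = jaccardMeasure(gt, test, "dice"),
      rfp = falsePositiveRatio(gt, test),
      rfn = falseNegativeRatio(gt, test),
      HD = hausdorffDistance(gt, test),
      MASD = meanSurfaceDistance(gt, test),
      V1 = voxelCount(gt), V2 = voxelCount(test))
}

setMethod("show", "MetricsReport", function(object) {
  cat(sprintf(
    paste0("MetricsReport: VD %.2f%% | JM %.2f%% (Dice %.2f%%) | ",
           "rfp %.2f%% | rfn %.2f%% | HD %.3f vx | MASD %.3f vx ",
           "| V1 %d V2 %d\n"),
    object@VD, object@JM, object@JMdice, object@rfp, object@rfn,
    object@HD, object@MASD, object@V1, object@V2))
})

#' @export
as.data.frame.MetricsReport <- function(x, row.names = NULL, optional = FALSE,
                                        ...) {
  data.frame(VD = x@VD, JM = x@JM, JMdice = x@JMdice, rfp = x@rfp,
             rfn = x@rfn, HD = x@HD, MASD = x@MASD, V1 = x@V1, V2 = x@V2,
             row.names = row.names)
}
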
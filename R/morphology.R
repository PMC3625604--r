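## Binary morphology with spherical structuring elements (via the exact
## Euclidean distance transform) and connected-component labelling; used for
## shape checks on segmentations (bleb protrusions, component structure).

#' Erode or dilate a mask with a spherical structuring element
#'
#' Erosion keeps foreground voxels farther than \code{radius} from the
#' background; dilation adds background voxels within \code{radius} of the
#' foreground. Distances are Euclidean between voxel centres.
#'
#' @param m a \linkS4class{VoxelMask}
#' @param radius sphere radius in voxels.
#' @return a \linkS4class{VoxelMask}
#' @export
morphErode <- function(m, radius) {
  stopifnot(is(m, "VoxelMask"), radius >= 0)
  if (radius == 0 || voxelCount(m) == 0L) return(m)
  if (all(m@data)) return(m)
  d <- array(cpp_edt(as.logical(!m@data), dim(m@data)), dim(m@data))
  VoxelMask(m@data & d > radius, m@spacing, m@origin)
}

#' @rdname morphErode
#' @export
morphDilate <- function(m, radius) {
  stopifnot(is(m, "VoxelMask"), radius >= 0)
  if (radius == 0 || voxelCount(m) == 0L) return(m)
  d <- array(cpp_edt(as.logical(m@data), dim(m@data)), dim(m@data))
  VoxelMask(m@data | d <= radius, m@spacing, m@origin)
}

#' Morphological opening with a spherical structuring element
#'
#' Erosion followed by dilation: removes protrusions thinner than the
#' structuring sphere. The set difference \code{mask minus opening} exposes
#' thin appendages such as aneurysm blebs.
#'
#' @inheritParams morphErode
#' @return a \linkS4class{VoxelMask}
#' @export
morphOpen <- function(m, radius) {
  morphDilate(morphErode(m, radius), radius)
}

#' Label the connected components of a mask
#'
#' @param m a \linkS4class{VoxelMask}
#' @param connectivity 6 or 26.
#' @return list with \code{labels} (integer array, 0 = background) and
#'   \code{sizes} (voxel count per component, decreasing)
#' @export
connectedComponents <- function(m, connectivity = 26L) {
  stopifnot(is(m, "VoxelMask"))
  remaining <- m@data
  labels <- array(0L, dim(remaining))
  sizes <- integer(0)
  lab <- 0L
  while (any(remaining)) {
    lab <- lab + 1L
    seed <- which(remaining, arr.ind = TRUE)[1, ] - 1L
    comp <- array(cpp_flood(as.logical(remaining), dim(remaining),
                            as.integer(seed), as.integer(connectivity)),
                  dim(remaining))
    labels[comp] <- lab
    sizes <- c(sizes, sum(comp))
    remaining <- remaining & !comp
  }
  ord <- order(sizes, decreasing = TRUE)
  relabel <- integer(length(sizes))
  relabel[ord] <- seq_along(sizes)
  out <- labels
  nz <- labels > 0L
  out[nz] <- relabel[labels[nz]]
  list(labels = out, sizes = sizes[ord])
}
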
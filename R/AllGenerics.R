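#' Voxel data accessor
#' @param x a ScanVolume, VoxelMask or LevelSetField
#' @return the underlying 3D array
#' @export
setGeneric("voxelData", function(x) standardGeneric("voxelData"))

#' Voxel spacing accessor
#' @param x an object with grid geometry
#' @return numeric(3) per-axis voxel size (mm)
#' @export
setGeneric("spacing", function(x) standardGeneric("spacing"))

#' Physical origin accessor
#' @param x an object with grid geometry
#' @return numeric(3) physical offset of voxel (0,0,0)
#' @export
setGeneric("origin", function(x) standardGeneric("origin"))

#' Number of foreground voxels in a mask
#' @param x a VoxelMask
#' @return integer count
#' @export
setGeneric("voxelCount", function(x) standardGeneric("voxelCount"))

#' Crop to a region of interest
#'
#' Extracts the half-open voxel box \code{[lower, upper)} of a volume or
#' mask; the origin is shifted by \code{lower * spacing} so physical
#' coordinates are preserved.
#'
#' @param x a ScanVolume or VoxelMask
#' @param roi a \linkS4class{VolumeROI}
#' @return an object of the same class as \code{x}
#' @export
setGeneric("crop", function(x, roi) standardGeneric("crop"))
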
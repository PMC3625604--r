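## Constructors, accessors and container I/O for volumes and masks.
## Supported on-disk formats: NIfTI (.nii/.nii.gz, via RNifti), NRRD (.nrrd)
## and MetaImage (.mha/.mhd), the latter two through a minimal raw-encoding
## reader/writer. The internal axis order is (x, y, z) with 0-based indices.

#' Construct a ScanVolume
#'
#' @param data 3D numeric array of intensities.
#' @param spacing numeric(3) voxel size in mm (default isotropic 1).
#' @param origin numeric(3) physical offset (default 0).
#' @return a \linkS4class{ScanVolume}
#' @examples
#' v <- ScanVolume(array(rnorm(64), c(4, 4, 4)))
#' dim(v)
#' @export
ScanVolume <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  storage.mode(data) <- "double"
  new("ScanVolume", data = data, spacing = as.numeric(spacing),
      origin = as.numeric(origin))
}

#' Construct a VoxelMask
#'
#' @param data 3D logical array, or numeric 0/1 array (coerced).
#' @param spacing,origin grid geometry of the source volume.
#' @return a \linkS4class{VoxelMask}
#' @export
VoxelMask <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (!is.logical(data)) {
    data <- array(data != 0, dim(data))
  }
  new("VoxelMask", data = data, spacing = as.numeric(spacing),
      origin = as.numeric(origin))
}

#' Construct a region of interest
#'
#' @param lower integer(3) inclusive start indices (0-based).
#' @param upper integer(3) exclusive end indices.
#' @return a \linkS4class{VolumeROI}
#' @examples
#' roi(c(2, 2, 2), c(5, 5, 5)) # the 3x3x3 block starting at voxel (2,2,2)
#' @export
roi <- function(lower, upper) {
  new("VolumeROI", lower = as.integer(lower), upper = as.integer(upper))
}

#' @describeIn voxelData volume intensities
setMethod("voxelData", "ScanVolume", function(x) x@data)
#' @describeIn voxelData mask foreground indicator
setMethod("voxelData", "VoxelMask", function(x) x@data)
#' @describeIn voxelData level-set values
setMethod("voxelData", "LevelSetField", function(x) x@phi)

#' @describeIn spacing volume spacing
setMethod("spacing", "ScanVolume", function(x) x@spacing)
#' @describeIn spacing mask spacing
setMethod("spacing", "VoxelMask", function(x) x@spacing)
#' @describeIn spacing level-set field spacing
setMethod("spacing", "LevelSetField", function(x) x@spacing)

#' @describeIn origin volume origin
setMethod("origin", "ScanVolume", function(x) x@origin)
#' @describeIn origin mask origin
setMethod("origin", "VoxelMask", function(x) x@origin)

#' @describeIn voxelCount foreground voxel count
setMethod("voxelCount", "VoxelMask", function(x) sum(x@data))

#' @export
setMethod("dim", "ScanVolume", function(x) dim(x@data))
#' @export
setMethod("dim", "VoxelMask", function(x) dim(x@data))
#' @export
setMethod("dim", "LevelSetField", function(x) dim(x@phi))

setMethod("show", "ScanVolume", function(object) {
  d <- dim(object@data)
  cat("ScanVolume", paste(d, collapse = " x "),
      sprintf("| spacing %s mm | range [%.6g, %.6g]\n",
              paste(signif(object@spacing, 4), collapse = ", "),
              min(object@data), max(object@data)))
})

setMethod("show", "VoxelMask", function(object) {
  d <- dim(object@data)
  cat("VoxelMask", paste(d, collapse = " x "),
      sprintf("| %d foreground voxels (%.2f%%)\n", sum(object@data),
              100 * mean(object@data)))
})

setMethod("show", "LevelSetField", function(object) {
  d <- dim(object@phi)
  cat("LevelSetField", paste(d, collapse = " x "),
      sprintf("| iteration %d | %d voxels inside (phi < 0)\n",
              object@iteration, sum(object@phi < 0)))
})

setMethod("show", "VolumeROI", function(object) {
  cat(sprintf("VolumeROI [%s) x [%s) x [%s)\n",
              paste(object@lower[1], object@upper[1], sep = ", "),
              paste(object@lower[2], object@upper[2], sep = ", "),
              paste(object@lower[3], object@upper[3], sep = ", ")))
})

.volFormat <- function(path) {
  low <- tolower(path)
  if (grepl("\\.nii(\\.gz)?$", low)) return("nifti")
  if (grepl("\\.nrrd$", low)) return("nrrd")
  if (grepl("\\.mh[ad]$", low)) return("metaimage")
  stop("unrecognized image container (expect .nii/.nii.gz, .nrrd, .mha/.mhd): ",
       path)
}

#' Read a 3D volume from a medical image container
#'
#' Reads NIfTI, NRRD or MetaImage files into a \linkS4class{ScanVolume}.
#' Integer intensities are preserved losslessly. If the container carries no
#' spacing, unit spacing is assumed with a warning.
#'
#' @param path file path; format chosen by extension.
#' @return a \linkS4class{ScanVolume}
#' @seealso \code{\link{writeVolume}}, \code{\link{readMask}}
#' @export
readVolume <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  fmt <- .volFormat(path)
  parsed <- switch(fmt,
    nifti = .readNifti(path),
    nrrd = .readNrrd(path),
    metaimage = .readMeta(path))
  if (length(dim(parsed$data)) != 3L)
    stop("expected 3D data, got ", length(dim(parsed$data)), "D: ", path)
  if (is.null(parsed$spacing)) {
    warning("container carries no spacing; assuming isotropic 1 mm")
    parsed$spacing <- c(1, 1, 1)
  }
  if (is.null(parsed$origin)) parsed$origin <- c(0, 0, 0)
  ScanVolume(parsed$data, parsed$spacing, parsed$origin)
}

#' Read a binary mask
#'
#' As \code{\link{readVolume}}, but any non-zero voxel becomes foreground.
#'
#' @param path file path.
#' @return a \linkS4class{VoxelMask}
#' @export
readMask <- function(path) {
  v <- readVolume(path)
  VoxelMask(v@data != 0, v@spacing, v@origin)
}

#' Write a volume or mask to a medical image container
#'
#' Volumes are stored as float64 (NIfTI) or double (NRRD/MetaImage), masks as
#' unsigned 8-bit 0/1 grids for interoperability with common viewers.
#'
#' @param v a \linkS4class{ScanVolume} or \linkS4class{VoxelMask}.
#' @param path output path; format chosen by extension.
#' @return invisibly, \code{path}
#' @export
writeVolume <- function(v, path) {
  mask <- is(v, "VoxelMask")
  dat <- if (mask) array(as.numeric(v@data), dim(v@data)) else v@data
  fmt <- .volFormat(path)
  if (!dir.exists(dirname(path)))
    stop("directory not writable: ", dirname(path))
  switch(fmt,
    nifti = .writeNifti(dat, v@spacing, v@origin, path,
                        datatype = if (mask) "uint8" else "double"),
    nrrd = .writeNrrd(dat, v@spacing, v@origin, path,
                      type = if (mask) "uint8" else "double"),
    metaimage = .writeMeta(dat, v@spacing, v@origin, path,
                           type = if (mask) "uint8" else "double"))
  invisible(path)
}

#' @rdname writeVolume
#' @param m a \linkS4class{VoxelMask}
#' @export
writeMask <- function(m, path) {
  stopifnot(is(m, "VoxelMask"))
  writeVolume(m, path)
}

## ---- NIfTI via RNifti ----

.readNifti <- function(path) {
  img <- RNifti::readNifti(path, internal = FALSE)
  d <- dim(img)
  pixdim <- RNifti::pixdim(img)
  sp <- if (length(pixdim) >= 3) abs(pixdim[1:3]) else NULL
  if (!is.null(sp) && any(sp == 0)) sp <- NULL
  orig <- tryCatch({
    xf <- RNifti::xform(img)
    as.numeric(xf[1:3, 4])
  }, error = function(e) NULL)
  list(data = array(as.numeric(img), d), spacing = sp, origin = orig)
}

.writeNifti <- function(data, spacing, origin, path, datatype = "double") {
  img <- RNifti::asNifti(data)
  xf <- diag(4)
  diag(xf)[1:3] <- spacing
  xf[1:3, 4] <- origin
  RNifti::sform(img) <- structure(xf, code = 2L)
  RNifti::qform(img) <- structure(xf, code = 2L)
  RNifti::pixdim(img) <- spacing   # the xform setters leave pixdim untouched
  RNifti::writeNifti(img, path, datatype = datatype)
}

## ---- NRRD (raw encoding) ----

.nrrdTypes <- c(uint8 = "uint8", uchar = "uint8", `unsigned char` = "uint8",
                short = "int16", int16 = "int16", `signed short` = "int16",
                ushort = "uint16", uint16 = "uint16",
                int = "int32", int32 = "int32",
                float = "float32", double = "float64", float64 = "float64")

.readBinArray <- function(con, type, n) {
  switch(type,
    uint8 = readBin(con, "integer", n = n, size = 1, signed = FALSE),
    int16 = readBin(con, "integer", n = n, size = 2, signed = TRUE,
                    endian = "little"),
    uint16 = readBin(con, "integer", n = n, size = 2, signed = FALSE,
                     endian = "little"),
    int32 = readBin(con, "integer", n = n, size = 4, endian = "little"),
    float32 = readBin(con, "numeric", n = n, size = 4, endian = "little"),
    float64 = readBin(con, "numeric", n = n, size = 8, endian = "little"),
    stop("unsupported element type: ", type))
}

.writeBinArray <- function(con, data, type) {
  switch(type,
    uint8 = writeBin(as.integer(data), con, size = 1),
    int16 = writeBin(as.integer(data), con, size = 2, endian = "little"),
    float64 = writeBin(as.numeric(data), con, size = 8, endian = "little"),
    stop("unsupported write type: ", type))
}

.readNrrd <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, n = 1)
  if (!grepl("^NRRD", magic)) stop("not an NRRD file: ", path)
  fields <- list()
  repeat {
    line <- readLines(con, n = 1)
    if (length(line) == 0) stop("truncated NRRD header: ", path)
    if (line == "") break
    if (grepl("^#", line)) next
    kv <- strsplit(line, ":\\s*", perl = TRUE)[[1]]
    if (length(kv) >= 2)
      fields[[tolower(kv[1])]] <- paste(kv[-1], collapse = ": ")
  }
  if (!is.null(fields$encoding) && tolower(fields$encoding) != "raw")
    stop("only raw NRRD encoding is supported, got: ", fields$encoding)
  sizes <- as.integer(strsplit(trimws(fields$sizes), "\\s+")[[1]])
  type <- .nrrdTypes[[tolower(trimws(fields$type))]]
  if (is.null(type)) stop("unsupported NRRD type: ", fields$type)
  sp <- NULL
  if (!is.null(fields$spacings)) {
    sp <- as.numeric(strsplit(trimws(fields$spacings), "\\s+")[[1]])
  } else if (!is.null(fields[["space directions"]])) {
    vecs <- regmatches(fields[["space directions"]],
                       gregexpr("\\(([^)]*)\\)", fields[["space directions"]]))[[1]]
    sp <- vapply(vecs, function(s) {
      v <- as.numeric(strsplit(gsub("[()]", "", s), ",")[[1]])
      sqrt(sum(v^2))
    }, numeric(1), USE.NAMES = FALSE)
  }
  orig <- NULL
  if (!is.null(fields[["space origin"]]))
    orig <- as.numeric(strsplit(gsub("[()]", "",
                                     fields[["space origin"]]), ",")[[1]])
  dat <- .readBinArray(con, type, prod(sizes))
  list(data = array(as.numeric(dat), sizes), spacing = sp, origin = orig)
}

.writeNrrd <- function(data, spacing, origin, path, type = "double") {
  nrrdType <- c(uint8 = "uint8", double = "double")[[type]]
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- c("NRRD0004",
           "# generated by aneuseg",
           paste0("type: ", nrrdType),
           "dimension: 3",
           paste0("sizes: ", paste(dim(data), collapse = " ")),
           paste0("spacings: ", paste(spacing, collapse = " ")),
           paste0("space origin: (", paste(origin, collapse = ","), ")"),
           "endian: little",
           "encoding: raw",
           "")
  writeLines(hdr, con, sep = "\n")
  .writeBinArray(con, data, if (type == "uint8") "uint8" else "float64")
}

## ---- MetaImage (.mha with LOCAL data, .mhd with external raw) ----

.metaTypes <- c(MET_UCHAR = "uint8", MET_SHORT = "int16", MET_USHORT = "uint16",
                MET_INT = "int32", MET_FLOAT = "float32", MET_DOUBLE = "float64")

.readMeta <- function(path) {
  con <- file(path, "rb")
  fields <- list()
  datafile <- NULL
  repeat {
    line <- readLines(con, n = 1)
    if (length(line) == 0) stop("truncated MetaImage header: ", path)
    kv <- strsplit(line, "\\s*=\\s*", perl = TRUE)[[1]]
    if (length(kv) >= 2) fields[[kv[1]]] <- paste(kv[-1], collapse = " = ")
    if (!is.null(fields$ElementDataFile)) {
      datafile <- fields$ElementDataFile
      break
    }
  }
  sizes <- as.integer(strsplit(trimws(fields$DimSize), "\\s+")[[1]])
  type <- .metaTypes[[trimws(fields$ElementType)]]
  if (is.null(type)) stop("unsupported ElementType: ", fields$ElementType)
  sp <- if (!is.null(fields$ElementSpacing))
    as.numeric(strsplit(trimws(fields$ElementSpacing), "\\s+")[[1]]) else NULL
  orig <- if (!is.null(fields$Offset))
    as.numeric(strsplit(trimws(fields$Offset), "\\s+")[[1]]) else NULL
  if (identical(datafile, "LOCAL")) {
    dat <- .readBinArray(con, type, prod(sizes))
    close(con)
  } else {
    close(con)
    rawPath <- file.path(dirname(path), datafile)
    rcon <- file(rawPath, "rb")
    dat <- .readBinArray(rcon, type, prod(sizes))
    close(rcon)
  }
  list(data = array(as.numeric(dat), sizes), spacing = sp, origin = orig)
}

.writeMeta <- function(data, spacing, origin, path, type = "double") {
  metaType <- c(uint8 = "MET_UCHAR", double = "MET_DOUBLE")[[type]]
  mhd <- grepl("\\.mhd$", tolower(path))
  datafile <- if (mhd) sub("\\.mhd$", ".raw", basename(path),
                           ignore.case = TRUE) else "LOCAL"
  hdr <- c("ObjectType = Image",
           "NDims = 3",
           "BinaryData = True",
           "BinaryDataByteOrderMSB = False",
           paste0("DimSize = ", paste(dim(data), collapse = " ")),
           paste0("ElementSpacing = ", paste(spacing, collapse = " ")),
           paste0("Offset = ", paste(origin, collapse = " ")),
           paste0("ElementType = ", metaType),
           paste0("ElementDataFile = ", datafile))
  con <- file(path, "wb")
  writeLines(hdr, con, sep = "\n")
  if (!mhd) .writeBinArray(con, data,
                           if (type == "uint8") "uint8" else "float64")
  close(con)
  if (mhd) {
    rcon <- file(file.path(dirname(path), datafile), "wb")
    .writeBinArray(rcon, data, if (type == "uint8") "uint8" else "float64")
    close(rcon)
  }
}

## ---- cropping ----

.cropArray <- function(a, r) {
  d <- dim(a)
  if (any(r@upper > d))
    stop("ROI exceeds volume bounds: upper = (",
         paste(r@upper, collapse = ","), "), dim = (",
         paste(d, collapse = ","), ")")
  a[(r@lower[1] + 1):r@upper[1],
    (r@lower[2] + 1):r@upper[2],
    (r@lower[3] + 1):r@upper[3], drop = FALSE]
}

#' @describeIn crop crop a volume
setMethod("crop", signature("ScanVolume", "VolumeROI"), function(x, roi) {
  ScanVolume(.cropArray(x@data, roi), x@spacing,
             x@origin + roi@lower * x@spacing)
})

#' @describeIn crop crop a mask
setMethod("crop", signature("VoxelMask", "VolumeROI"), function(x, roi) {
  VoxelMask(.cropArray(x@data, roi), x@spacing,
            x@origin + roi@lower * x@spacing)
})
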
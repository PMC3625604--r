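## Numerical machinery shared by the Chan-Vese and TLS evolutions:
## signed-distance initialization, curvature, Godunov upwind time stepping,
## subcell-preserving reinitialization, and mask <-> field conversion.
## Unit voxel spacing is assumed in all finite differences.

.dims <- function(x) as.integer(dim(x))

#' Initialize a level-set field as a signed distance to an inset box
#'
#' The zero level set is the axis-aligned rectangular box obtained by
#' retracting \code{inset} voxels from each face of the grid; \eqn{\phi < 0}
#' inside. This is the standard initial surface for segmenting a cropped ROI:
#' the box encloses nearly the whole ROI and shrinks onto the target.
#'
#' @param shape integer(3) grid dimensions.
#' @param inset integer box inset in voxels (>= 1, and 2*inset must be
#'   smaller than every dimension).
#' @param spacing,origin grid geometry to attach to the field.
#' @return a \linkS4class{LevelSetField}
#' @examples
#' ls <- initBoxLevelSet(c(16, 16, 16), inset = 2)
#' sum(voxelData(ls) < 0) # interior voxel count: 12^3
#' @export
initBoxLevelSet <- function(shape, inset = 2L, spacing = c(1, 1, 1),
                            origin = c(0, 0, 0)) {
  shape <- as.integer(shape)
  inset <- as.integer(inset)
  if (inset < 1L || any(2L * inset >= shape))
    stop("degenerate box: need inset >= 1 and 2*inset < every dimension")
  # box faces half a voxel outside the retained voxel layers, so exactly
  # (n - 2*inset) voxel centres per axis fall inside
  lo <- inset - 0.5
  hi <- shape - inset - 0.5
  ctr <- (lo + hi) / 2
  half <- (hi - lo) / 2
  ax <- lapply(1:3, function(a) abs((seq_len(shape[a]) - 1) - ctr[a]) - half[a])
  qx <- array(rep(ax[[1]], times = shape[2] * shape[3]), shape)
  qy <- aperm(array(rep(ax[[2]], times = shape[1] * shape[3]),
                    shape[c(2, 1, 3)]), c(2, 1, 3))
  qz <- aperm(array(rep(ax[[3]], times = shape[1] * shape[2]),
                    shape[c(3, 1, 2)]), c(2, 3, 1))
  outside <- sqrt(pmax(qx, 0)^2 + pmax(qy, 0)^2 + pmax(qz, 0)^2)
  inside <- pmin(pmax(qx, pmax(qy, qz)), 0)
  new("LevelSetField", phi = outside + inside, iteration = 0L,
      spacing = as.numeric(spacing), origin = as.numeric(origin))
}

#' Mean curvature of the level-set interface
#'
#' Computes \eqn{\kappa = \mathrm{div}(\nabla\phi / |\nabla\phi|)} by central
#' differences (the sum of the two principal curvatures; \eqn{2/R} on a sphere
#' of radius R with the negative-inside convention). Values are clamped to
#' \code{[-clamp, clamp]} — curvature beyond the 1/voxel resolution bound is
#' not meaningful on the grid — and regularized where \eqn{|\nabla\phi|} is
#' below \code{eps}.
#'
#' @param ls a \linkS4class{LevelSetField}
#' @param clamp curvature magnitude bound (1/voxels).
#' @param eps gradient regularization.
#' @return 3D numeric array of curvatures
#' @export
levelSetCurvature <- function(ls, clamp = 1, eps = 1e-8) {
  array(cpp_div_g_norm_grad(as.numeric(ls@phi), NULL, .dims(ls@phi), eps,
                            clamp), dim(ls@phi))
}

#' Geodesic divergence term
#'
#' Computes \eqn{\mathrm{div}(g \nabla\phi/|\nabla\phi|) = g\kappa + \nabla g
#' \cdot \nabla\phi/|\nabla\phi|}, the boundary term of geodesic active
#' contours, with the curvature clamped as in
#' \code{\link{levelSetCurvature}}.
#'
#' @param ls a \linkS4class{LevelSetField}
#' @param g 3D array, edge-stopping map in (0, 1].
#' @param clamp,eps as in \code{\link{levelSetCurvature}}.
#' @return 3D numeric array
#' @export
geodesicDivergence <- function(ls, g, clamp = 1, eps = 1e-8) {
  stopifnot(identical(dim(g), dim(ls@phi)))
  array(cpp_div_g_norm_grad(as.numeric(ls@phi), as.numeric(g), .dims(ls@phi),
                            eps, clamp), dim(ls@phi))
}

#' Stable explicit time step for a speed field
#'
#' Combines the hyperbolic bound (no more than ~0.45 voxel of interface
#' displacement per step) with a parabolic bound for the explicitly
#' discretized curvature term.
#'
#' @param speed 3D array of normal speeds.
#' @param betaEff effective curvature weight entering the speed (0 when the
#'   speed has no curvature contribution).
#' @return a positive time step
#' @export
stableTimeStep <- function(speed, betaEff = 0) {
  m <- max(abs(speed))
  dt <- if (m > 0) 0.45 / m else 1
  if (betaEff > 0) dt <- min(dt, 0.12 / betaEff)
  dt
}

#' Advance a level-set field by one explicit Euler step
#'
#' Updates \eqn{\phi \leftarrow \phi - \Delta t\, F\, |\nabla\phi|}. The
#' advective part of the speed uses the Godunov upwind gradient norm chosen
#' by the sign of F at each voxel; a curvature-derived part, when supplied
#' separately, uses the central-difference norm (the standard discretization
#' for parabolic terms, which avoids the upwind scheme's dissipative shrink
#' bias). Positive speed expands the region \eqn{\{\phi<0\}} in the normal
#' direction.
#'
#' @param ls a \linkS4class{LevelSetField}
#' @param speed 3D array of advective normal speeds (finite), or NULL.
#' @param dt time step; default \code{stableTimeStep} of the combined speed.
#' @param curvatureSpeed optional 3D array with the curvature-derived speed
#'   contribution, differenced centrally.
#' @return the advanced \linkS4class{LevelSetField} (iteration incremented)
#' @export
levelSetStep <- function(ls, speed = NULL, dt = NULL, curvatureSpeed = NULL) {
  if (is.null(speed) && is.null(curvatureSpeed))
    stop("need a speed field")
  upd <- 0
  maxF <- 0
  if (!is.null(speed)) {
    stopifnot(identical(dim(speed), dim(ls@phi)))
    if (any(!is.finite(speed))) stop("non-finite speed field")
    gmag <- cpp_godunov_norm(as.numeric(ls@phi), as.numeric(speed),
                             .dims(ls@phi))
    upd <- speed * array(gmag, dim(ls@phi))
    maxF <- max(abs(speed))
  }
  if (!is.null(curvatureSpeed)) {
    stopifnot(identical(dim(curvatureSpeed), dim(ls@phi)))
    if (any(!is.finite(curvatureSpeed))) stop("non-finite speed field")
    cmag <- cpp_gradmag(as.numeric(ls@phi), .dims(ls@phi))
    upd <- upd + curvatureSpeed * array(cmag, dim(ls@phi))
    maxF <- maxF + max(abs(curvatureSpeed))
  }
  if (is.null(dt)) dt <- if (maxF > 0) 0.45 / maxF else 1
  if (dt <= 0) stop("dt must be > 0")
  new("LevelSetField",
      phi = ls@phi - dt * upd,
      iteration = ls@iteration + 1L,
      spacing = ls@spacing, origin = ls@origin)
}

#' Reinitialize a level-set field toward a signed distance function
#'
#' Runs the Sussman reinitialization PDE \eqn{\phi_t = \mathrm{sign}(\phi_0)
#' (1 - |\nabla\phi|)} with a subcell fix that pins the zero level set to its
#' interpolated position in the input field, so the interface moves by less
#' than half a voxel and no voxel changes sign. Restores
#' \eqn{|\nabla\phi| \approx 1} in a band around the interface.
#'
#' @param ls a \linkS4class{LevelSetField} with both signs present.
#' @param iterations relaxation sweeps (each extends the valid band by about
#'   one voxel on each side).
#' @return the reinitialized \linkS4class{LevelSetField}
#' @export
reinitializeLevelSet <- function(ls, iterations = 10L) {
  phi <- ls@phi
  if (all(phi >= 0) || all(phi <= 0))
    stop("degenerate interface: phi must take both signs")
  out <- cpp_reinit(as.numeric(phi), .dims(phi), as.integer(iterations), 0.3)
  new("LevelSetField", phi = array(out, dim(phi)),
      iteration = ls@iteration, spacing = ls@spacing, origin = ls@origin)
}

#' Extract the segmented mask from a level-set field
#'
#' Foreground is the interior \eqn{\{\phi < 0\}}.
#'
#' @param ls a \linkS4class{LevelSetField}
#' @return a \linkS4class{VoxelMask}
#' @export
maskFromLevelSet <- function(ls) {
  VoxelMask(ls@phi < 0, ls@spacing, ls@origin)
}

#' Exact signed Euclidean distance field of a mask
#'
#' Negative inside, positive outside, with the zero crossing placed on the
#' voxel-boundary surface between foreground and background voxel centres
#' (so \code{maskFromLevelSet(sdfFromMask(m))} reproduces \code{m} exactly).
#'
#' @param m a \linkS4class{VoxelMask} with at least one foreground and one
#'   background voxel.
#' @return a \linkS4class{LevelSetField}
#' @export
sdfFromMask <- function(m) {
  fg <- m@data
  nfg <- sum(fg)
  if (nfg == 0L || nfg == length(fg))
    stop("degenerate interface: mask must contain both phases")
  dOut <- array(cpp_edt(as.logical(fg), .dims(fg)), dim(fg))
  dIn <- array(cpp_edt(as.logical(!fg), .dims(fg)), dim(fg))
  phi <- ifelse(fg, -(dIn - 0.5), dOut - 0.5)
  new("LevelSetField", phi = phi, iteration = 0L,
      spacing = m@spacing, origin = m@origin)
}

# fraction of voxels whose inside/outside state differs between two fields
.interfaceChange <- function(a, b) mean((a@phi < 0) != (b@phi < 0))
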
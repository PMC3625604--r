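#' Separable Gaussian smoothing of a 3D array
#'
#' Discrete Gaussian convolution applied axis by axis with replicated
#' (clamped) boundaries; kernel truncated at 3 sigma. \code{sigma = 0} returns
#' the input unchanged.
#'
#' @param a 3D numeric array (or a \linkS4class{ScanVolume}, smoothed in
#'   place).
#' @param sigma kernel SD in voxels.
#' @return same type as the input
#' @export
gaussianSmooth <- function(a, sigma) {
  if (is(a, "ScanVolume"))
    return(ScanVolume(gaussianSmooth(a@data, sigma), a@spacing, a@origin))
  if (sigma <= 0) return(a)
  r <- max(1L, ceiling(3 * sigma))
  x <- (-r):r
  kern <- exp(-x^2 / (2 * sigma^2))
  kern <- kern / sum(kern)
  convAxis <- function(m, n1) {
    # banded convolution as a matrix product along the first dimension
    K <- matrix(0, n1, n1)
    for (d in seq_along(x)) {
      idx <- pmin(pmax(seq_len(n1) + x[d], 1L), n1)
      K[cbind(seq_len(n1), idx)] <- K[cbind(seq_len(n1), idx)] + kern[d]
    }
    K %*% m
  }
  d <- dim(a)
  a <- array(convAxis(matrix(a, d[1]), d[1]), d)
  a <- aperm(a, c(2, 3, 1))
  a <- array(convAxis(matrix(a, d[2]), d[2]), dim(a))
  a <- aperm(a, c(2, 3, 1))
  a <- array(convAxis(matrix(a, d[3]), d[3]), dim(a))
  aperm(a, c(2, 3, 1))
}
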
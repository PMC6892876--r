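## Low-level array operations shared by the generators and the
## quantification modules.

# 1-D Gaussian kernel, sigma in voxels, truncated at 3 sigma, unit sum.
.gaussKernel <- function(sigma) {
  if (sigma <= 0) return(1)
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  k / sum(k)
}

# Convolve a 3-D array along one dimension with kernel k, replicating
# edges. Uses stats::filter column-wise after permuting the target
# dimension to the front.
.convolveAlong <- function(arr, k, dimIdx) {
  if (length(k) == 1) return(arr * k)
  d <- dim(arr)
  perm <- c(dimIdx, setdiff(1:3, dimIdx))
  a <- aperm(arr, perm)
  dp <- dim(a)
  m <- matrix(a, nrow = dp[1])
  r <- (length(k) - 1) / 2
  pad <- rbind(m[rep(1, r), , drop = FALSE], m,
               m[rep(nrow(m), r), , drop = FALSE])
  f <- stats::filter(pad, k, sides = 2)
  f <- f[(r + 1):(r + dp[1]), , drop = FALSE]
  out <- array(as.numeric(f), dp)
  aperm(out, order(perm))
}

#' Separable 3-D Gaussian smoothing
#'
#' Smooths a voxel array with an axis-separable Gaussian. Sigmas are
#' given per axis in voxels (use `sigmaNm / voxel size` to smooth at a
#' fixed physical scale on anisotropic stacks). Kernels are truncated at
#' 3 sigma, normalized to unit sum (DC gain 1), and edges are replicated.
#'
#' @param arr 3-D numeric array
#' @param sigmaVox sigma per axis in voxels, length 1 (isotropic) or 3
#' @return smoothed array of the same dimensions
#' @export
gaussianSmooth3D <- function(arr, sigmaVox) {
  if (length(dim(arr)) != 3) stop("'arr' must be a 3-D array")
  if (length(sigmaVox) == 1) sigmaVox <- rep(sigmaVox, 3)
  if (any(sigmaVox < 0)) stop("sigmas must be >= 0")
  for (i in 1:3)
    if (sigmaVox[i] > 0)
      arr <- .convolveAlong(arr, .gaussKernel(sigmaVox[i]), i)
  arr
}

# Distance of every voxel centre from a point (nm); returns a 3-D array.
.radiusField <- function(geom, dims, centerNm) {
  x2 <- (voxelCenters(geom, dims[1], "x") - centerNm[1])^2
  y2 <- (voxelCenters(geom, dims[2], "y") - centerNm[2])^2
  z2 <- (voxelCenters(geom, dims[3], "z") - centerNm[3])^2
  sqrt(outer(outer(x2, y2, "+"), z2, "+"))
}
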
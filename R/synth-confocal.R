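#' Simulate a confocal stack of spherical HA brushes
#'
#' Renders one or more microspheres (default radius 4 um, emulating 8 um
#' glass beads) carrying an exponentially decaying brush: the brush-label
#' channel follows \eqn{I_0 e^{-r/\lambda}} for distances
#' \eqn{0 \le r \le h} from the sphere surface and is truncated beyond
#' the brush height `h`. A surface-marker channel (GFPn-like) peaks at
#' the sphere surface. An optional nanoparticle channel is excluded
#' within the brush, rising to its bulk plateau through a logistic
#' transition centred at the brush edge. Gaussian background noise of
#' standard deviation `noiseSd` is added to every channel, so the
#' per-voxel signal-to-noise ratio at the sphere surface is
#' `I0 / noiseSd`.
#'
#' The default stack is sized so that the analyzed cone axes (along
#' +/-x) traverse the full brush plus at least `h + 3 lambda` of
#' clearance before the stack edge, leaving ample pure-background bins
#' for tail statistics, while the transverse extents only need to contain
#' the sphere.
#'
#' @param heightNm true brush height h (nm)
#' @param lambdaNm profile decay length lambda (nm); `Inf` gives a flat
#'   (uniform shell) profile
#' @param I0 brush intensity at the sphere surface (arbitrary units)
#' @param noiseSd Gaussian background noise sd (same units as `I0`)
#' @param sphereRadiusNm microsphere radius (nm); default 4000 (8 um bead)
#' @param centersNm matrix of sphere centres (nm), one row per sphere;
#'   `NULL` places a single sphere at the stack centre
#' @param geometry a [VoxelGeometry-class]; default 50 nm lateral /
#'   470 nm axial
#' @param dims stack dimensions `c(nx, ny, nz)`; `NULL` sizes the stack
#'   automatically for single-sphere +/-x cone analysis
#' @param particleChannel add an excluded-nanoparticle channel
#' @param particleBulk bulk plateau intensity of the particle channel
#' @param exclusionWidthNm logistic transition width of the particle
#'   exclusion edge (nm); default 2 lateral voxels
#' @param surfacePeakWidthNm Gaussian width of the surface-marker shell
#' @param seed RNG seed recorded in the truth metadata
#' @return an [ImageStack-class] with channels `brush`, `surface` (and
#'   optionally `particle`); `stackMetadata()` carries the ground truth,
#'   including an `overlap` flag set when any two spheres sit closer than
#'   `2 * (R + h)`
#' @export
simulateSphericalBrushStack <- function(heightNm = 3750, lambdaNm = 1500,
    I0 = 100, noiseSd = 5, sphereRadiusNm = 4000, centersNm = NULL,
    geometry = VoxelGeometry(50, 50, 470), dims = NULL,
    particleChannel = FALSE, particleBulk = 100,
    exclusionWidthNm = 2 * geometry@dx, surfacePeakWidthNm = 100,
    seed = NULL) {
  if (heightNm < 0) stop("'heightNm' must be >= 0")
  if (lambdaNm <= 0) stop("'lambdaNm' must be > 0")
  R <- sphereRadiusNm
  clearance <- heightNm + if (is.finite(lambdaNm)) 3 * lambdaNm else 0
  if (is.null(dims)) {
    halfX <- R + clearance + 50 * geometry@dx  # room for 50 tail bins
    halfT <- R + 500
    dims <- c(2 * ceiling(halfX / geometry@dx),
              2 * ceiling(halfT / geometry@dy),
              2 * ceiling(halfT / geometry@dz) + 1)
  }
  extent <- dims * c(geometry@dx, geometry@dy, geometry@dz)
  if (is.null(centersNm)) centersNm <- matrix(extent / 2, nrow = 1)
  centersNm <- rbind(centersNm)
  for (i in seq_len(nrow(centersNm)))
    if (any(centersNm[i, ] - R < 0) || any(centersNm[i, ] + R > extent))
      stop(sprintf("sphere %d (radius %g nm) is clipped by the stack bounds",
                   i, R))
  overlap <- FALSE
  if (nrow(centersNm) > 1) {
    dmat <- as.matrix(stats::dist(centersNm))
    overlap <- any(dmat[upper.tri(dmat)] < 2 * (R + heightNm))
  }
  nch <- if (particleChannel) 3L else 2L
  arr <- array(0, c(dims, nch))
  for (i in seq_len(nrow(centersNm))) {
    r <- .radiusField(geometry, dims, centersNm[i, ])
    s <- r - R  # distance from the sphere surface
    brush <- ifelse(s >= 0 & s <= heightNm,
                    if (is.finite(lambdaNm)) I0 * exp(-pmax(s, 0) / lambdaNm)
                    else I0, 0)
    arr[, , , 1] <- arr[, , , 1] + brush
    arr[, , , 2] <- arr[, , , 2] +
      2 * I0 * exp(-s^2 / (2 * surfacePeakWidthNm^2))
    if (particleChannel) {
      pen <- 1 / (1 + exp(-(s - heightNm) / exclusionWidthNm))
      pen[r < R] <- 0
      # multiplicative exclusion so overlapping spheres stay bounded
      arr[, , , 3] <- if (i == 1) particleBulk * pen
                      else pmin(arr[, , , 3], particleBulk * pen)
    }
  }
  withSeed(seed, {
    if (noiseSd > 0)
      arr <- arr + stats::rnorm(length(arr), 0, noiseSd)
  })
  channels <- c("brush", "surface", if (particleChannel) "particle")
  ImageStack(arr, geometry, channels, metadata = list(truth = list(
    kind = "spherical", centersNm = centersNm, sphereRadiusNm = R,
    heightNm = heightNm, lambdaNm = lambdaNm, I0 = I0, noiseSd = noiseSd,
    overlap = overlap, seed = seed)))
}

#' Simulate a confocal stack of a planar HA brush
#'
#' Renders a planar brush grown from a substrate plane at `substrateZNm`:
#' the brush-label channel decays exponentially in z above the substrate
#' (truncated at the brush height `h`); the nanoparticle channel is ~0
#' below `substrate + h` and rises to its bulk plateau through a logistic
#' transition of configurable width (the particle-exclusion readout); the
#' dextran channel penetrates the brush with a linear gradient, depleted
#' by `dextranDepletion` at the substrate and reaching bulk at the brush
#' edge; a thin surface-marker channel peaks at the substrate plane. All
#' channels are zero below the substrate (glass) and carry Gaussian
#' noise.
#'
#' @param heightNm true brush height h (nm); 0 renders no brush, with
#'   the particle plateau reaching down to the substrate
#' @param lambdaNm brush profile decay length (nm)
#' @param I0 brush intensity at the substrate
#' @param noiseSd Gaussian noise sd
#' @param substrateZNm z position of the substrate plane (nm)
#' @param geometry a [VoxelGeometry-class]; default 100 nm axial step
#' @param nx,ny lateral stack size (voxels)
#' @param nz axial size; `NULL` sizes to `substrate + h + 3 lambda` plus
#'   tail room
#' @param particleBulk bulk plateau of the nanoparticle channel
#' @param exclusionWidthNm logistic transition width (nm); default 2
#'   axial voxels
#' @param dextranBulk,dextranDepletion dextran bulk level and fractional
#'   depletion at the substrate (0.5 = drops by 50 percent)
#' @param seed RNG seed
#' @return an [ImageStack-class] with channels `brush`, `particle`,
#'   `dextran`, `surface` and truth metadata
#' @export
simulatePlanarBrushStack <- function(heightNm = 2620, lambdaNm = 1000,
    I0 = 100, noiseSd = 5, substrateZNm = 500,
    geometry = VoxelGeometry(100, 100, 100), nx = 48, ny = 48, nz = NULL,
    particleBulk = 100, exclusionWidthNm = 2 * geometry@dz,
    dextranBulk = 100, dextranDepletion = 0.5, seed = NULL) {
  if (heightNm < 0) stop("'heightNm' must be >= 0")
  if (dextranDepletion < 0 || dextranDepletion > 1)
    stop("'dextranDepletion' must lie in [0, 1]")
  if (is.null(nz))
    nz <- ceiling((substrateZNm + heightNm + 3 * lambdaNm +
                   55 * geometry@dz) / geometry@dz)
  zExtent <- nz * geometry@dz
  if (zExtent < substrateZNm + heightNm + 3 * lambdaNm)
    stop("stack z-extent must be >= substrate + h + 3*lambda")
  z <- voxelCenters(geometry, nz, "z")
  s <- z - substrateZNm  # height above the substrate
  above <- s >= 0
  brushZ <- ifelse(above & s <= heightNm, I0 * exp(-pmax(s, 0) / lambdaNm), 0)
  partZ <- particleBulk / (1 + exp(-(s - heightNm) / exclusionWidthNm))
  partZ[!above] <- 0
  dexZ <- ifelse(s >= heightNm, dextranBulk,
                 dextranBulk * (1 - dextranDepletion *
                                  (1 - s / max(heightNm, geometry@dz))))
  dexZ[!above] <- 0
  surfZ <- 2 * I0 * exp(-s^2 / (2 * (geometry@dz / 2)^2))
  arr <- array(0, c(nx, ny, nz, 4))
  for (k in seq_len(nz)) {
    arr[, , k, 1] <- brushZ[k]
    arr[, , k, 2] <- partZ[k]
    arr[, , k, 3] <- dexZ[k]
    arr[, , k, 4] <- surfZ[k]
  }
  withSeed(seed, {
    if (noiseSd > 0) arr <- arr + stats::rnorm(length(arr), 0, noiseSd)
  })
  ImageStack(arr, geometry, c("brush", "particle", "dextran", "surface"),
    metadata = list(truth = list(
      kind = "planar", substrateZNm = substrateZNm, heightNm = heightNm,
      lambdaNm = lambdaNm, I0 = I0, noiseSd = noiseSd,
      dextranDepletion = dextranDepletion, particleBulk = particleBulk,
      exclusionWidthNm = exclusionWidthNm, seed = seed)))
}

#' Simulate a confocal stack of surface-attached bacteria
#'
#' Places ellipsoidal bright bodies (rod-bacterium scale, default
#' 1 x 1 x 2 um full axes) near the substrate plane, at a given surface
#' density, with random in-plane orientation. The rendered binary body
#' mask is blurred with a Gaussian and Gaussian noise is added. The
#' *exact voxelized biovolume* (union of the body masks, in um^3) is
#' returned as ground truth along with the mask itself.
#'
#' @param densityPerUm2 bacteria per um^2 of substrate (>= 0); the count
#'   is Poisson-distributed unless `centersNm` is given
#' @param geometry a [VoxelGeometry-class]; default 100 x 100 x 200 nm
#'   (axial sampling fine enough to resolve ~1 um bodies)
#' @param nx,ny,nz stack dimensions (voxels)
#' @param semiAxesNm body semi-axes (nm): in-plane long, in-plane short,
#'   axial
#' @param amplitude body intensity above background
#' @param noiseSd Gaussian noise sd
#' @param blurSigmaVox Gaussian blur sigma (voxels)
#' @param centersNm optional matrix of body centres (nm), one row each,
#'   overriding random placement (density is then ignored)
#' @param thetaRad optional in-plane orientations (radians), one per body
#' @param seed RNG seed
#' @return list with `stack` (an [ImageStack-class], channel
#'   `bacteria`), `mask` (logical truth array), `biovolumeUm3` (exact
#'   voxelized truth), and `nCells`
#' @export
simulateBiofilmStack <- function(densityPerUm2,
    geometry = VoxelGeometry(100, 100, 200), nx = 128, ny = 128, nz = 30,
    semiAxesNm = c(1000, 500, 500), amplitude = 100, noiseSd = 5,
    blurSigmaVox = 1, centersNm = NULL, thetaRad = NULL, seed = NULL) {
  if (is.null(centersNm) && densityPerUm2 < 0)
    stop("'densityPerUm2' must be >= 0")
  dims <- c(nx, ny, nz)
  extent <- dims * c(geometry@dx, geometry@dy, geometry@dz)
  withSeed(seed, {
    if (is.null(centersNm)) {
      areaUm2 <- extent[1] * extent[2] / 1e6
      n <- stats::rpois(1, densityPerUm2 * areaUm2)
      if (n > 0) {
        marg <- max(semiAxesNm)
        centersNm <- cbind(stats::runif(n, marg, extent[1] - marg),
                           stats::runif(n, marg, extent[2] - marg),
                           semiAxesNm[3] + stats::runif(n, 0, geometry@dz))
      } else centersNm <- matrix(numeric(0), ncol = 3)
    } else centersNm <- rbind(centersNm)
    n <- nrow(centersNm)
    if (is.null(thetaRad)) thetaRad <- stats::runif(n, 0, pi)
    mask <- array(FALSE, dims)
    xc <- voxelCenters(geometry, nx, "x")
    yc <- voxelCenters(geometry, ny, "y")
    zc <- voxelCenters(geometry, nz, "z")
    for (i in seq_len(n)) {
      c3 <- centersNm[i, ]
      rmax <- max(semiAxesNm)
      ix <- which(abs(xc - c3[1]) <= rmax)
      iy <- which(abs(yc - c3[2]) <= rmax)
      iz <- which(abs(zc - c3[3]) <= rmax)
      if (!length(ix) || !length(iy) || !length(iz)) next
      dx <- xc[ix] - c3[1]; dy <- yc[iy] - c3[2]; dz <- zc[iz] - c3[3]
      ct <- cos(thetaRad[i]); st <- sin(thetaRad[i])
      # body-frame coordinates: rotate in-plane by theta
      u <- outer(dx * ct, dy * st, "+")           # [ix, iy]
      v <- outer(-dx * st, dy * ct, "+")
      q2 <- (u / semiAxesNm[1])^2 + (v / semiAxesNm[2])^2
      for (k in seq_along(iz)) {
        inside <- q2 + (dz[k] / semiAxesNm[3])^2 <= 1
        mask[ix, iy, iz[k]] <- mask[ix, iy, iz[k]] | inside
      }
    }
    img <- amplitude * mask
    if (blurSigmaVox > 0) img <- gaussianSmooth3D(img, blurSigmaVox)
    if (noiseSd > 0) img <- img + stats::rnorm(length(img), 0, noiseSd)
    stack <- ImageStack(array(img, c(dims, 1)), geometry, "bacteria",
      metadata = list(truth = list(
        kind = "biofilm", nCells = n, centersNm = centersNm,
        thetaRad = thetaRad, semiAxesNm = semiAxesNm,
        biovolumeUm3 = sum(mask) * voxelVolumeUm3(geometry),
        noiseSd = noiseSd, seed = seed)))
    list(stack = stack, mask = mask,
         biovolumeUm3 = sum(mask) * voxelVolumeUm3(geometry), nCells = n)
  })
}
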
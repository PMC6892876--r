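#' Brush heights of spherical brushes in a confocal stack
#'
#' The full spherical-brush measurement pipeline: microspheres are
#' located by Otsu segmentation of the brush-label channel; for each
#' sphere, azimuthally averaged profiles are extracted along a set of
#' cone axes; cones aimed at a neighbouring sphere's brush, or leaving
#' the stack before reaching the background regime, are dropped; per
#' cone, background statistics come from the outermost `nTail` bins, the
#' brush edge from the background + 2 sigma rule, and the surface from
#' the surface-marker peak (falling back to the nominal sphere radius).
#' The brush height of a cone is edge minus surface; a sphere's height
#' is the mean over its clear cones, and the population mean and sd over
#' spheres are reported.
#'
#' @param stack an [ImageStack-class]
#' @param channel brush-label channel role
#' @param surfaceChannel surface-marker channel role; if absent the
#'   brush channel itself is used (its maximum also sits at the surface)
#' @param segmentChannel channel used to locate the spheres (defaults
#'   to the brush channel; use the surface or dextran channel when the
#'   brush is too faint to segment)
#' @param axes matrix of candidate cone axes (one row each); default the
#'   four lateral directions +/-x, +/-y
#' @param apertureDeg full cone aperture (degrees)
#' @param nTail background tail bins
#' @param kSigma,kSustain edge-rule parameters, see [detectBrushEdge()]
#' @param binWidthNm radial bin width; default lateral voxel size
#' @param hMaxNm maximum plausible brush height (nm), used for the
#'   clear-cone test and the required radial reach
#' @param sphereRadiusNm nominal sphere radius (nm) for the surface
#'   fallback and reach; `NULL` uses each component's equivalent radius
#' @param minVoxels minimum segmented component size
#' @return list with `perCone` (data.frame: sphere, axis, surface, edge,
#'   height, flags), `perSphere` (data.frame: centre, height mean/sd,
#'   cones used) and `summary` (list: `meanNm`, `sdNm`, `nSpheres`)
#' @export
sphericalBrushHeights <- function(stack, channel = "brush",
    surfaceChannel = "surface", segmentChannel = channel, axes = NULL,
    apertureDeg = 30, nTail = 50, kSigma = 2, kSustain = 3,
    binWidthNm = NULL, hMaxNm = 6000, sphereRadiusNm = NULL,
    minVoxels = 50) {
  geom <- voxelGeometry(stack)
  if (is.null(binWidthNm)) binWidthNm <- geom@dx
  if (is.null(axes))
    axes <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0))
  if (!surfaceChannel %in% channelNames(stack)) surfaceChannel <- channel
  spheres <- segmentSphereCenters(stack, segmentChannel,
                                  minVoxels = minVoxels)
  if (nrow(spheres) == 0)
    stop("no segmentable sphere in the stack")
  perCone <- list()
  perSphere <- list()
  for (i in seq_len(nrow(spheres))) {
    ctr <- as.numeric(spheres[i, c("x_nm", "y_nm", "z_nm")])
    Rnom <- if (is.null(sphereRadiusNm)) spheres$equivRadiusNm[i]
            else sphereRadiusNm
    required <- Rnom + hMaxNm + nTail * binWidthNm
    heights <- c()
    for (a in seq_len(nrow(axes))) {
      axis <- axes[a, ] / sqrt(sum(axes[a, ]^2))
      clear <- TRUE
      if (nrow(spheres) > 1) {
        for (j in seq_len(nrow(spheres))[-i]) {
          dvec <- as.numeric(spheres[j, c("x_nm", "y_nm", "z_nm")]) - ctr
          dist <- sqrt(sum(dvec^2))
          proj <- sum(dvec * axis)
          if (proj <= 0) next
          perp <- sqrt(max(dist^2 - proj^2, 0))
          spread <- proj * tan(apertureDeg / 2 * pi / 180)
          if (perp < Rnom + hMaxNm + spread &&
              proj < required + Rnom + hMaxNm) clear <- FALSE
        }
      }
      flag <- if (!clear) "overlap" else "ok"
      surfaceNm <- edgeNm <- heightNm <- NA_real_
      if (clear) {
        prof <- coneProfile(stack, ctr, axis, apertureDeg, channel,
                            binWidthNm, requiredRNm = required)
        if (prof@truncated) {
          flag <- "truncated"
        } else {
          bg <- backgroundStats(prof, nTail)
          edge <- detectBrushEdge(prof, bg, kSigma, kSustain)
          sprof <- coneProfile(stack, ctr, axis, apertureDeg,
                               surfaceChannel, binWidthNm)
          surf <- detectSurface(sprof, nominalRadiusNm = Rnom)
          surfaceNm <- surf$surfaceNm
          if (edge$flag != "ok") {
            flag <- edge$flag
          } else {
            edgeNm <- edge$edgeNm
            heightNm <- edgeNm - surfaceNm
            if (heightNm < 0) flag <- "negative-height"
          }
        }
      }
      perCone[[length(perCone) + 1]] <- data.frame(
        sphere = i, ax = axis[1], ay = axis[2], az = axis[3],
        surfaceNm = surfaceNm, edgeNm = edgeNm, heightNm = heightNm,
        flag = flag)
      if (flag == "ok") heights <- c(heights, heightNm)
    }
    perSphere[[i]] <- data.frame(
      sphere = i, x_nm = ctr[1], y_nm = ctr[2], z_nm = ctr[3],
      heightNm = if (length(heights)) mean(heights) else NA_real_,
      heightSdNm = if (length(heights) > 1) stats::sd(heights) else NA_real_,
      nCones = length(heights),
      flag = if (length(heights)) "ok" else "all-cones-invalid")
  }
  perCone <- do.call(rbind, perCone)
  perSphere <- do.call(rbind, perSphere)
  ok <- !is.na(perSphere$heightNm)
  list(perCone = perCone, perSphere = perSphere,
       summary = list(
         meanNm = if (any(ok)) mean(perSphere$heightNm[ok]) else NA_real_,
         sdNm = if (sum(ok) > 1) stats::sd(perSphere$heightNm[ok]) else NA_real_,
         nSpheres = sum(ok)))
}

#' Planar brush height from a particle-exclusion stack
#'
#' The nanoparticle channel of a planar brush stack is ~0 inside the
#' brush and rises to its bulk plateau above it. After lateral averaging
#' over the ROI, the plateau is estimated from the topmost fraction of
#' slices and the floor from the bottommost slices; the brush edge is
#' the z position where the particle intensity crosses half way between
#' floor and plateau (linear sub-slice interpolation). The height is
#' that edge minus the surface z, located from the surface-marker peak
#' (fallbacks: `surfaceZNm`, else the first slice).
#'
#' @param stack an [ImageStack-class]
#' @param particleChannel nanoparticle channel role
#' @param surfaceChannel surface-marker channel role (optional)
#' @param roi optional lateral ROI `c(x0, x1, y0, y1)` (voxel indices)
#' @param topFrac fraction of topmost slices defining the plateau
#' @param bottomSlices number of bottommost slices defining the floor
#' @param minContrast minimum plateau-floor contrast, in floor-region
#'   sds, below which the result is flagged invalid
#' @param surfaceZNm fallback surface position (nm)
#' @return list with `heightNm`, `surfaceNm`, `edgeNm` (half-maximum z),
#'   `plateau`, `floor`, `method = "particle_exclusion"` and `flag`
#' @export
planarExclusionHeight <- function(stack, particleChannel = "particle",
    surfaceChannel = "surface", roi = NULL, topFrac = 0.2,
    bottomSlices = 3, minContrast = 5, surfaceZNm = NULL) {
  prof <- axialProfile(stack, particleChannel, roi)
  z <- prof@r
  p <- prof@intensity
  nz <- length(z)
  nTop <- max(1L, floor(topFrac * nz))
  plateau <- mean(p[(nz - nTop + 1):nz])
  floorIdx <- seq_len(min(bottomSlices, nz))
  floorLevel <- mean(p[floorIdx])
  floorSd <- stats::sd(p[floorIdx])
  if (!is.finite(floorSd) || floorSd == 0) floorSd <- .Machine$double.eps
  surf <- list(surfaceNm = NA_real_, flag = "none")
  if (surfaceChannel %in% channelNames(stack)) {
    sprof <- axialProfile(stack, surfaceChannel, roi)
    surf <- tryCatch(detectSurface(sprof, nominalRadiusNm = surfaceZNm),
                     error = function(e) list(surfaceNm = NA_real_,
                                              flag = "none"))
  }
  surfaceNm <- if (!is.na(surf$surfaceNm)) surf$surfaceNm
               else if (!is.null(surfaceZNm)) surfaceZNm else z[1]
  if (plateau - floorLevel < minContrast * floorSd)
    return(list(heightNm = NA_real_, surfaceNm = surfaceNm,
                edgeNm = NA_real_, plateau = plateau, floor = floorLevel,
                method = "particle_exclusion", flag = "no-plateau"))
  half <- (plateau + floorLevel) / 2
  aboveIdx <- which(p >= half)
  i1 <- min(aboveIdx)
  edgeNm <- if (i1 == 1) z[1]
            else .crossingX(z[i1 - 1], p[i1 - 1], z[i1], p[i1], half)
  list(heightNm = edgeNm - surfaceNm, surfaceNm = surfaceNm,
       edgeNm = edgeNm, plateau = plateau, floor = floorLevel,
       method = "particle_exclusion", flag = "ok")
}

#' Planar brush height from the brush-label channel
#'
#' The surface-marker analogue of [planarExclusionHeight()]: the axial
#' brush-label profile is thresholded with the background + 2 sigma edge
#' rule (background from the topmost `nTail` slices, which lie above the
#' brush) and the height is the edge minus the surface-marker peak z.
#'
#' @inheritParams planarExclusionHeight
#' @param channel brush-label channel role
#' @param nTail background tail slices (topmost)
#' @param kSigma,kSustain see [detectBrushEdge()]
#' @return list with `heightNm`, `surfaceNm`, `edgeNm`,
#'   `method = "edge_2sigma"` and `flag`
#' @export
planarEdgeHeight <- function(stack, channel = "brush",
    surfaceChannel = "surface", roi = NULL, nTail = 50, kSigma = 2,
    kSustain = 3, surfaceZNm = NULL) {
  prof <- axialProfile(stack, channel, roi)
  bg <- backgroundStats(prof, nTail)
  edge <- detectBrushEdge(prof, bg, kSigma, kSustain)
  surf <- list(surfaceNm = NA_real_)
  if (surfaceChannel %in% channelNames(stack)) {
    sprof <- axialProfile(stack, surfaceChannel, roi)
    surf <- tryCatch(detectSurface(sprof, nominalRadiusNm = surfaceZNm),
                     error = function(e) list(surfaceNm = NA_real_))
  }
  surfaceNm <- if (!is.na(surf$surfaceNm)) surf$surfaceNm
               else if (!is.null(surfaceZNm)) surfaceZNm else prof@r[1]
  if (edge$flag == "no-crossing")
    return(list(heightNm = NA_real_, surfaceNm = surfaceNm,
                edgeNm = NA_real_, method = "edge_2sigma",
                flag = "no-crossing"))
  list(heightNm = edge$edgeNm - surfaceNm, surfaceNm = surfaceNm,
       edgeNm = edge$edgeNm, method = "edge_2sigma", flag = edge$flag)
}
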
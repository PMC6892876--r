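#' Azimuthally averaged cone profile from a sphere centre
#'
#' Averages intensity over all voxels whose direction from `centerNm`
#' lies within half the (full) aperture of the cone axis, binned by
#' physical radial distance. Voxel indices are converted to nm before
#' binning, so anisotropic voxel geometry is honoured without resampling
#' the stack. The profile is cut where the axis ray leaves the stack; if
#' that happens before `requiredRNm` the profile is flagged truncated.
#'
#' @param stack an [ImageStack-class]
#' @param centerNm cone apex (sphere centre), length-3 nm coordinates
#' @param axis cone axis direction (length 3; normalized internally)
#' @param apertureDeg full cone aperture in degrees, default 30 (i.e.
#'   15 degree half-angle)
#' @param channel source channel role or index
#' @param binWidthNm radial bin width; default the lateral voxel size
#' @param requiredRNm radial reach the caller needs (e.g. sphere radius +
#'   maximum expected brush height + background span); the `truncated`
#'   flag is set when the stack ends earlier. `NULL` skips the check.
#' @return a [RadialProfile-class]
#' @export
coneProfile <- function(stack, centerNm, axis = c(1, 0, 0),
                        apertureDeg = 30, channel = "brush",
                        binWidthNm = NULL, requiredRNm = NULL) {
  geom <- voxelGeometry(stack)
  if (is.null(binWidthNm)) binWidthNm <- geom@dx
  if (apertureDeg <= 0 || apertureDeg > 180)
    stop("aperture must be in (0, 180] degrees")
  axis <- axis / sqrt(sum(axis^2))
  arr <- stackData(stack, channel)
  d <- dim(arr)
  ux <- voxelCenters(geom, d[1], "x") - centerNm[1]
  uy <- voxelCenters(geom, d[2], "y") - centerNm[2]
  uz <- voxelCenters(geom, d[3], "z") - centerNm[3]
  # distance along the axis and squared distance, by separability
  proj <- outer(outer(ux * axis[1], uy * axis[2], "+"), uz * axis[3], "+")
  r2 <- outer(outer(ux^2, uy^2, "+"), uz^2, "+")
  r <- sqrt(r2)
  cosHalf <- cos(apertureDeg / 2 * pi / 180)
  member <- r > 0 & proj >= r * cosHalf
  # where the axis ray exits the stack (distance from the apex, nm)
  extent <- d * c(geom@dx, geom@dy, geom@dz)
  tExit <- Inf
  for (i in 1:3) {
    if (axis[i] > 0) tExit <- min(tExit, (extent[i] - centerNm[i]) / axis[i])
    if (axis[i] < 0) tExit <- min(tExit, -centerNm[i] / axis[i])
  }
  member <- member & r <= tExit
  rm <- r[member]
  vm <- arr[member]
  if (!length(rm)) stop("cone contains no voxels")
  bin <- floor(rm / binWidthNm) + 1L
  nb <- max(bin)
  cnt <- tabulate(bin, nb)
  sums <- numeric(nb)
  agg <- rowsum(vm, bin)
  sums[as.integer(rownames(agg))] <- agg
  keep <- cnt > 0
  truncated <- !is.null(requiredRNm) && tExit < requiredRNm
  new("RadialProfile",
      r = ((seq_len(nb) - 0.5) * binWidthNm)[keep],
      intensity = (sums / pmax(cnt, 1))[keep],
      count = as.numeric(cnt[keep]),
      axis = axis, apertureDeg = apertureDeg,
      channel = if (is.character(channel)) channel else
        channelNames(stack)[channel],
      binWidth = binWidthNm, truncated = truncated)
}

#' Laterally averaged axial (z) profile of a planar stack
#'
#' Mean intensity per z-slice over a rectangular lateral ROI, as a
#' [RadialProfile-class] with distance measured from the bottom of the
#' stack (z = 0 convention).
#'
#' @param stack an [ImageStack-class]
#' @param channel channel role or index
#' @param roi optional `c(x0, x1, y0, y1)` voxel index range (1-based,
#'   inclusive); `NULL` averages the full field
#' @return a [RadialProfile-class] with axis `(0, 0, 1)`
#' @export
axialProfile <- function(stack, channel = "brush", roi = NULL) {
  arr <- stackData(stack, channel)
  geom <- voxelGeometry(stack)
  if (!is.null(roi))
    arr <- arr[roi[1]:roi[2], roi[3]:roi[4], , drop = FALSE]
  prof <- apply(arr, 3, mean)
  nPerSlice <- prod(dim(arr)[1:2])
  new("RadialProfile", r = voxelCenters(geom, dim(arr)[3], "z"),
      intensity = as.numeric(prof), count = rep(nPerSlice, length(prof)),
      axis = c(0, 0, 1), apertureDeg = 180, channel = as.character(channel),
      binWidth = geom@dz, truncated = FALSE)
}

#' Background statistics from the profile tail
#'
#' Mean and standard deviation of the outermost `nTail` profile bins
#' (the bins at the edge of the image, away from the brush). Errors if
#' the profile is shorter than `nTail` rather than silently shrinking
#' the tail.
#'
#' @param profile a [RadialProfile-class]
#' @param nTail number of tail bins to use (default 50)
#' @return list with `mean`, `sd` and `nTail`
#' @export
backgroundStats <- function(profile, nTail = 50) {
  n <- length(profile@r)
  if (n < nTail)
    stop(sprintf("profile has %d bins but %d tail bins were requested",
                 n, nTail))
  tail <- profile@intensity[(n - nTail + 1):n]
  list(mean = mean(tail), sd = stats::sd(tail), nTail = nTail)
}

#' Detect the brush edge by the background + 2 sigma rule
#'
#' Scanning from the outermost bin inward, the edge is the outermost bin
#' whose intensity is >= `bg$mean + kSigma * bg$sd`, sustained for
#' `kSustain` consecutive bins (continuing inward), which suppresses
#' isolated noise spikes. The edge position is refined to sub-bin
#' precision by linear interpolation of the threshold crossing between
#' the edge bin and its outer neighbour.
#'
#' Azimuthally averaged bins do not all carry the same number of
#' voxels: bins near the cone apex may average tens of voxels where the
#' tail bins average thousands, so a sd estimated from the tail
#' understates the noise of the inner bins by the square root of the
#' count ratio. With `countAware = TRUE` (the default) the threshold for
#' each bin scales the background sd by `sqrt(tailCount / binCount)`,
#' which reduces to the plain rule whenever bins have equal support —
#' in particular for laterally averaged axial profiles.
#'
#' @param profile a [RadialProfile-class]
#' @param bg background statistics from [backgroundStats()]
#' @param kSigma threshold in background sds above the mean (default 2)
#' @param kSustain consecutive bins required above threshold (default 3)
#' @param countAware scale the per-bin sd by the bin's voxel support
#' @return list with `edgeNm` (NA if no crossing), `binIndex`,
#'   `threshold` (at the edge bin) and `flag` (`"ok"`, `"no-crossing"`
#'   or `"edge-at-boundary"`)
#' @export
detectBrushEdge <- function(profile, bg, kSigma = 2, kSustain = 3,
                            countAware = TRUE) {
  if (bg$sd < 0) stop("background sd must be >= 0")
  y <- profile@intensity
  r <- profile@r
  n <- length(y)
  scale <- 1
  if (countAware && length(profile@count) == n && any(profile@count > 0)) {
    nTail <- if (!is.null(bg$nTail)) bg$nTail else min(50, n)
    tailCnt <- mean(profile@count[max(1, n - nTail + 1):n])
    scale <- sqrt(tailCnt / pmax(profile@count, 1))
  }
  thr <- bg$mean + kSigma * bg$sd * scale
  # with a degenerate (sd = 0) background the threshold equals the
  # background mean; bins exactly at background must not count as brush
  above <- if (bg$sd > 0) y >= thr else y > thr
  # sustained[i]: bins i, i-1, ..., i-kSustain+1 (continuing inward)
  # all above threshold
  runIn <- stats::filter(as.numeric(above), rep(1, kSustain), sides = 1)
  sustained <- as.numeric(runIn) == kSustain
  sustained[is.na(sustained)] <- FALSE
  thrAt <- function(i) if (length(thr) > 1) thr[i] else thr
  cand <- which(sustained)
  if (!length(cand))
    return(list(edgeNm = NA_real_, binIndex = NA_integer_,
                threshold = thrAt(n), flag = "no-crossing"))
  i <- max(cand)
  if (i == n)
    return(list(edgeNm = r[n], binIndex = n, threshold = thrAt(n),
                flag = "edge-at-boundary"))
  edge <- .crossingX(r[i], y[i], r[i + 1], y[i + 1], thrAt(i))
  list(edgeNm = edge, binIndex = i, threshold = thrAt(i), flag = "ok")
}

#' Locate the surface from a surface-marker profile
#'
#' The surface is the interior peak of the surface-marker (GFPn-like)
#' profile, refined to sub-bin precision by parabolic interpolation. If
#' the profile has no interior peak (monotone, or maximum on the first
#' or last bin) the nominal sphere radius is used as fallback and the
#' result is flagged.
#'
#' @param profile a [RadialProfile-class] of the surface-marker channel
#' @param nominalRadiusNm fallback surface position (distance from the
#'   profile origin, nm); required when no interior peak exists
#' @return list with `surfaceNm`, `flag` (`"peak"` or
#'   `"fallback-radius"`)
#' @export
detectSurface <- function(profile, nominalRadiusNm = NULL) {
  y <- profile@intensity
  n <- length(y)
  i <- which.max(y)
  if (n >= 3 && i > 1 && i < n)
    return(list(surfaceNm = .parabolicPeak(profile@r, y, i), flag = "peak"))
  if (is.null(nominalRadiusNm))
    stop("no interior peak in the surface-marker profile and no nominal radius given")
  list(surfaceNm = nominalRadiusNm, flag = "fallback-radius")
}

#' Fit an exponential concentration profile
#'
#' Least-squares fit of \eqn{I(r) = I_0 e^{-(r - r_s)/\lambda} + bg}
#' between the surface and the brush edge, the functional form that
#' describes polydisperse HA brush concentration profiles. Starting
#' values come from a log-linear regression of the background-subtracted
#' intensities; the nonlinear refinement uses Levenberg-Marquardt.
#'
#' @param profile a [RadialProfile-class]
#' @param surfaceNm surface position (nm, same origin as the profile)
#' @param edgeNm outer fit limit; `NULL` uses the whole profile
#' @param bg optional [backgroundStats()] result; background level is
#'   then held fixed at `bg$mean` and bins below `bg$mean + 2 bg$sd` are
#'   not counted as signal
#' @param minBins minimum number of signal bins required (default 5)
#' @return list with `I0`, `lambdaNm`, `background`, `converged`,
#'   `nBins`, `rmse` and `flag`
#' @export
fitExponentialProfile <- function(profile, surfaceNm, edgeNm = NULL,
                                  bg = NULL, minBins = 5) {
  r <- profile@r
  y <- profile@intensity
  sel <- r >= surfaceNm & (if (is.null(edgeNm)) TRUE else r <= edgeNm)
  bgMean <- if (is.null(bg)) 0 else bg$mean
  if (!is.null(bg))
    sel <- sel & y > bg$mean + 2 * bg$sd
  if (sum(sel) < minBins)
    return(list(I0 = NA_real_, lambdaNm = NA_real_, background = bgMean,
                converged = FALSE, nBins = sum(sel), rmse = NA_real_,
                flag = "insufficient-signal"))
  rs <- r[sel] - surfaceNm
  ys <- y[sel]
  pos <- ys - bgMean > 0
  if (sum(pos) < minBins)
    return(list(I0 = NA_real_, lambdaNm = NA_real_, background = bgMean,
                converged = FALSE, nBins = sum(pos), rmse = NA_real_,
                flag = "insufficient-signal"))
  start <- stats::lm(log(ys[pos] - bgMean) ~ rs[pos])$coefficients
  lam0 <- if (start[2] < 0) -1 / start[2] else max(rs)
  fit <- tryCatch(
    minpack.lm::nlsLM(ys ~ I0 * exp(-rs / lambda) + bgMean,
                      start = list(I0 = unname(exp(start[1])),
                                   lambda = unname(lam0)),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit))
    return(list(I0 = NA_real_, lambdaNm = NA_real_, background = bgMean,
                converged = FALSE, nBins = sum(sel), rmse = NA_real_,
                flag = "no-convergence"))
  cf <- stats::coef(fit)
  list(I0 = unname(cf["I0"]), lambdaNm = unname(cf["lambda"]),
       background = bgMean, converged = TRUE, nBins = sum(sel),
       rmse = sqrt(mean(stats::residuals(fit)^2)), flag = "ok")
}
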
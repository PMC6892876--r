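#' High-pass filter a stack for bacteria segmentation
#'
#' Subtracts a Gaussian-blurred copy of the stack from itself (unsharp
#' high-pass), removing smooth background so that cell-sized bright
#' bodies stand out. The smoothing scale should be much larger than a
#' cell and much smaller than the field; the default is 2 um. Output is
#' ~0 on smooth backgrounds (DC is removed).
#'
#' @param stack an [ImageStack-class]
#' @param sigmaNm Gaussian scale (nm) of the removed background
#' @param channel channel to filter; `NULL` filters all channels
#' @return an [ImageStack-class] with the filtered channel(s)
#' @export
highpassStack <- function(stack, sigmaNm = 2000, channel = NULL) {
  if (sigmaNm <= 0) stop("'sigmaNm' must be > 0")
  geom <- voxelGeometry(stack)
  sig <- sigmaNm / c(geom@dx, geom@dy, geom@dz)
  chs <- if (is.null(channel)) seq_along(channelNames(stack))
         else channelIndex(stack, channel)
  arr <- stack@data
  for (ci in chs) {
    a <- arr[, , , ci, drop = TRUE]
    arr[, , , ci] <- a - gaussianSmooth3D(a, sig)
  }
  ImageStack(arr, geom, channelNames(stack), stackMetadata(stack))
}

#' Binarize a stack with Otsu's method and a noise-floor guard
#'
#' Thresholds a channel with Otsu's method, with two safeguards for
#' sparse fluorescent stacks. First, the threshold is by default
#' computed from the voxels above a preliminary noise level (median +
#' 2 robust sds): with a tiny foreground against an overwhelming
#' background peak, plain Otsu is biased toward the background and
#' systematically dilates the mask. Second, the threshold is never taken
#' below a noise floor of `noiseFloorK` robust sds (MAD x 1.4826) above
#' the median: on a signal-free stack Otsu would split the noise
#' distribution in half, and the guard is what keeps empty fields
#' empty. A fixed `threshold` overrides both. Set `polarity = "dark"`
#' to segment dark objects on a bright background (the stack is negated
#' first, so an inverted-contrast stack yields the same mask).
#'
#' @param stack an [ImageStack-class] or 3-D array
#' @param channel channel role or index (ignored for arrays)
#' @param threshold optional fixed threshold
#' @param noiseFloorK noise-floor multiplier (robust sds)
#' @param restrictToSignal compute Otsu from above-noise voxels only
#'   (default TRUE); FALSE pools the full histogram
#' @param polarity `"bright"` (default) or `"dark"`
#' @return list with `mask` (logical array), `threshold`, and
#'   `usedFloor` (TRUE when the noise floor overrode Otsu)
#' @export
binarizeStack <- function(stack, channel = 1, threshold = NULL,
                          noiseFloorK = 4, restrictToSignal = TRUE,
                          polarity = c("bright", "dark")) {
  polarity <- match.arg(polarity)
  arr <- if (is(stack, "ImageStack")) stackData(stack, channel) else stack
  if (polarity == "dark") arr <- -arr
  if (!is.null(threshold))
    return(list(mask = arr > threshold, threshold = threshold,
                usedFloor = FALSE))
  if (min(arr) == max(arr))
    stop("degenerate histogram: constant stack cannot be binarized")
  med <- stats::median(arr)
  s <- stats::mad(arr)
  floorTh <- med + noiseFloorK * s
  cand <- if (restrictToSignal) arr[arr > med + 2 * s] else arr
  th <- tryCatch(otsuThreshold(cand), error = function(e) NA_real_)
  if (is.na(th))
    th <- tryCatch(otsuThreshold(arr), error = function(e) NA_real_)
  if (is.na(th))
    return(list(mask = array(FALSE, dim(arr)), threshold = floorTh,
                usedFloor = TRUE))
  usedFloor <- th < floorTh
  th <- max(th, floorTh)
  list(mask = arr > th, threshold = th, usedFloor = usedFloor)
}

#' Biovolume by voxel counting
#'
#' Total volume of the segmented bacteria: the number of nonzero mask
#' voxels times the voxel volume, plus the volume restricted to a
#' near-surface z band (default the 5 um above the surface, where
#' surface retention is assessed).
#'
#' @param mask logical 3-D array (from [binarizeStack()])
#' @param geom a [VoxelGeometry-class]
#' @param bandNm near-surface band `c(lo, hi)` in nm above the surface,
#'   default `c(0, 5000)`
#' @param surfaceZNm z of the substrate/brush-top surface (nm); default
#'   0 (the bottom of the stack)
#' @return list with `totalUm3`, `bandUm3`, `bandNm`, `surfaceZNm`,
#'   `nVoxels`; the band is clipped to the stack with a warning if it
#'   extends outside
#' @export
biovolume <- function(mask, geom, bandNm = c(0, 5000), surfaceZNm = 0) {
  if (length(dim(mask)) != 3) stop("'mask' must be a 3-D array")
  vox <- voxelVolumeUm3(geom)
  nz <- dim(mask)[3]
  z <- voxelCenters(geom, nz, "z")
  lo <- surfaceZNm + bandNm[1]
  hi <- surfaceZNm + bandNm[2]
  if (hi > nz * geom@dz || lo < 0)
    warning("near-surface band extends outside the stack; clipping")
  sel <- z >= lo & z <= hi
  total <- sum(mask) * vox
  band <- if (any(sel)) sum(mask[, , sel, drop = FALSE]) * vox else 0
  list(totalUm3 = total, bandUm3 = band, bandNm = bandNm,
       surfaceZNm = surfaceZNm, nVoxels = sum(mask))
}

#' Surface-retention comparison against a reference surface
#'
#' Percent reduction `(reference - sample)/reference * 100` and fold
#' ratio `reference/sample` of retained biovolume, with the sample mean
#' and SEM over imaged regions. A zero sample volume gives an infinite
#' fold ratio, flagged rather than dropped.
#'
#' @param sampleVolumesUm3 biovolumes of the test surface, one per
#'   region (um^3)
#' @param referenceVolumesUm3 biovolume(s) of the reference surface
#' @return list with `percentReduction`, `foldRatio`, `sampleMeanUm3`,
#'   `sampleSEMUm3`, `referenceMeanUm3`, `infiniteFold`
#' @export
retentionComparison <- function(sampleVolumesUm3, referenceVolumesUm3) {
  if (any(sampleVolumesUm3 < 0) || any(referenceVolumesUm3 < 0))
    stop("volumes must be >= 0")
  refMean <- mean(referenceVolumesUm3)
  if (refMean <= 0) stop("reference volume must be > 0")
  sMean <- mean(sampleVolumesUm3)
  nReg <- length(sampleVolumesUm3)
  sem <- if (nReg > 1) stats::sd(sampleVolumesUm3) / sqrt(nReg) else NA_real_
  list(percentReduction = (refMean - sMean) / refMean * 100,
       foldRatio = if (sMean > 0) refMean / sMean else Inf,
       sampleMeanUm3 = sMean, sampleSEMUm3 = sem,
       referenceMeanUm3 = refMean, infiniteFold = sMean == 0)
}

#' Estimate a bacterial cell count from biovolume
#'
#' Divides the biovolume by an assumed per-cell volume (default 1 um^3,
#' a typical rod bacterium). The conversion factor is reported alongside
#' the count since it is an assumption, not a measurement.
#'
#' @param biovolumeUm3 biovolume (um^3)
#' @param perCellVolumeUm3 assumed volume per cell (um^3), > 0
#' @return list with `count` and `perCellVolumeUm3`
#' @export
estimateCellCount <- function(biovolumeUm3, perCellVolumeUm3 = 1.0) {
  if (perCellVolumeUm3 <= 0) stop("'perCellVolumeUm3' must be > 0")
  if (any(biovolumeUm3 < 0)) stop("biovolume must be >= 0")
  list(count = biovolumeUm3 / perCellVolumeUm3,
       perCellVolumeUm3 = perCellVolumeUm3)
}

#' Biofilm biovolume pipeline
#'
#' High-pass filtering, binarization with the noise-floor guard, and
#' voxel-count biovolume with the near-surface band, composed as in the
#' standard bacteria-quantification procedure.
#'
#' @param stack an [ImageStack-class]
#' @param channel bacteria channel role or index
#' @param sigmaNm high-pass scale (nm)
#' @param bandNm near-surface band (nm above the surface)
#' @param surfaceZNm surface z (nm)
#' @param perCellVolumeUm3 assumed per-cell volume for the count
#' @param noiseFloorK see [binarizeStack()]
#' @return list combining [biovolume()] output with `estimatedCells`,
#'   `threshold` and `usedFloor`
#' @export
biofilmBiovolume <- function(stack, channel = 1, sigmaNm = 2000,
                             bandNm = c(0, 5000), surfaceZNm = 0,
                             perCellVolumeUm3 = 1.0, noiseFloorK = 4) {
  hp <- highpassStack(stack, sigmaNm, channel)
  bin <- binarizeStack(hp, channel, noiseFloorK = noiseFloorK)
  bv <- biovolume(bin$mask, voxelGeometry(stack), bandNm, surfaceZNm)
  bv$estimatedCells <- estimateCellCount(bv$totalUm3, perCellVolumeUm3)$count
  bv$threshold <- bin$threshold
  bv$usedFloor <- bin$usedFloor
  bv
}
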
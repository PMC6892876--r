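#' Construct a VoxelGeometry
#'
#' @param dx,dy lateral voxel size (nm). `dy` defaults to `dx`.
#' @param dz axial voxel size (nm). Confocal spherical-brush stacks are
#'   typically acquired with 30-60 nm lateral pixels and a 470 nm axial
#'   step; planar brush stacks with a 100 nm axial step.
#' @return a [VoxelGeometry-class]
#' @examples
#' g <- VoxelGeometry(dx = 50, dz = 470)
#' anisotropy(g)
#' @export
VoxelGeometry <- function(dx = 50, dy = dx, dz = 470) {
  new("VoxelGeometry", dx = as.numeric(dx), dy = as.numeric(dy),
      dz = as.numeric(dz), origin = "corner0")
}

#' @describeIn VoxelGeometry axial-to-lateral anisotropy ratio `dz/dx`
#' @param geom a [VoxelGeometry-class]
#' @export
anisotropy <- function(geom) geom@dz / geom@dx

#' @describeIn VoxelGeometry voxel volume in cubic micrometres
#' @export
voxelVolumeUm3 <- function(geom) geom@dx * geom@dy * geom@dz / 1e9

#' Physical voxel-centre coordinates along one axis
#'
#' @param geom a [VoxelGeometry-class]
#' @param n number of voxels along the axis
#' @param axis `"x"`, `"y"` or `"z"`
#' @return numeric vector of `n` centre coordinates (nm), 0-based voxels
#' @export
voxelCenters <- function(geom, n, axis = c("x", "y", "z")) {
  axis <- match.arg(axis)
  step <- switch(axis, x = geom@dx, y = geom@dy, z = geom@dz)
  (seq_len(n) - 0.5) * step
}

setMethod("show", "VoxelGeometry", function(object) {
  cat(sprintf("VoxelGeometry: %g x %g x %g nm (dz/dx = %.2f)\n",
              object@dx, object@dy, object@dz, anisotropy(object)))
})

#' Construct an ImageStack
#'
#' @param data a 3-D array `[x, y, z]` (single channel) or 4-D array
#'   `[x, y, z, channel]`
#' @param geometry a [VoxelGeometry-class]
#' @param channels channel role names, one per channel plane
#' @param metadata free-form list
#' @return an [ImageStack-class]
#' @export
ImageStack <- function(data, geometry = VoxelGeometry(),
                       channels = NULL, metadata = list()) {
  if (length(dim(data)) == 3) dim(data) <- c(dim(data), 1L)
  if (is.null(channels))
    channels <- if (!is.null(dimnames(data)[[4]])) dimnames(data)[[4]]
                else paste0("ch", seq_len(dim(data)[4]))
  new("ImageStack", data = data, geometry = geometry,
      channels = as.character(channels), metadata = metadata)
}

#' @describeIn ImageStack the voxel array of one channel (3-D) or all
#'   channels (4-D when `channel` is `NULL`)
#' @param x,stack an [ImageStack-class]
#' @param channel channel role name or index; `NULL` for all
#' @export
stackData <- function(stack, channel = NULL) {
  if (is.null(channel)) return(stack@data)
  i <- channelIndex(stack, channel)
  stack@data[, , , i, drop = TRUE]
}

#' @describeIn ImageStack channel role names
#' @export
channelNames <- function(stack) stack@channels

#' @describeIn ImageStack the stack's [VoxelGeometry-class]
#' @export
voxelGeometry <- function(stack) stack@geometry

#' @describeIn ImageStack generator truth / provenance metadata list
#' @export
stackMetadata <- function(stack) stack@metadata

channelIndex <- function(stack, channel) {
  if (is.numeric(channel)) {
    i <- as.integer(channel)
    if (i < 1 || i > length(stack@channels))
      stop("channel index out of range")
    return(i)
  }
  i <- match(channel, stack@channels)
  if (is.na(i))
    stop(sprintf("no channel with role '%s' (available: %s)", channel,
                 paste(stack@channels, collapse = ", ")))
  i
}

setMethod("dim", "ImageStack", function(x) dim(x@data))

setMethod("show", "ImageStack", function(object) {
  d <- dim(object@data)
  g <- object@geometry
  cat(sprintf("ImageStack: %d x %d x %d voxels, %d channel(s) [%s]\n",
              d[1], d[2], d[3], d[4],
              paste(object@channels, collapse = ", ")))
  cat(sprintf("  field of view: %.1f x %.1f x %.1f um (voxel %g x %g x %g nm)\n",
              d[1] * g@dx / 1e3, d[2] * g@dy / 1e3, d[3] * g@dz / 1e3,
              g@dx, g@dy, g@dz))
  if (length(object@metadata))
    cat("  metadata:", paste(names(object@metadata), collapse = ", "), "\n")
})

setMethod("show", "RadialProfile", function(object) {
  cat(sprintf(
    "RadialProfile (%s): %d bins, r in [%.0f, %.0f] nm, aperture %g deg%s\n",
    object@channel, length(object@r),
    if (length(object@r)) min(object@r) else NA,
    if (length(object@r)) max(object@r) else NA,
    object@apertureDeg, if (object@truncated) " [truncated]" else ""))
})

#' @export
#' @describeIn RadialProfile-class profile as a data.frame with columns
#'   `r_nm`, `intensity`, `count`
#' @param x a [RadialProfile-class]
#' @param ... ignored
as.data.frame.RadialProfile <- function(x, ...) {
  data.frame(r_nm = x@r, intensity = x@intensity, count = x@count)
}
setMethod("as.data.frame", "RadialProfile", as.data.frame.RadialProfile)

#' Construct a NanoporeTrace
#'
#' @param current current samples (pA)
#' @param samplingRate sampling rate (Hz); acquisition default 200 kHz
#' @param voltage applied voltage (mV)
#' @param filterInfo list describing filters already applied
#' @return a [NanoporeTrace-class]
#' @export
NanoporeTrace <- function(current, samplingRate = 2e5, voltage = 200,
                          filterInfo = list()) {
  new("NanoporeTrace", current = as.numeric(current),
      samplingRate = samplingRate, voltage = voltage,
      filterInfo = filterInfo)
}

#' @describeIn NanoporeTrace current samples (pA)
#' @param trace a [NanoporeTrace-class]
#' @export
traceCurrent <- function(trace) trace@current

#' @describeIn NanoporeTrace sampling rate (Hz)
#' @export
samplingRate <- function(trace) trace@samplingRate

setMethod("length", "NanoporeTrace", function(x) length(x@current))

setMethod("show", "NanoporeTrace", function(object) {
  cat(sprintf(
    "NanoporeTrace: %d samples at %g kHz (%.3f s), %g mV\n",
    length(object@current), object@samplingRate / 1e3,
    length(object@current) / object@samplingRate, object@voltage))
  if (length(object@filterInfo))
    cat("  filters:", paste(names(object@filterInfo), collapse = ", "), "\n")
})

#' Construct an MWDistribution
#'
#' @param weights molecular weights (Da), all positive
#' @param metadata free-form list
#' @return an [MWDistribution-class]
#' @export
MWDistribution <- function(weights, metadata = list()) {
  new("MWDistribution", weights = as.numeric(weights), metadata = metadata)
}

#' @describeIn MWDistribution per-molecule weights (Da)
#' @param dist an [MWDistribution-class]
#' @export
mwWeights <- function(dist) dist@weights

setMethod("length", "MWDistribution", function(x) length(x@weights))

setMethod("show", "MWDistribution", function(object) {
  n <- length(object@weights)
  cat(sprintf("MWDistribution: %d molecules\n", n))
  if (n > 0) {
    s <- mwStats(object)
    cat(sprintf("  Mn = %.3g MDa, Mw = %.3g MDa, PDI = %.3g\n",
                s$Mn / 1e6, s$Mw / 1e6, s$PDI))
  }
})

setMethod("show", "ECDCalibration", function(object) {
  cat(sprintf("ECDCalibration (%s): %d standards, ECD range [%.3g, %.3g] pA s\n",
              object@method, nrow(object@standards),
              object@range[1], object@range[2]))
  if (object@method == "powerlaw")
    cat(sprintf("  log(MW) = %.4g + %.4g log(ECD)\n",
                object@coef[["a"]], object@coef[["b"]]))
})

setMethod("show", "BrushPhysicsReport", function(object) {
  cat("BrushPhysicsReport\n")
  fmt <- function(lst, indent) {
    for (nm in names(lst)) {
      q <- lst[[nm]]
      val <- if (is.numeric(q$value)) format(signif(q$value, 4))
             else as.character(q$value)
      cat(sprintf("%s%-28s %s %s\n", indent, nm, val, q$unit))
    }
  }
  if (length(object@inputs)) { cat(" inputs:\n"); fmt(object@inputs, "   ") }
  if (length(object@values)) { cat(" derived:\n"); fmt(object@values, "   ") }
})

#' @describeIn BrushPhysicsReport-class report as a plain nested list
#'   (suitable for JSON serialization)
#' @param x a [BrushPhysicsReport-class]
#' @param ... ignored
#' @export
as.list.BrushPhysicsReport <- function(x, ...) {
  list(inputs = x@inputs, derived = x@values)
}
setMethod("as.list", "BrushPhysicsReport", as.list.BrushPhysicsReport)
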
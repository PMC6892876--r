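#' @import methods
NULL

#' Physical voxel geometry of a confocal stack
#'
#' Carries the lateral (`dx`, `dy`) and axial (`dz`) voxel sizes in
#' nanometres. Voxel indices are 0-based with half-open extents; physical
#' coordinates refer to voxel centres, so voxel `i` along x spans
#' `[i*dx, (i+1)*dx)` with centre `(i + 0.5)*dx`. The axial step of a
#' confocal stack is typically several times the lateral pixel size; the
#' anisotropy ratio `dz/dx` is available through [anisotropy()].
#'
#' @slot dx,dy lateral voxel size (nm)
#' @slot dz axial voxel size (nm)
#' @slot origin origin convention; currently always `"corner0"` (physical
#'   origin at the outer corner of voxel `(0,0,0)`)
#' @seealso [VoxelGeometry()]
#' @export
setClass("VoxelGeometry",
  representation(dx = "numeric", dy = "numeric", dz = "numeric",
                 origin = "character"),
  prototype(dx = 50, dy = 50, dz = 470, origin = "corner0"))

setValidity("VoxelGeometry", function(object) {
  msg <- NULL
  for (s in c("dx", "dy", "dz")) {
    v <- slot(object, s)
    if (length(v) != 1 || !is.finite(v) || v <= 0)
      msg <- c(msg, sprintf("'%s' must be a single positive number (nm)", s))
  }
  if (length(object@origin) != 1) msg <- c(msg, "'origin' must be length 1")
  if (is.null(msg)) TRUE else msg
})

#' Multichannel 3-D image stack with physical voxel geometry
#'
#' The carrier for all confocal data in the package: a 4-D numeric array
#' indexed `[x, y, z, channel]` together with a [VoxelGeometry-class] and
#' channel role names (e.g. `"brush"`, `"particle"`, `"dextran"`,
#' `"surface"`). Intensities are arbitrary fluorescence units.
#'
#' @slot data 4-D numeric array `[x, y, z, channel]`
#' @slot geometry a [VoxelGeometry-class]
#' @slot channels character vector naming the channel roles, one per
#'   channel plane
#' @slot metadata free-form list (generator truth, provenance, ...)
#' @seealso [ImageStack()], [stackData()], [channelNames()]
#' @export
setClass("ImageStack",
  representation(data = "array", geometry = "VoxelGeometry",
                 channels = "character", metadata = "list"),
  prototype(metadata = list()))

setValidity("ImageStack", function(object) {
  d <- dim(object@data)
  if (length(d) != 4)
    return("'data' must be a 4-D array [x, y, z, channel]")
  if (length(object@channels) != d[4])
    return(sprintf("%d channel names for %d channel planes",
                   length(object@channels), d[4]))
  if (anyDuplicated(object@channels))
    return("channel names must be unique")
  TRUE
})

#' Azimuthally averaged radial intensity profile
#'
#' Intensity versus radial distance from a reference point (a microsphere
#' centre) or plane, averaged over the voxels of a cone of given axis and
#' full aperture. Distances are physical (nm): anisotropic voxels are
#' converted to nm before binning, never resampled.
#'
#' @slot r radial bin centres (nm), strictly increasing
#' @slot intensity mean intensity per bin
#' @slot count number of voxels contributing to each bin
#' @slot axis unit direction of the cone axis (x, y, z components)
#' @slot apertureDeg full cone aperture in degrees, in (0, 180]
#' @slot channel source channel role
#' @slot binWidth radial bin width (nm)
#' @slot truncated `TRUE` if the cone left the stack before reaching the
#'   background regime requested of it
#' @export
setClass("RadialProfile",
  representation(r = "numeric", intensity = "numeric", count = "numeric",
                 axis = "numeric", apertureDeg = "numeric",
                 channel = "character", binWidth = "numeric",
                 truncated = "logical"),
  prototype(axis = c(1, 0, 0), apertureDeg = 30, channel = "brush",
            truncated = FALSE))

setValidity("RadialProfile", function(object) {
  msg <- NULL
  n <- length(object@r)
  if (length(object@intensity) != n || length(object@count) != n)
    msg <- c(msg, "'r', 'intensity' and 'count' must have equal length")
  if (n > 1 && any(diff(object@r) <= 0))
    msg <- c(msg, "bin centres must be strictly increasing")
  if (any(object@count < 0)) msg <- c(msg, "bin counts must be >= 0")
  if (object@apertureDeg <= 0 || object@apertureDeg > 180)
    msg <- c(msg, "aperture must be in (0, 180] degrees")
  if (is.null(msg)) TRUE else msg
})

#' Nanopore ionic-current trace
#'
#' A uniformly sampled trans-pore ionic current recording (pA). Typical
#' acquisition for HA translocation experiments is 200 kHz at 200 mV with
#' an additional 5 kHz digital low-pass applied before event detection.
#'
#' @slot current current samples (pA)
#' @slot samplingRate sampling rate (Hz)
#' @slot voltage applied voltage (mV)
#' @slot filterInfo list describing filters already applied
#' @export
setClass("NanoporeTrace",
  representation(current = "numeric", samplingRate = "numeric",
                 voltage = "numeric", filterInfo = "list"),
  prototype(voltage = 200, filterInfo = list()))

setValidity("NanoporeTrace", function(object) {
  msg <- NULL
  if (length(object@samplingRate) != 1 || object@samplingRate <= 0)
    msg <- c(msg, "sampling rate must be a single positive number (Hz)")
  if (length(object@current) < 2)
    msg <- c(msg, "trace must contain at least 2 samples")
  if (is.null(msg)) TRUE else msg
})

#' Molecular-weight distribution of a polymer sample
#'
#' Per-molecule molecular weights (Da) with the standard polymer moments
#' available through [mwStats()]: the number average
#' \eqn{M_n = \sum n_i M_i / \sum n_i}, the weight average
#' \eqn{M_w = \sum n_i M_i^2 / \sum n_i M_i}, and the polydispersity index
#' \eqn{PDI = M_w/M_n \ge 1}.
#'
#' @slot weights molecular weights (Da), all positive
#' @slot metadata free-form list (sampling scheme, seed, targets, ...)
#' @export
setClass("MWDistribution",
  representation(weights = "numeric", metadata = "list"),
  prototype(metadata = list()))

setValidity("MWDistribution", function(object) {
  if (length(object@weights) > 0 &&
      (any(!is.finite(object@weights)) || any(object@weights <= 0)))
    return("all molecular weights must be finite and positive")
  TRUE
})

#' ECD-to-molecular-weight calibration
#'
#' A fitted monotone map from event charge deficit (pA s) to molecular
#' weight (Da), built from quasi-monodisperse calibration standards. The
#' default model is a power law, i.e. a straight line in log-log space:
#' `log(MW) = a + b log(ECD)` with `b > 0`.
#'
#' @slot coef named numeric `c(a = ..., b = ...)` of the log-log fit
#' @slot standards data.frame of the `(ecd_pAs, mw_Da)` standards used
#' @slot range ECD validity range (pA s); predictions outside it are
#'   flagged as extrapolated
#' @slot method `"powerlaw"` or `"spline"` (monotone interpolating spline)
#' @slot spline the spline function when `method == "spline"`
#' @export
setClass("ECDCalibration",
  representation(coef = "numeric", standards = "data.frame",
                 range = "numeric", method = "character", spline = "ANY"),
  prototype(method = "powerlaw", spline = NULL))

setValidity("ECDCalibration", function(object) {
  if (object@method == "powerlaw") {
    if (!all(c("a", "b") %in% names(object@coef)))
      return("power-law calibration needs coefficients 'a' and 'b'")
    if (object@coef[["b"]] <= 0)
      return("calibration must be strictly increasing (b > 0)")
  }
  if (length(object@range) != 2 || diff(object@range) <= 0)
    return("'range' must be an increasing length-2 ECD interval")
  TRUE
})

#' Derived polymer-brush physics quantities
#'
#' The closed-form quantities derived from molecular weight and dry brush
#' thickness: monomer count N, contour length, grafting density (chains
#' per nm^2 and per um^2), mean inter-chain spacing, hydrodynamic radius
#' and the brush-regime ratio (chain diameter over spacing). Inputs are
#' echoed with units so a report is self-describing.
#'
#' @slot values named list of derived quantities, each a list with
#'   `value` and `unit`
#' @slot inputs named list of the inputs used, each with `value` and `unit`
#' @export
setClass("BrushPhysicsReport",
  representation(values = "list", inputs = "list"),
  prototype(values = list(), inputs = list()))
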
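#' Write an ImageStack as multi-page TIFF with a JSON sidecar
#'
#' Pages are written channel-major (all z slices of channel 1, then
#' channel 2, ...) as 32-bit float TIFF, scaled into \[0, 1\] by a
#' recorded scale factor. Voxel geometry, channel roles, dimensions, the
#' scale and any metadata (generator truth) go into `<path>.json`, so a
#' stack round-trips losslessly to numerical precision.
#'
#' @param stack an [ImageStack-class]
#' @param path output TIFF path; the sidecar is written at `<path>.json`
#' @return `path`, invisibly
#' @export
writeStack <- function(stack, path) {
  d <- dim(stack)
  lo <- min(stack@data)
  hi <- max(stack@data)
  scale <- if (hi > lo) hi - lo else 1
  pages <- vector("list", d[3] * d[4])
  k <- 0
  for (ci in seq_len(d[4])) for (zi in seq_len(d[3])) {
    k <- k + 1
    # TIFF convention: rows = y; transpose the [x, y] plane
    pages[[k]] <- t((stack@data[, , zi, ci] - lo) / scale)
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
  geom <- voxelGeometry(stack)
  sidecar <- list(
    dims = d, channels = channelNames(stack),
    voxel_nm = list(dx = geom@dx, dy = geom@dy, dz = geom@dz),
    intensity_offset = lo, intensity_scale = scale,
    page_order = "z-within-channel",
    metadata = stackMetadata(stack))
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read an ImageStack written by [writeStack()]
#'
#' @param path TIFF path with a `<path>.json` sidecar
#' @return an [ImageStack-class]
#' @export
readStack <- function(path) {
  sc <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  d <- as.integer(sc$dims)
  arr <- array(0, d)
  k <- 0
  for (ci in seq_len(d[4])) for (zi in seq_len(d[3])) {
    k <- k + 1
    arr[, , zi, ci] <- t(pages[[k]]) * sc$intensity_scale +
      sc$intensity_offset
  }
  geom <- VoxelGeometry(sc$voxel_nm[["dx"]], sc$voxel_nm[["dy"]],
                        sc$voxel_nm[["dz"]])
  md <- if (is.null(sc$metadata)) list() else sc$metadata
  ImageStack(arr, geom, sc$channels, md)
}

#' Write a nanopore trace as CSV with a JSON sidecar
#'
#' Two columns, `time_s` and `current_pA`; sampling rate, voltage and
#' filter metadata go into `<path>.json`.
#'
#' @param trace a [NanoporeTrace-class]
#' @param path output CSV path
#' @return `path`, invisibly
#' @export
writeTrace <- function(trace, path) {
  fs <- samplingRate(trace)
  dt <- data.table::data.table(
    time_s = (seq_along(traceCurrent(trace)) - 1) / fs,
    current_pA = traceCurrent(trace))
  data.table::fwrite(dt, path)
  jsonlite::write_json(
    list(samplingRate_Hz = fs, voltage_mV = trace@voltage,
         n_samples = length(trace), filterInfo = trace@filterInfo),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a nanopore trace written by [writeTrace()]
#'
#' @param path CSV path; sampling rate is taken from the `<path>.json`
#'   sidecar when present, else inferred from the time column
#' @return a [NanoporeTrace-class]
#' @export
readTrace <- function(path) {
  dt <- data.table::fread(path)
  sidecarPath <- paste0(path, ".json")
  if (file.exists(sidecarPath)) {
    sc <- jsonlite::read_json(sidecarPath, simplifyVector = TRUE)
    fs <- sc$samplingRate_Hz
    voltage <- if (!is.null(sc$voltage_mV)) sc$voltage_mV else 200
    fi <- if (is.null(sc$filterInfo)) list() else as.list(sc$filterInfo)
  } else {
    fs <- 1 / stats::median(diff(dt$time_s))
    voltage <- 200
    fi <- list()
  }
  NanoporeTrace(dt$current_pA, fs, voltage, fi)
}

#' Read ECD calibration standards from CSV
#'
#' @param path CSV with columns `ecd_pAs` and `mw_Da`
#' @return data.frame suitable for [fitECDCalibration()]
#' @export
readCalibrationStandards <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("ecd_pAs", "mw_Da") %in% names(df)))
    stop("calibration CSV needs columns 'ecd_pAs' and 'mw_Da'")
  df
}
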
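#' Otsu threshold of an intensity sample
#'
#' The threshold maximizing the between-class variance of the intensity
#' histogram. Intensities are pooled over the whole array (whatever its
#' dimensionality), binned into `levels` equal-width bins over the data
#' range, and the optimal histogram cut is located; the returned value is
#' on the original intensity scale and foreground is `x > threshold`.
#'
#' @param x numeric vector or array of intensities with at least two
#'   distinct values
#' @param levels number of histogram bins
#' @return the threshold (original intensity units)
#' @export
otsuThreshold <- function(x, levels = 256) {
  v <- as.numeric(x)
  v <- v[is.finite(v)]
  rng <- range(v)
  if (length(v) < 2 || rng[1] == rng[2])
    stop("degenerate histogram: need at least two distinct intensities")
  scaled <- matrix((v - rng[1]) / (rng[2] - rng[1]), ncol = 1)
  th <- EBImage::otsu(scaled, range = c(0, 1), levels = levels)
  rng[1] + th * (rng[2] - rng[1])
}

# 3-D 6-connected component labelling by frontier flood fill on linear
# indices. Returns an integer array, 0 = background.
.labelComponents3D <- function(mask) {
  d <- dim(mask)
  n <- prod(d)
  nx <- d[1]; nxy <- d[1] * d[2]
  lab <- integer(n)
  todo <- which(mask)
  unvisited <- logical(n)
  unvisited[todo] <- TRUE
  cur <- 0L
  for (s in todo) {
    if (!unvisited[s]) next
    cur <- cur + 1L
    frontier <- s
    unvisited[s] <- FALSE
    lab[s] <- cur
    while (length(frontier)) {
      i0 <- frontier - 1L  # 0-based for coordinate arithmetic
      x <- i0 %% nx
      y <- (i0 %/% nx) %% d[2]
      z <- i0 %/% nxy
      nb <- c(frontier[x > 0] - 1L, frontier[x < nx - 1L] + 1L,
              frontier[y > 0] - nx, frontier[y < d[2] - 1L] + nx,
              frontier[z > 0] - nxy, frontier[z < d[3] - 1L] + nxy)
      nb <- unique(nb[unvisited[nb]])
      unvisited[nb] <- FALSE
      lab[nb] <- cur
      frontier <- nb
    }
  }
  array(lab, d)
}

#' Locate microspheres in a confocal stack
#'
#' Thresholds the requested channel with [binarizeStack()] (Otsu with a
#' noise-floor guard, so signal-free stacks yield no components), labels
#' the 6-connected components of the mask, and reports each component's
#' centroid in physical coordinates (nm), its equivalent-sphere radius
#' (from the component volume) and whether it touches the stack border.
#' For a brush-labelled microsphere the bright component is the brush
#' shell around the bead; by symmetry its centroid is the bead centre.
#'
#' @param stack an [ImageStack-class]
#' @param channel channel to segment (role name or index); the dextran or
#'   brush-label channel both work
#' @param minVoxels components smaller than this are discarded
#' @param threshold optional fixed threshold overriding Otsu
#' @return data.frame with one row per sphere: `x_nm`, `y_nm`, `z_nm`,
#'   `equivRadiusNm`, `nVoxels`, `touchesBorder`. Zero rows (with a
#'   `note` attribute) if nothing exceeds `minVoxels`.
#' @export
segmentSphereCenters <- function(stack, channel = "brush",
                                 minVoxels = 50, threshold = NULL) {
  arr <- stackData(stack, channel)
  geom <- voxelGeometry(stack)
  bin <- binarizeStack(arr, threshold = threshold)
  mask <- bin$mask
  threshold <- bin$threshold
  empty <- data.frame(x_nm = numeric(0), y_nm = numeric(0),
                      z_nm = numeric(0), equivRadiusNm = numeric(0),
                      nVoxels = integer(0), touchesBorder = logical(0))
  if (!any(mask)) {
    attr(empty, "note") <- "no voxels above threshold"
    return(empty)
  }
  lab <- .labelComponents3D(mask)
  d <- dim(mask)
  idx <- which(lab > 0)
  comp <- lab[idx]
  keep <- which(tabulate(comp) >= minVoxels)
  if (!length(keep)) {
    attr(empty, "note") <- sprintf("no component with >= %d voxels", minVoxels)
    return(empty)
  }
  coords <- arrayInd(idx, d)
  vox <- voxelVolumeUm3(geom) * 1e9  # nm^3
  out <- do.call(rbind, lapply(keep, function(k) {
    sel <- comp == k
    ijk <- coords[sel, , drop = FALSE]
    data.frame(
      x_nm = mean((ijk[, 1] - 0.5) * geom@dx),
      y_nm = mean((ijk[, 2] - 0.5) * geom@dy),
      z_nm = mean((ijk[, 3] - 0.5) * geom@dz),
      equivRadiusNm = (3 * sum(sel) * vox / (4 * pi))^(1 / 3),
      nVoxels = sum(sel),
      touchesBorder = any(ijk[, 1] %in% c(1L, d[1])) ||
                      any(ijk[, 2] %in% c(1L, d[2])) ||
                      any(ijk[, 3] %in% c(1L, d[3])))
  }))
  attr(out, "threshold") <- threshold
  out[order(-out$nVoxels), , drop = FALSE]
}
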
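# Independent reference implementations used to validate the package's
# optimized code paths. Each is written as a direct transcription of the
# definition, with no shared code with the implementation it checks.

# Otsu by exhaustive search over every histogram cut point: for each of
# the `levels` cuts, the between-class variance w1*w2*(mu1 - mu2)^2 is
# computed from scratch (same equal-width binning over the data range as
# the package). Returns the per-cut variance curve and its maximum; the
# variance achieved at any threshold can then be compared against the
# exhaustive maximum. (The argmax can be a plateau — every cut through
# an empty histogram gap is equally optimal — so the meaningful check is
# achieved-variance optimality, not the tie-breaking convention.)
oracleOtsuCurve <- function(v, levels = 256) {
  v <- as.numeric(v)
  breaks <- seq(min(v), max(v), length.out = levels + 1)
  h <- hist(v, breaks = breaks, plot = FALSE)
  cnt <- as.double(h$counts)
  mids <- h$mids
  vs <- rep(NA_real_, levels)
  for (t in seq_len(levels)) {
    w1 <- sum(cnt[seq_len(t)])
    w2 <- sum(cnt) - w1
    if (w1 == 0 || w2 == 0) next
    mu1 <- sum(cnt[seq_len(t)] * mids[seq_len(t)]) / w1
    mu2 <- sum(cnt[-seq_len(t)] * mids[-seq_len(t)]) / w2
    vs[t] <- w1 * w2 * (mu1 - mu2)^2
  }
  list(mids = mids, var = vs, maxVar = max(vs, na.rm = TRUE))
}

# Between-class variance achieved by cutting the same histogram at a
# given threshold (bins whose mid is <= threshold form class 1).
oracleVarAt <- function(curve, threshold) {
  t <- findInterval(threshold, curve$mids)
  if (t < 1 || t > length(curve$var)) return(NA_real_)
  curve$var[t]
}

# Cone profile by a per-voxel triple loop: membership tested voxel by
# voxel against the angle criterion, sums accumulated per radial bin.
oracleConeProfile <- function(arr, geom, centerNm, axis, apertureDeg,
                              binWidthNm) {
  axis <- axis / sqrt(sum(axis^2))
  cosHalf <- cos(apertureDeg / 2 * pi / 180)
  d <- dim(arr)
  extent <- d * c(geom@dx, geom@dy, geom@dz)
  tExit <- Inf
  for (i in 1:3) {
    if (axis[i] > 0) tExit <- min(tExit, (extent[i] - centerNm[i]) / axis[i])
    if (axis[i] < 0) tExit <- min(tExit, -centerNm[i] / axis[i])
  }
  sums <- numeric(0)
  cnts <- numeric(0)
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    v <- c((i - 0.5) * geom@dx, (j - 0.5) * geom@dy,
           (k - 0.5) * geom@dz) - centerNm
    r <- sqrt(sum(v^2))
    if (r == 0 || r > tExit) next
    if (sum(v * axis) / r < cosHalf) next
    b <- floor(r / binWidthNm) + 1
    if (b > length(sums)) {
      sums <- c(sums, numeric(b - length(sums)))
      cnts <- c(cnts, numeric(b - length(cnts)))
    }
    sums[b] <- sums[b] + arr[i, j, k]
    cnts[b] <- cnts[b] + 1
  }
  keep <- cnts > 0
  list(r = ((seq_along(sums) - 0.5) * binWidthNm)[keep],
       intensity = (sums / pmax(cnts, 1))[keep], count = cnts[keep])
}

# Build a RadialProfile directly from vectors (for closed-form tests).
makeProfile <- function(r, intensity, binWidth = diff(r[1:2])) {
  new("RadialProfile", r = r, intensity = intensity,
      count = rep(1, length(r)), axis = c(1, 0, 0), apertureDeg = 30,
      channel = "brush", binWidth = binWidth, truncated = FALSE)
}

# A raw trace with rectangular pulses at known positions on a constant
# baseline (noise optional), bypassing the generator.
makePulseTrace <- function(n, fs, baseline, pulses, noiseSd = 0,
                           seed = NULL) {
  y <- rep(baseline, n)
  if (!is.null(seed)) set.seed(seed)
  if (noiseSd > 0) y <- y + rnorm(n, 0, noiseSd)
  for (p in pulses)
    y[p$start:(p$start + p$len - 1)] <-
      y[p$start:(p$start + p$len - 1)] - p$depth
  NanoporeTrace(y, fs)
}
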
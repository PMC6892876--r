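## internal helpers shared across modules

# Evaluate `code` under a temporary RNG seed, restoring the caller's RNG
# state afterwards. seed = NULL uses (and advances) the current stream.
withSeed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  genv <- globalenv()
  if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
    old <- get(".Random.seed", envir = genv, inherits = FALSE)
    on.exit(assign(".Random.seed", old, envir = genv))
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = genv)))
  }
  set.seed(seed)
  force(code)
}

# Linear interpolation of the x where y crosses `level` between two
# samples (x1,y1) -> (x2,y2); falls back to x1 when flat.
.crossingX <- function(x1, y1, x2, y2, level) {
  if (y2 == y1) return(x1)
  x1 + (level - y1) * (x2 - x1) / (y2 - y1)
}

# Parabolic (3-point) refinement of a peak at index i of (x, y);
# returns the refined x. Assumes uniform-ish spacing around i.
.parabolicPeak <- function(x, y, i) {
  if (i <= 1 || i >= length(y)) return(x[i])
  denom <- y[i - 1] - 2 * y[i] + y[i + 1]
  if (denom >= 0) return(x[i])  # not a strict local max in curvature
  delta <- 0.5 * (y[i - 1] - y[i + 1]) / denom
  delta <- max(min(delta, 0.5), -0.5)
  x[i] + delta * (x[i + 1] - x[i])
}
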
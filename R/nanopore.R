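#' Robust baseline and noise level of a nanopore trace
#'
#' Baseline by rolling median, insensitive to translocation events
#' occupying a minority of the window, and noise sigma as the scaled
#' median absolute deviation (MAD x 1.4826) of the residuals. For speed
#' on long traces the rolling median is evaluated hierarchically: the
#' trace is cut into blocks of `windowSamples / 25` samples, a running
#' median is taken over the block medians spanning one window, and the
#' result is interpolated back to sample resolution. An event is
#' rejected from the baseline as long as it occupies a minority of the
#' window, so keep the window at least ~5x the longest expected event.
#'
#' @param trace a [NanoporeTrace-class]
#' @param windowSamples rolling-median window (samples)
#' @return list with `baseline` (per-sample vector, pA) and `sigma` (pA)
#' @export
estimateBaseline <- function(trace, windowSamples = 50001) {
  y <- traceCurrent(trace)
  n <- length(y)
  if (windowSamples >= n)
    stop("baseline window must be shorter than the trace")
  block <- max(1L, as.integer(windowSamples) %/% 25L)
  nb <- n %/% block
  if (nb < 3L) {
    baseline <- rep(stats::median(y), n)
  } else {
    used <- nb * block
    bm <- .colMedians(matrix(y[seq_len(used)], nrow = block))
    k <- as.integer(round(windowSamples / block))
    if (k %% 2L == 0L) k <- k + 1L
    rb <- if (k >= nb) rep(stats::median(bm), nb)
          else as.numeric(stats::runmed(bm, k, endrule = "median"))
    centers <- (seq_len(nb) - 0.5) * block
    baseline <- stats::approx(centers, rb, xout = seq_len(n),
                              rule = 2)$y
  }
  sigma <- stats::mad(y - baseline)
  list(baseline = baseline, sigma = sigma)
}

# column medians without extra dependencies
.colMedians <- function(m) apply(m, 2, stats::median)

#' Zero-phase low-pass filter
#'
#' Forward-backward (zero-lag) Butterworth low-pass with unit DC gain,
#' the digital analogue of the 5 kHz software filter applied to nanopore
#' recordings before event detection. The trace is extended at both ends
#' by odd (mirror) reflection before filtering and trimmed afterwards,
#' which suppresses the start-up transients a recursive filter otherwise
#' injects at the trace boundaries.
#'
#' @param trace a [NanoporeTrace-class]
#' @param cutoffHz cutoff frequency (Hz); must be below Nyquist
#' @param order Butterworth order (each pass; default 4)
#' @return the filtered [NanoporeTrace-class] with updated `filterInfo`
#' @export
lowpassTrace <- function(trace, cutoffHz = 5000, order = 4) {
  fs <- samplingRate(trace)
  if (cutoffHz >= fs / 2)
    stop(sprintf("cutoff %g Hz is not below the Nyquist frequency %g Hz",
                 cutoffHz, fs / 2))
  bf <- signal::butter(order, cutoffHz / (fs / 2), type = "low")
  y <- traceCurrent(trace)
  n <- length(y)
  pad <- min(n - 1, ceiling(3 * fs / cutoffHz))
  ext <- c(2 * y[1] - y[(pad + 1):2],
           y,
           2 * y[n] - y[(n - 1):(n - pad)])
  filtered <- signal::filtfilt(bf, ext)[(pad + 1):(pad + n)]
  fi <- trace@filterInfo
  fi$lowpass <- list(cutoffHz = cutoffHz, order = order,
                     type = "butterworth-filtfilt")
  NanoporeTrace(filtered, fs, trace@voltage, fi)
}

#' Event charge deficit of one event
#'
#' The time-integrated current deficit
#' \eqn{ECD = \sum (baseline - I) \Delta t} over the event window
#' (half-open sample indices), clamped at >= 0. The trapezoidal option
#' weights the first and last samples by 1/2.
#'
#' @param trace a [NanoporeTrace-class]
#' @param startIdx,endIdx event window, 1-based half-open
#'   (`startIdx` inclusive, `endIdx` exclusive)
#' @param baseline per-sample baseline vector or scalar (pA)
#' @param method `"sum"` (rectangle rule, default) or `"trapezoid"`
#' @return ECD in pA s
#' @export
eventECD <- function(trace, startIdx, endIdx, baseline, method = "sum") {
  n <- length(trace)
  if (startIdx >= endIdx) stop("inverted event boundaries")
  if (startIdx < 1 || endIdx > n + 1) stop("event boundaries outside trace")
  idx <- startIdx:(endIdx - 1)
  b <- if (length(baseline) == 1) rep(baseline, length(idx))
       else baseline[idx]
  deficit <- b - traceCurrent(trace)[idx]
  dt <- 1 / samplingRate(trace)
  ecd <- if (method == "trapezoid" && length(deficit) > 1) {
    w <- rep(1, length(deficit)); w[c(1, length(w))] <- 0.5
    sum(w * deficit) * dt
  } else sum(deficit) * dt
  max(ecd, 0)
}

#' Detect translocation events in a nanopore trace
#'
#' Resistive pulses are identified as maximal runs of samples deviating
#' below the baseline by more than `kSigma * sigma`; each run is then
#' extended outward to the nearest baseline re-crossings so that shallow
#' pulse shoulders are integrated, and runs whose extensions touch are
#' merged. Candidates with durations outside the closed gate
#' `[dminS, dmaxS]` are rejected with a reason code. Detection is
#' invariant to adding a constant to the whole trace.
#'
#' @param trace a [NanoporeTrace-class] (normally low-pass filtered
#'   first, see [lowpassTrace()])
#' @param baselineFit result of [estimateBaseline()]; `NULL` estimates
#'   it with default settings
#' @param kSigma detection threshold in noise sigmas (default 5)
#' @param dminS,dmaxS duration gate in seconds, inclusive at both ends
#'   (defaults 25 us and 2.5 s)
#' @param extend extend run boundaries to baseline re-crossings
#' @return data.frame with one row per candidate: `startIdx`, `endIdx`
#'   (half-open), `durationS`, `meanAmpPA`, `ecdPAs`, `accepted`,
#'   `reason` (`"ok"`, `"too-short"`, `"too-long"`)
#' @export
detectEvents <- function(trace, baselineFit = NULL, kSigma = 5,
                         dminS = 25e-6, dmaxS = 2.5, extend = TRUE) {
  if (is.null(baselineFit)) baselineFit <- estimateBaseline(trace)
  y <- traceCurrent(trace)
  b <- baselineFit$baseline
  if (length(b) == 1) b <- rep(b, length(y))
  sigma <- baselineFit$sigma
  if (sigma == 0 && any(y != y[1]))
    stop("degenerate noise estimate: sigma = 0 on a nonconstant trace")
  fs <- samplingRate(trace)
  below <- y < b - kSigma * sigma
  runs <- rle(below)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  sel <- runs$values
  empty <- data.frame(startIdx = integer(0), endIdx = integer(0),
                      durationS = numeric(0), meanAmpPA = numeric(0),
                      ecdPAs = numeric(0), accepted = logical(0),
                      reason = character(0))
  if (!any(sel)) return(empty)
  s0 <- starts[sel]
  e0 <- ends[sel]  # inclusive last below-threshold sample
  if (extend) {
    # extend to the nearest samples at/above baseline on either side
    atBaseline <- which(y >= b)
    if (length(atBaseline)) {
      li <- findInterval(s0, atBaseline)         # last crossing before run
      s0 <- ifelse(li >= 1, atBaseline[pmax(li, 1)] + 1L, 1L)
      ri <- length(atBaseline) - findInterval(-e0, rev(-atBaseline))
      nxt <- ifelse(ri < length(atBaseline), atBaseline[ri + 1L],
                    length(y) + 1L)
      e0 <- nxt - 1L
    } else {
      s0 <- rep(1L, length(s0))
      e0 <- rep(length(y), length(e0))
    }
    # merge events whose extended windows overlap or touch
    if (length(s0) > 1) {
      keep <- c(TRUE, s0[-1] > cummax(e0[-length(e0)]) + 0L)
      grp <- cumsum(keep)
      s0 <- tapply(s0, grp, min)
      e0 <- tapply(e0, grp, max)
    }
  }
  s0 <- as.integer(s0)
  e1 <- as.integer(e0) + 1L  # half-open end
  durS <- (e1 - s0) / fs
  amp <- mapply(function(a, b2) mean(b[a:(b2 - 1)] - y[a:(b2 - 1)]), s0, e1)
  ecd <- mapply(function(a, b2) eventECD(trace, a, b2, b), s0, e1)
  reason <- ifelse(durS < dminS, "too-short",
                   ifelse(durS > dmaxS, "too-long", "ok"))
  data.frame(startIdx = s0, endIdx = e1, durationS = durS,
             meanAmpPA = amp, ecdPAs = ecd, accepted = reason == "ok",
             reason = reason)
}

#' Reference event detector (single-pass scan)
#'
#' A deliberately plain, loop-based implementation of the same event
#' semantics as [detectEvents()] (threshold runs, boundary extension to
#' baseline re-crossings, merging, inclusive duration gate), written as
#' an explicit sample-by-sample scan. It serves as an independent
#' reference for validating the vectorized detector and is practical for
#' traces up to ~1e5 samples.
#'
#' @inheritParams detectEvents
#' @return same data.frame as [detectEvents()]
#' @export
detectEventsNaive <- function(trace, baselineFit = NULL, kSigma = 5,
                              dminS = 25e-6, dmaxS = 2.5, extend = TRUE) {
  if (is.null(baselineFit)) baselineFit <- estimateBaseline(trace)
  y <- traceCurrent(trace)
  b <- baselineFit$baseline
  if (length(b) == 1) b <- rep(b, length(y))
  sigma <- baselineFit$sigma
  if (sigma == 0 && any(y != y[1]))
    stop("degenerate noise estimate: sigma = 0 on a nonconstant trace")
  fs <- samplingRate(trace)
  thr <- b - kSigma * sigma
  n <- length(y)
  starts <- integer(0); ends <- integer(0)
  i <- 1L
  while (i <= n) {
    if (y[i] < thr[i]) {
      j <- i
      while (j < n && y[j + 1L] < thr[j + 1L]) j <- j + 1L
      s <- i; e <- j
      if (extend) {
        while (s > 1L && y[s - 1L] < b[s - 1L]) s <- s - 1L
        while (e < n && y[e + 1L] < b[e + 1L]) e <- e + 1L
      }
      if (length(ends) && s <= ends[length(ends)] ) {
        ends[length(ends)] <- e
      } else {
        starts <- c(starts, s); ends <- c(ends, e)
      }
      i <- j + 1L
    } else i <- i + 1L
  }
  if (!length(starts))
    return(data.frame(startIdx = integer(0), endIdx = integer(0),
                      durationS = numeric(0), meanAmpPA = numeric(0),
                      ecdPAs = numeric(0), accepted = logical(0),
                      reason = character(0)))
  out <- lapply(seq_along(starts), function(k) {
    s <- starts[k]; e1 <- ends[k] + 1L
    dur <- (e1 - s) / fs
    deficit <- b[s:(e1 - 1L)] - y[s:(e1 - 1L)]
    reason <- if (dur < dminS) "too-short"
              else if (dur > dmaxS) "too-long" else "ok"
    data.frame(startIdx = s, endIdx = e1, durationS = dur,
               meanAmpPA = mean(deficit),
               ecdPAs = max(sum(deficit) / fs, 0),
               accepted = reason == "ok", reason = reason)
  })
  do.call(rbind, out)
}

#' Fit an ECD-to-molecular-weight calibration
#'
#' Least-squares fit of `log(MW) = a + b log(ECD)` to quasi-monodisperse
#' calibration standards (power-law map), or a monotone interpolating
#' spline in log-log space. The fitted map must be strictly increasing;
#' non-monotone standards are an error.
#'
#' @param standards data.frame with columns `ecd_pAs` and `mw_Da`
#' @param method `"powerlaw"` (default) or `"spline"`
#' @return an [ECDCalibration-class]
#' @export
fitECDCalibration <- function(standards, method = c("powerlaw", "spline")) {
  method <- match.arg(method)
  if (!all(c("ecd_pAs", "mw_Da") %in% names(standards)))
    stop("standards need columns 'ecd_pAs' and 'mw_Da'")
  st <- standards[order(standards$ecd_pAs), c("ecd_pAs", "mw_Da")]
  if (nrow(st) < 2 || anyDuplicated(st$ecd_pAs))
    stop("need at least 2 standards with distinct ECD values")
  if (any(st$ecd_pAs <= 0) || any(st$mw_Da <= 0))
    stop("standards must be positive")
  if (any(diff(st$mw_Da) <= 0))
    stop("standards are not monotone: MW must increase with ECD")
  if (method == "powerlaw") {
    fit <- stats::lm(log(mw_Da) ~ log(ecd_pAs), data = st)
    cf <- stats::coef(fit)
    new("ECDCalibration", coef = c(a = unname(cf[1]), b = unname(cf[2])),
        standards = st, range = range(st$ecd_pAs), method = "powerlaw")
  } else {
    sf <- stats::splinefun(log(st$ecd_pAs), log(st$mw_Da), method = "hyman")
    new("ECDCalibration", coef = c(a = NA_real_, b = 1),
        standards = st, range = range(st$ecd_pAs), method = "spline",
        spline = sf)
  }
}

#' Convert event charge deficits to molecular weights
#'
#' @param calibration an [ECDCalibration-class]
#' @param ecdPAs ECD values (pA s)
#' @return list with `mwDa` and logical `extrapolated` (ECD outside the
#'   standards' range)
#' @export
predictMW <- function(calibration, ecdPAs) {
  if (any(ecdPAs <= 0)) stop("ECD values must be positive")
  mw <- if (calibration@method == "powerlaw")
    exp(calibration@coef[["a"]] + calibration@coef[["b"]] * log(ecdPAs))
  else exp(calibration@spline(log(ecdPAs)))
  list(mwDa = as.numeric(mw),
       extrapolated = ecdPAs < calibration@range[1] |
                      ecdPAs > calibration@range[2])
}

#' End-to-end nanopore molecular-weight pipeline
#'
#' Low-pass filter, baseline estimation, event detection, ECD
#' computation and calibration to molecular weight, returning the
#' molecular-weight distribution with per-event provenance in its
#' metadata.
#'
#' @param trace a raw [NanoporeTrace-class]
#' @param calibration an [ECDCalibration-class]
#' @param cutoffHz low-pass cutoff (Hz); `NULL` skips filtering
#' @param kSigma,dminS,dmaxS see [detectEvents()]
#' @param windowSamples see [estimateBaseline()]
#' @return an [MWDistribution-class]; `metadata$events` holds the
#'   accepted-event table with ECDs and assigned MWs, and
#'   `metadata$rejected` the rejected candidates
#' @export
nanoporeMWPipeline <- function(trace, calibration, cutoffHz = 5000,
                               kSigma = 5, dminS = 25e-6, dmaxS = 2.5,
                               windowSamples = 50001) {
  filtered <- if (is.null(cutoffHz)) trace else lowpassTrace(trace, cutoffHz)
  bl <- estimateBaseline(filtered, windowSamples)
  ev <- detectEvents(filtered, bl, kSigma, dminS, dmaxS)
  acc <- ev[ev$accepted & ev$ecdPAs > 0, , drop = FALSE]
  if (nrow(acc) == 0)
    return(MWDistribution(numeric(0), metadata = list(
      events = acc, rejected = ev[!ev$accepted, , drop = FALSE],
      sigma = bl$sigma)))
  pred <- predictMW(calibration, acc$ecdPAs)
  acc$mwDa <- pred$mwDa
  acc$extrapolated <- pred$extrapolated
  MWDistribution(acc$mwDa, metadata = list(
    events = acc, rejected = ev[!ev$accepted, , drop = FALSE],
    sigma = bl$sigma))
}
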
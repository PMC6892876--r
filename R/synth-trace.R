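#' Simulate a nanopore ionic-current trace from a molecular-weight
#' distribution
#'
#' Renders one resistive pulse per molecule on a noisy baseline. The
#' forward map from molecular weight to pulse shape keeps the blockade
#' amplitude fixed and makes the dwell time proportional to MW, so the
#' event charge deficit is proportional to MW (only the ECD, not the
#' pulse shape, carries information downstream). Pulses are rectangular
#' by default (optionally with smoothed edges) and are placed
#' sequentially with exponential gaps plus a guaranteed minimum gap, so
#' events never overlap. The per-event ground truth (sample indices,
#' rendered duration, amplitude, noiseless ECD, molecular weight) is
#' returned in the trace metadata and as a data.frame.
#'
#' @param mw an [MWDistribution-class] or numeric vector of molecular
#'   weights (Da); may be empty (pure baseline trace)
#' @param samplingRate sampling rate (Hz), default 200 kHz
#' @param baselinePA open-pore baseline current (pA)
#' @param noiseSdPA Gaussian baseline noise sd (pA)
#' @param amplitudePA pulse amplitude (pA): a scalar, or a function of
#'   the MW vector returning per-event amplitudes
#' @param dwellPerDaS dwell time per Dalton (s/Da); default 1e-9, i.e.
#'   1 ms per MDa
#' @param meanGapS mean of the exponential inter-event gap (s)
#' @param minGapS minimum gap between events (s)
#' @param padS padding before the first and after the last event (s)
#' @param riseSamples 0 for rectangular pulses; > 0 applies a moving
#'   average of that many samples to the pulse train (smoothed edges)
#' @param seed RNG seed
#' @return list with `trace` (a [NanoporeTrace-class]) and `events`
#'   (data.frame: `startIdx`, `endIdx` half-open, `durationS`,
#'   `amplitudePA`, `ecdPAs`, `mwDa`)
#' @export
simulateNanoporeTrace <- function(mw, samplingRate = 2e5,
    baselinePA = 10000, noiseSdPA = 10, amplitudePA = 200,
    dwellPerDaS = 1e-9, meanGapS = 0.02, minGapS = 0.005, padS = 0.05,
    riseSamples = 0, seed = NULL) {
  weights <- if (is(mw, "MWDistribution")) mwWeights(mw) else as.numeric(mw)
  fs <- samplingRate
  n <- length(weights)
  amps <- if (is.function(amplitudePA)) amplitudePA(weights)
          else rep(amplitudePA, n)
  dur <- weights * dwellPerDaS
  if (n > 0 && any(dur < 1 / fs))
    stop("requested event durations fall below one sampling interval")
  durSamp <- pmax(1L, as.integer(round(dur * fs)))
  withSeed(seed, {
    gaps <- if (n > 0) minGapS + stats::rexp(n, 1 / meanGapS) else numeric(0)
    starts <- integer(n)
    pos <- as.integer(round(padS * fs)) + 1L
    for (i in seq_len(n)) {
      pos <- pos + as.integer(round(gaps[i] * fs))
      starts[i] <- pos
      pos <- pos + durSamp[i]
    }
    total <- pos + as.integer(round(padS * fs))
    if (n > 0 && any(dur > total / fs))
      stop("requested event durations exceed the trace length")
    pulse <- numeric(total)
    for (i in seq_len(n))
      pulse[starts[i]:(starts[i] + durSamp[i] - 1L)] <- -amps[i]
    if (riseSamples > 0) {
      k <- rep(1 / riseSamples, riseSamples)
      pulse <- as.numeric(stats::filter(pulse, k, sides = 2,
                                        circular = TRUE))
    }
    y <- baselinePA + pulse
    if (noiseSdPA > 0) y <- y + stats::rnorm(total, 0, noiseSdPA)
    events <- data.frame(
      startIdx = starts, endIdx = starts + durSamp,
      durationS = durSamp / fs, amplitudePA = amps,
      ecdPAs = amps * durSamp / fs, mwDa = weights)
    trace <- NanoporeTrace(y, fs, filterInfo = list(
      synthetic = list(baselinePA = baselinePA, noiseSdPA = noiseSdPA,
                       seed = seed, riseSamples = riseSamples)))
    list(trace = trace, events = events)
  })
}

#' Calibration standards from the synthetic forward map
#'
#' Builds an `(ECD, MW)` standards table consistent with the synthetic
#' forward map of [simulateNanoporeTrace()] (fixed amplitude, dwell
#' proportional to MW), emulating quasi-monodisperse calibration
#' samples.
#'
#' @param mwDa molecular weights of the standards (Da)
#' @param amplitudePA,dwellPerDaS forward-map parameters, matching the
#'   trace generator
#' @return data.frame with `ecd_pAs` and `mw_Da`
#' @export
syntheticCalibrationStandards <- function(mwDa = c(0.5e6, 1e6, 2e6, 4e6, 8e6),
                                          amplitudePA = 200,
                                          dwellPerDaS = 1e-9) {
  data.frame(ecd_pAs = amplitudePA * mwDa * dwellPerDaS, mw_Da = mwDa)
}
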
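test_that("baseline estimation is robust to events and exact on clean traces", {
  set.seed(1)
  tr <- NanoporeTrace(rnorm(5e4, 1000, 12), 2e5)
  bl <- estimateBaseline(tr, windowSamples = 5001)
  expect_equal(bl$sigma, 12, tolerance = 0.05)
  expect_equal(mean(bl$baseline), 1000, tolerance = 0.01)
  const <- NanoporeTrace(rep(500, 1000), 2e5)
  blc <- estimateBaseline(const, windowSamples = 301)
  expect_equal(blc$sigma, 0)
  expect_true(all(blc$baseline == 500))
  # ~10 percent event occupancy must not drag the baseline down
  pulses <- lapply(seq(2000, 46000, by = 5000), function(s)
    list(start = s, len = 500, depth = 300))
  tro <- makePulseTrace(5e4, 2e5, 1000, pulses, noiseSd = 12, seed = 2)
  blo <- estimateBaseline(tro, windowSamples = 5001)
  expect_lt(abs(mean(blo$baseline) - 1000), blo$sigma)
  expect_error(estimateBaseline(const, windowSamples = 2000), "shorter")
})

test_that("the zero-phase low-pass has unit DC gain and a sharp rolloff", {
  fs <- 2e5
  n <- 2e4
  const <- NanoporeTrace(rep(123.4, n), fs)
  expect_equal(traceCurrent(lowpassTrace(const, 5000)),
               rep(123.4, n), tolerance = 1e-6)
  t <- (0:(n - 1)) / fs
  hi <- NanoporeTrace(sin(2 * pi * 5e4 * t), fs)   # 10x cutoff
  hiOut <- traceCurrent(lowpassTrace(hi, 5000))
  att <- max(abs(hiOut[2000:18000]))
  expect_lt(20 * log10(att), -20)
  lo <- NanoporeTrace(sin(2 * pi * 500 * t), fs)   # 0.1x cutoff
  loOut <- traceCurrent(lowpassTrace(lo, 5000))
  expect_equal(max(abs(loOut[2000:18000])), 1, tolerance = 0.01)
  expect_error(lowpassTrace(const, 1.1e5), "Nyquist")
})

test_that("event detection finds deep pulses, rejects shallow and short ones", {
  fs <- 2e5
  tr <- makePulseTrace(4e4, fs, 1000,
                       list(list(start = 20000, len = 200, depth = 100)),
                       noiseSd = 10, seed = 3)
  bl <- estimateBaseline(tr, windowSamples = 5001)
  ev <- detectEvents(tr, bl)   # depth 10 sigma
  acc <- ev[ev$accepted, ]
  expect_equal(nrow(acc), 1)
  expect_lt(abs(acc$startIdx - 20000), 3)
  expect_lt(abs(acc$endIdx - 20200), 3)
  expect_equal(acc$durationS, 1e-3, tolerance = 0.05)
  # 3 sigma pulse: below the 5 sigma detection threshold
  tr3 <- makePulseTrace(4e4, fs, 1000,
                        list(list(start = 20000, len = 200, depth = 30)))
  ev3 <- detectEvents(tr3, list(baseline = rep(1000, 4e4), sigma = 10))
  expect_equal(sum(ev3$accepted), 0)
  # 10 us pulse (2 samples) is gated out as too short
  tr10 <- makePulseTrace(4e4, fs, 1000,
                         list(list(start = 20000, len = 2, depth = 200)))
  ev10 <- detectEvents(tr10, list(baseline = rep(1000, 4e4), sigma = 10))
  expect_true(any(ev10$reason == "too-short"))
  expect_equal(sum(ev10$accepted), 0)
})

test_that("detection is invariant to a constant baseline shift", {
  tr <- makePulseTrace(3e4, 2e5, 1000,
                       list(list(start = 10000, len = 300, depth = 150),
                            list(start = 20000, len = 100, depth = 120)),
                       noiseSd = 10, seed = 6)
  trShift <- NanoporeTrace(traceCurrent(tr) + 5000, 2e5)
  e1 <- detectEvents(tr, estimateBaseline(tr, windowSamples = 3001))
  e2 <- detectEvents(trShift, estimateBaseline(trShift,
                                               windowSamples = 3001))
  expect_equal(e1$startIdx, e2$startIdx)
  expect_equal(e1$endIdx, e2$endIdx)
  expect_equal(e1$ecdPAs, e2$ecdPAs, tolerance = 1e-6)
})

test_that("duration gate is inclusive at both ends", {
  fs <- 2e5
  bl <- list(baseline = rep(1000, 3e4), sigma = 2)
  # exactly 25 us = 5 samples at 200 kHz
  tr <- makePulseTrace(3e4, fs, 1000,
                       list(list(start = 15000, len = 5, depth = 100)))
  ev <- detectEvents(tr, bl)
  expect_equal(ev$durationS, 25e-6)
  expect_true(ev$accepted)
  # exactly 2.5 s at a low sampling rate; one sample longer is rejected
  fs2 <- 1000
  bl2 <- list(baseline = rep(1000, 4000), sigma = 2)
  tr2 <- makePulseTrace(4000, fs2, 1000,
                        list(list(start = 500, len = 2500, depth = 100)))
  ev2 <- detectEvents(NanoporeTrace(traceCurrent(tr2), fs2), bl2)
  expect_true(ev2$accepted)
  tr3 <- makePulseTrace(4000, fs2, 1000,
                        list(list(start = 500, len = 2501, depth = 100)))
  ev3 <- detectEvents(NanoporeTrace(traceCurrent(tr3), fs2), bl2)
  expect_equal(ev3$reason, "too-long")
})

test_that("degenerate noise on a nonconstant trace is an error", {
  tr <- makePulseTrace(1000, 2e5, 100,
                       list(list(start = 500, len = 10, depth = 50)))
  expect_error(detectEvents(tr, list(baseline = rep(100, 1000), sigma = 0)),
               "degenerate")
})

test_that("ECD matches analytic pulse areas, scales linearly, and is additive", {
  fs <- 2e5
  tr <- makePulseTrace(1000, fs, 1000,
                       list(list(start = 400, len = 200, depth = 100)))
  expect_equal(eventECD(tr, 400, 600, 1000), 0.1)  # 100 pA x 1 ms
  tr2 <- makePulseTrace(1000, fs, 1000,
                        list(list(start = 400, len = 200, depth = 300)))
  expect_equal(eventECD(tr2, 400, 600, 1000), 0.3)
  # triangular pulse of peak 100 pA and width 1 ms: area 0.05 pA s
  # (midpoint-sampled, so the rectangle-rule integral is exact)
  m <- 200
  tmid <- (seq_len(m) - 0.5) / m
  yd <- 1000 - 100 * (1 - abs(2 * tmid - 1))
  trT <- NanoporeTrace(c(rep(1000, 400), yd, rep(1000, 400)), fs)
  ecdT <- eventECD(trT, 401, 401 + m, 1000)
  expect_equal(ecdT, 0.05, tolerance = 1e-3)
  # splitting at any interior point conserves the integral
  for (cut in c(450, 500, 555)) {
    expect_equal(eventECD(trT, 401, cut, 1000) +
                   eventECD(trT, cut, 401 + m, 1000), ecdT)
  }
  expect_error(eventECD(tr, 600, 400, 1000), "inverted")
})

test_that("vectorized detector is identical to the single-pass reference scan", {
  set.seed(10)
  for (i in 1:20) {
    n <- sample(2e4:5e4, 1)
    nEv <- sample(3:12, 1)
    pulses <- lapply(seq_len(nEv), function(k)
      list(start = sample(1000:(n - 1000), 1),
           len = sample(c(2:4, 20:400), 1),
           depth = sample(c(20, 40, 80, 200), 1)))
    tr <- makePulseTrace(n, 2e5, 1000, pulses, noiseSd = 8)
    bl <- estimateBaseline(tr, windowSamples = 5001)
    a <- detectEvents(tr, bl)
    b <- detectEventsNaive(tr, bl)
    expect_equal(a$startIdx, b$startIdx)
    expect_equal(a$endIdx, b$endIdx)
    expect_equal(a$ecdPAs, b$ecdPAs)
    expect_equal(a$reason, b$reason)
  }
})

test_that("calibration fits are exact on power laws and match closed-form regression", {
  st <- data.frame(ecd_pAs = c(0.05, 0.1, 0.4, 1.6),
                   mw_Da = 5e6 * c(0.05, 0.1, 0.4, 1.6)^1.2)
  cal <- fitECDCalibration(st)
  expect_equal(cal@coef[["b"]], 1.2, tolerance = 1e-12)
  expect_equal(predictMW(cal, 0.4)$mwDa, st$mw_Da[3], tolerance = 1e-12)
  expect_true(predictMW(cal, 5)$extrapolated)
  expect_false(predictMW(cal, 0.2)$extrapolated)
  expect_error(fitECDCalibration(st[1, , drop = FALSE]), "2 standards")
  bad <- data.frame(ecd_pAs = c(0.1, 0.2, 0.3), mw_Da = c(2e6, 1e6, 3e6))
  expect_error(fitECDCalibration(bad), "monotone")
  # noisy standards: coefficients equal the closed-form log-log regression
  set.seed(11)
  stn <- data.frame(ecd_pAs = c(0.05, 0.1, 0.2, 0.4, 0.8, 1.6))
  stn$mw_Da <- 4e6 * stn$ecd_pAs * exp(rnorm(6, 0, 0.05))
  stn <- stn[order(stn$ecd_pAs), ]
  if (all(diff(stn$mw_Da) > 0)) {
    caln <- fitECDCalibration(stn)
    x <- log(stn$ecd_pAs); yv <- log(stn$mw_Da)
    bHat <- sum((x - mean(x)) * (yv - mean(yv))) / sum((x - mean(x))^2)
    aHat <- mean(yv) - bHat * mean(x)
    expect_equal(cal_b <- caln@coef[["b"]], bHat, tolerance = 1e-10)
    expect_equal(caln@coef[["a"]], aHat, tolerance = 1e-10)
  }
})

test_that("recall and precision are 1 for well-separated deep events", {
  d <- sampleMW(60, Mn = 2.42e6, Mw = 6.76e6, seed = 12)
  sim <- simulateNanoporeTrace(d, noiseSdPA = 10, amplitudePA = 100,
                               seed = 12)  # 10 sigma pulses
  ev <- detectEvents(sim$trace)
  acc <- ev[ev$accepted, ]
  truth <- sim$events
  matched <- vapply(seq_len(nrow(truth)), function(i)
    any(acc$startIdx < truth$endIdx[i] & acc$endIdx > truth$startIdx[i]),
    logical(1))
  fp <- vapply(seq_len(nrow(acc)), function(i)
    !any(truth$startIdx < acc$endIdx[i] & truth$endIdx > acc$startIdx[i]),
    logical(1))
  expect_equal(mean(matched), 1)   # recall
  expect_equal(mean(fp), 0)        # precision
})

test_that("the end-to-end pipeline recovers the distribution it was fed", {
  d <- sampleMW(80, Mn = 2.42e6, Mw = 6.76e6, seed = 13)
  sim <- simulateNanoporeTrace(d, seed = 13)
  cal <- fitECDCalibration(syntheticCalibrationStandards())
  out <- nanoporeMWPipeline(sim$trace, cal)
  sTruth <- mwStats(d)
  sGot <- mwStats(out)
  expect_equal(sGot$Mn, sTruth$Mn, tolerance = 0.05)
  expect_equal(sGot$Mw, sTruth$Mw, tolerance = 0.05)
  expect_true(!is.null(out@metadata$events))
})

test_that("an eventless trace yields an empty distribution and a clean stats error", {
  sim <- simulateNanoporeTrace(numeric(0), noiseSdPA = 10, seed = 14)
  cal <- fitECDCalibration(syntheticCalibrationStandards())
  out <- nanoporeMWPipeline(sim$trace, cal, windowSamples = 5001)
  expect_equal(length(out), 0)
  expect_error(mwStats(out), "empty")
})
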
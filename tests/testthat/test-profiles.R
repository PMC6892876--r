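test_that("Otsu threshold achieves the exhaustive-search variance maximum", {
  set.seed(7)
  for (i in 1:5) {
    v <- c(rnorm(2000, 30, 8), rnorm(500 + 100 * i, 120 + 10 * i, 15))
    th <- otsuThreshold(v)
    curve <- oracleOtsuCurve(v)
    expect_equal(oracleVarAt(curve, th), curve$maxVar,
                 tolerance = 1e-9)
  }
  # bimodal two-level sample: threshold strictly separates the modes
  v <- c(rep(0, 600), rep(100, 400))
  th <- otsuThreshold(v)
  expect_gt(th, 0)
  expect_lt(th, 100)
  expect_error(otsuThreshold(rep(5, 100)), "degenerate")
})

test_that("Otsu segments a bright disk to within 5 percent of its area", {
  n <- 128
  cx <- 64.5; rad <- 30
  img <- outer(1:n, 1:n, function(i, j)
    ifelse((i - cx)^2 + (j - cx)^2 <= rad^2, 100, 0))
  set.seed(1)
  img <- img + rnorm(n * n, 0, 5)
  mask <- img > otsuThreshold(img)
  expect_equal(sum(mask), pi * rad^2, tolerance = 0.05)
})

test_that("cone profile equals the per-voxel brute-force oracle", {
  set.seed(3)
  geom <- VoxelGeometry(80, 100, 250)  # deliberately anisotropic
  arr <- array(runif(18 * 15 * 10), c(18, 15, 10))
  st <- ImageStack(array(arr, c(dim(arr), 1)), geom, "brush")
  cases <- list(
    list(ctr = c(700, 700, 1200), axis = c(1, 0, 0), ap = 30),
    list(ctr = c(600, 800, 1000), axis = c(-1, 1, 0.5), ap = 45),
    list(ctr = c(750, 750, 1250), axis = c(0, 0, 1), ap = 60))
  for (cs in cases) {
    p <- coneProfile(st, cs$ctr, cs$axis, cs$ap, "brush", binWidthNm = 120)
    o <- oracleConeProfile(arr, geom, cs$ctr, cs$axis, cs$ap, 120)
    expect_equal(p@r, o$r)
    expect_equal(p@count, o$count)
    expect_equal(p@intensity, o$intensity)
  }
})

test_that("background statistics use exactly the outermost tail bins", {
  prof <- makeProfile(seq(50, 5000, by = 50),
                      c(seq(100, 1, length.out = 50), rep(3, 50)))
  bg <- backgroundStats(prof, 50)
  expect_equal(bg$mean, 3)
  expect_equal(bg$sd, 0)
  set.seed(9)
  noise <- rnorm(50, 10, 2)
  prof2 <- makeProfile(seq(50, 5000, by = 50),
                       c(seq(100, 15, length.out = 50), noise))
  bg2 <- backgroundStats(prof2, 50)
  expect_equal(bg2$mean, mean(noise))
  expect_equal(bg2$sd, sd(noise))
  short <- makeProfile(seq(50, 2450, by = 50), rep(1, 49))
  expect_error(backgroundStats(short, 50), "49")
})

test_that("edge detection matches the closed-form 2 sigma crossing of an exponential", {
  # I(r) = 100 exp(-r / 1 um), background mean 0 sd 1:
  # crossing of 2 sigma at r = lambda ln(50) = 3.912 um
  r <- seq(25, 8000, by = 50)
  prof <- makeProfile(r, 100 * exp(-r / 1000))
  edge <- detectBrushEdge(prof, list(mean = 0, sd = 1))
  expect_equal(edge$flag, "ok")
  expect_equal(edge$edgeNm, 1000 * log(50), tolerance = 50 / (1000 * log(50)))
  # below threshold everywhere -> no crossing
  flat <- makeProfile(r, rep(0.5, length(r)))
  expect_equal(detectBrushEdge(flat, list(mean = 0, sd = 1))$flag,
               "no-crossing")
  # step profile: edge within one bin of the step
  step <- makeProfile(r, ifelse(r <= 3000, 50, 0))
  es <- detectBrushEdge(step, list(mean = 0, sd = 1))
  expect_lt(abs(es$edgeNm - 3000), 50)
})

test_that("edge location grows with brush amplitude and height", {
  r <- seq(25, 10000, by = 50)
  bg <- list(mean = 0, sd = 1)
  e1 <- detectBrushEdge(makeProfile(r, 50 * exp(-r / 1000)), bg)$edgeNm
  e2 <- detectBrushEdge(makeProfile(r, 200 * exp(-r / 1000)), bg)$edgeNm
  expect_gt(e2, e1)
  h1 <- detectBrushEdge(makeProfile(r, 100 * exp(-r / 800) *
                                       (r <= 3000)), bg)$edgeNm
  h2 <- detectBrushEdge(makeProfile(r, 100 * exp(-r / 800) *
                                       (r <= 4500)), bg)$edgeNm
  expect_gt(h2, h1)
})

test_that("surface detection finds the marker peak, with radius fallback", {
  r <- seq(25, 6000, by = 50)
  shell <- makeProfile(r, 100 * exp(-(r - 4000)^2 / (2 * 100^2)))
  s <- detectSurface(shell)
  expect_equal(s$flag, "peak")
  expect_lt(abs(s$surfaceNm - 4000), 50)
  flat <- makeProfile(r, rep(1, length(r)))
  sf <- detectSurface(flat, nominalRadiusNm = 4000)
  expect_equal(sf$flag, "fallback-radius")
  expect_equal(sf$surfaceNm, 4000)
  mono <- makeProfile(r, seq(1, 100, length.out = length(r)))
  sm <- detectSurface(mono, nominalRadiusNm = 3500)
  expect_equal(sm$flag, "fallback-radius")
  expect_error(detectSurface(mono), "nominal")
})

test_that("exponential profile fit recovers parameters and rejects background", {
  r <- seq(25, 8000, by = 50)
  y <- 100 * exp(-r / 1500)
  fit <- fitExponentialProfile(makeProfile(r, y), surfaceNm = 0)
  expect_true(fit$converged)
  expect_equal(fit$I0, 100, tolerance = 0.01)
  expect_equal(fit$lambdaNm, 1500, tolerance = 0.01)
  # a profile sitting at the background level has no signal to fit
  flat <- makeProfile(r, rep(3, length(r)))
  fb <- fitExponentialProfile(flat, surfaceNm = 0,
                              bg = list(mean = 3, sd = 1))
  expect_false(fb$converged)
  expect_equal(fb$flag, "insufficient-signal")
})

test_that("decay-length recovery is unbiased over noisy replicates", {
  r <- seq(25, 8000, by = 50)
  set.seed(4)
  lams <- replicate(50, {
    y <- 100 * exp(-r / 1500) + rnorm(length(r), 0, 2)
    fitExponentialProfile(makeProfile(r, y), surfaceNm = 0,
                          edgeNm = 6000)$lambdaNm
  })
  expect_lt(abs(mean(lams) / 1500 - 1), 0.05)
})
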
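# Small, fast geometries are used throughout: the generators are fully
# configurable, so correctness can be checked on miniature stacks.

miniGeom <- VoxelGeometry(100, 100, 100)

test_that("flat-profile limit renders a uniform shell of the right thickness", {
  st <- simulateSphericalBrushStack(heightNm = 2000, lambdaNm = Inf,
    I0 = 100, noiseSd = 0, sphereRadiusNm = 1000, geometry = miniGeom,
    dims = c(80, 80, 80))
  a <- stackData(st, "brush")
  truth <- stackMetadata(st)$truth
  ctr <- truth$centersNm[1, ]
  r <- sqrt(outer(outer((voxelCenters(miniGeom, 80, "x") - ctr[1])^2,
                        (voxelCenters(miniGeom, 80, "y") - ctr[2])^2, "+"),
                  (voxelCenters(miniGeom, 80, "z") - ctr[3])^2, "+"))
  inShell <- r >= 1000 & r <= 3000
  expect_true(all(a[inShell] == 100))
  expect_true(all(a[!inShell] == 0))
})

test_that("clipped spheres are a geometry error and close pairs set the overlap flag", {
  expect_error(simulateSphericalBrushStack(sphereRadiusNm = 1000,
    geometry = miniGeom, dims = c(30, 30, 30),
    centersNm = matrix(c(500, 1500, 1500), 1)), "clipped")
  st <- simulateSphericalBrushStack(heightNm = 500, lambdaNm = 300,
    noiseSd = 0, sphereRadiusNm = 600, geometry = miniGeom,
    dims = c(60, 40, 40),
    centersNm = rbind(c(1500, 2000, 2000), c(3500, 2000, 2000)))
  expect_true(stackMetadata(st)$truth$overlap)
  stFar <- simulateSphericalBrushStack(heightNm = 100, lambdaNm = 300,
    noiseSd = 0, sphereRadiusNm = 600, geometry = miniGeom,
    dims = c(60, 40, 40),
    centersNm = rbind(c(1200, 2000, 2000), c(4600, 2000, 2000)))
  expect_false(stackMetadata(stFar)$truth$overlap)
})

test_that("noiseless spherical stacks are rotationally symmetric across cone axes", {
  st <- simulateSphericalBrushStack(heightNm = 1500, lambdaNm = 800,
    I0 = 100, noiseSd = 0, sphereRadiusNm = 1000, geometry = miniGeom,
    dims = c(70, 70, 70))
  ctr <- stackMetadata(st)$truth$centersNm[1, ]
  p1 <- coneProfile(st, ctr, c(1, 0, 0), 30, "brush")
  p2 <- coneProfile(st, ctr, c(0, -1, 0), 30, "brush")
  p3 <- coneProfile(st, ctr, c(1, 1, 1), 30, "brush")
  # align on common radial bins (near-apex bins may be empty for some
  # axes) before comparing
  cmp <- function(a, b, tol) {
    rs <- intersect(a@r, b@r)
    expect_equal(a@intensity[match(rs, a@r)],
                 b@intensity[match(rs, b@r)], tolerance = tol)
  }
  cmp(p1, p2, 0.05)
  cmp(p1, p3, 0.08)
})

test_that("planar generator: no-brush limit, dextran depletion and determinism", {
  st0 <- simulatePlanarBrushStack(heightNm = 0, lambdaNm = 500,
    noiseSd = 0, substrateZNm = 500, nx = 8, ny = 8, nz = 40)
  p <- axialProfile(st0, "particle")
  aboveIdx <- p@r > 500 + 3 * 200  # a few exclusion widths above substrate
  expect_true(all(p@intensity[aboveIdx] > 0.95 * 100))
  # dextran drops by the configured 50 percent at the substrate
  st <- simulatePlanarBrushStack(heightNm = 2000, lambdaNm = 800,
    noiseSd = 0, substrateZNm = 500, nx = 8, ny = 8, nz = 60,
    dextranDepletion = 0.5)
  d <- axialProfile(st, "dextran")
  iSurf <- which.min(abs(d@r - 550))
  iEdge <- which.min(abs(d@r - 2500))
  expect_equal(d@intensity[iSurf] / d@intensity[iEdge], 0.5,
               tolerance = 0.05)
  a <- simulatePlanarBrushStack(nx = 8, ny = 8, seed = 3)
  b <- simulatePlanarBrushStack(nx = 8, ny = 8, seed = 3)
  expect_identical(stackData(a), stackData(b))
})

test_that("spherical generator is bit-identical under a fixed seed", {
  args <- list(heightNm = 800, lambdaNm = 400, sphereRadiusNm = 800,
               geometry = miniGeom, dims = c(50, 30, 30),
               centersNm = matrix(c(1500, 1500, 1500), 1), seed = 9)
  a <- do.call(simulateSphericalBrushStack, args)
  b <- do.call(simulateSphericalBrushStack, args)
  expect_identical(stackData(a), stackData(b))
})

test_that("trace generator renders exact rectangular pulses and truth ECDs", {
  sim <- simulateNanoporeTrace(1e6, samplingRate = 2e5, baselinePA = 1000,
    noiseSdPA = 0, amplitudePA = 100, dwellPerDaS = 1e-9, seed = 1)
  y <- traceCurrent(sim$trace)
  ev <- sim$events
  expect_equal(nrow(ev), 1)
  expect_equal(ev$durationS, 1e-3)           # 1 MDa -> 1 ms
  expect_equal(min(y), 1000 - 100)
  expect_equal(sum(y == 900), 200)           # exactly 1 ms at 200 kHz
  expect_equal(ev$ecdPAs, 100 * 1e-3)
  # forward-map consistency: module ECD equals generator ECD exactly
  ecd <- eventECD(sim$trace, ev$startIdx, ev$endIdx, 1000)
  expect_equal(ecd, ev$ecdPAs)
})

test_that("empty distributions give a pure baseline and bad durations error", {
  sim <- simulateNanoporeTrace(numeric(0), baselinePA = 500,
                               noiseSdPA = 0)
  expect_true(all(traceCurrent(sim$trace) == 500))
  expect_equal(nrow(sim$events), 0)
  expect_error(simulateNanoporeTrace(100, samplingRate = 2e5,
                                     dwellPerDaS = 1e-9),
               "sampling interval")
})

test_that("biofilm generator: zero density, analytic ellipsoid volume, additivity", {
  s0 <- simulateBiofilmStack(0, nx = 32, ny = 32, nz = 20, seed = 2)
  expect_equal(s0$biovolumeUm3, 0)
  expect_equal(s0$nCells, 0)
  # single ellipsoid with 1 x 1 x 2 um axes vs (4/3) pi a b c
  s1 <- simulateBiofilmStack(0, nx = 40, ny = 40, nz = 20,
    centersNm = matrix(c(2000, 2000, 1500), 1),
    semiAxesNm = c(500, 500, 1000), thetaRad = 0, noiseSd = 0)
  analytic <- 4 / 3 * pi * 0.5 * 0.5 * 1
  expect_equal(s1$biovolumeUm3, analytic, tolerance = 0.05)
  # two disjoint bodies add exactly in voxel counts
  s2 <- simulateBiofilmStack(0, nx = 60, ny = 40, nz = 20,
    centersNm = rbind(c(1500, 2000, 1500), c(4500, 2000, 1500)),
    semiAxesNm = c(500, 500, 1000), thetaRad = c(0, 0), noiseSd = 0)
  expect_equal(s2$biovolumeUm3, 2 * s1$biovolumeUm3)
})
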
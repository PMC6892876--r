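test_that("high-pass filtering removes smooth backgrounds, keeps small bodies", {
  geom <- VoxelGeometry(100, 100, 200)
  const <- ImageStack(array(7, c(40, 40, 12, 1)), geom, "bacteria")
  hp <- highpassStack(const, 2000)
  expect_lt(max(abs(stackData(hp, 1))), 1e-9)
  # linear lateral ramp: interior residual much smaller than the range
  ramp <- array(rep(seq(0, 100, length.out = 40), times = 40 * 12),
                c(40, 40, 12))
  hpR <- highpassStack(ImageStack(array(ramp, c(40, 40, 12, 1)), geom,
                                  "bacteria"), 2000)
  inner <- stackData(hpR, 1)[10:30, 10:30, ]
  expect_lt(max(abs(inner)), 10)
  # small bright body on a sloped background survives with its contrast
  sim <- simulateBiofilmStack(0, nx = 60, ny = 60, nz = 16,
    centersNm = matrix(c(3000, 3000, 1400), 1),
    semiAxesNm = c(500, 500, 800), thetaRad = 0, noiseSd = 0,
    blurSigmaVox = 0, geometry = geom)
  slope <- array(rep(seq(0, 50, length.out = 60), times = 60 * 16),
                 c(60, 60, 16, 1))
  withBg <- ImageStack(stackData(sim$stack) + slope, geom, "bacteria")
  hpB <- stackData(highpassStack(withBg, 2000), 1)
  peak <- max(hpB)
  expect_gt(peak, 0.8 * 100)
  away <- hpB[45:58, 45:58, ]
  expect_lt(max(abs(away)), 0.1 * 100)
  expect_error(highpassStack(const, -1), "> 0")
})

test_that("binarization recovers body volumes and guards empty stacks", {
  sim <- simulateBiofilmStack(0.05, nx = 96, ny = 96, nz = 26, seed = 1)
  hp <- highpassStack(sim$stack, 2000)
  bin <- binarizeStack(hp, 1)
  geom <- voxelGeometry(sim$stack)
  vol <- sum(bin$mask) * voxelVolumeUm3(geom)
  expect_equal(vol, sim$biovolumeUm3, tolerance = 0.1)
  # signal-free noise stack: the noise floor keeps the mask empty
  s0 <- simulateBiofilmStack(0, nx = 96, ny = 96, nz = 26, seed = 2)
  bin0 <- binarizeStack(highpassStack(s0$stack, 2000), 1)
  expect_true(bin0$usedFloor)
  expect_lt(mean(bin0$mask), 0.001)
  # inverted contrast with the polarity flag gives the same mask
  arr <- stackData(hp, 1)
  binInv <- binarizeStack(-arr, polarity = "dark")
  expect_identical(bin$mask, binInv$mask)
  expect_error(binarizeStack(array(3, c(5, 5, 5))), "degenerate")
})

test_that("biovolume is voxel count times voxel volume, with the z band", {
  geom <- VoxelGeometry(100, 100, 470)
  mask <- array(FALSE, c(50, 50, 20))
  mask[sample(length(mask), 1000)] <- TRUE
  while (sum(mask) < 1000) mask[sample(length(mask), 1)] <- TRUE
  bv <- biovolume(mask, geom, bandNm = c(0, 20 * 470))
  expect_equal(bv$totalUm3, sum(mask) * 0.1 * 0.1 * 0.47)
  expect_equal(bv$bandUm3, bv$totalUm3)  # band spanning the whole stack
  # the 5 um default band only counts voxels near the surface
  mask2 <- array(FALSE, c(10, 10, 20))
  mask2[, , 2] <- TRUE    # z centre 705 nm, inside the band
  mask2[, , 15] <- TRUE   # z centre 6815 nm, outside
  bv2 <- biovolume(mask2, geom)
  expect_equal(bv2$totalUm3, 2 * bv2$bandUm3)
  expect_warning(biovolume(mask2, geom, bandNm = c(0, 50000)), "clip")
})

test_that("biovolume is additive over disjoint masks and translation invariant", {
  geom <- VoxelGeometry(100, 100, 200)
  a <- array(FALSE, c(30, 30, 10)); a[3:8, 3:8, 2:4] <- TRUE
  b <- array(FALSE, c(30, 30, 10)); b[20:26, 20:26, 5:8] <- TRUE
  both <- a | b
  band <- c(0, 2000)
  expect_equal(biovolume(both, geom, band)$totalUm3,
               biovolume(a, geom, band)$totalUm3 +
                 biovolume(b, geom, band)$totalUm3)
  shifted <- array(FALSE, c(30, 30, 10)); shifted[13:18, 13:18, 2:4] <- TRUE
  expect_equal(biovolume(shifted, geom, band)$totalUm3,
               biovolume(a, geom, band)$totalUm3)
})

test_that("retention comparison reproduces the percent/fold structure", {
  r <- retentionComparison(1, 100)
  expect_equal(r$percentReduction, 99)
  expect_equal(r$foldRatio, 100)
  eq <- retentionComparison(5, 5)
  expect_equal(eq$percentReduction, 0)
  expect_equal(eq$foldRatio, 1)
  expect_equal(retentionComparison(1, 6)$foldRatio, 6)
  z <- retentionComparison(c(0, 0), 10)
  expect_true(z$infiniteFold)
  expect_equal(z$foldRatio, Inf)
  multi <- retentionComparison(c(2, 4, 6), 100)
  expect_equal(multi$sampleMeanUm3, 4)
  expect_equal(multi$sampleSEMUm3, sd(c(2, 4, 6)) / sqrt(3))
  expect_error(retentionComparison(-1, 10), ">= 0")
})

test_that("cell-count estimation divides by the assumed per-cell volume", {
  expect_equal(estimateCellCount(10, 1)$count, 10)
  expect_equal(estimateCellCount(0)$count, 0)
  expect_error(estimateCellCount(10, 0), "> 0")
  # against generator truth with the body volume as conversion factor
  sim <- simulateBiofilmStack(0.04, nx = 96, ny = 96, nz = 26, seed = 3)
  res <- biofilmBiovolume(sim$stack)
  perCell <- 4 / 3 * pi * 1 * 0.5 * 0.5  # the generator's body volume
  est <- estimateCellCount(res$totalUm3, perCell)$count
  expect_equal(est, sim$nCells, tolerance = 0.15)
})

test_that("the pipeline returns ~zero volume on bacteria-free stacks", {
  s0 <- simulateBiofilmStack(0, nx = 96, ny = 96, nz = 26, seed = 4)
  res <- biofilmBiovolume(s0$stack)
  stackVol <- prod(dim(stackData(s0$stack, 1))) *
    voxelVolumeUm3(voxelGeometry(s0$stack))
  expect_lt(res$totalUm3 / stackVol, 0.001)
})

test_that("measured biovolume increases with seeded surface density", {
  vols <- vapply(c(0.01, 0.05, 0.12), function(dens) {
    mean(vapply(1:2, function(s) {
      sim <- simulateBiofilmStack(dens, nx = 96, ny = 96, nz = 26,
                                  seed = 100 * s + round(1000 * dens))
      biofilmBiovolume(sim$stack)$totalUm3
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(vols) > 0))
})
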
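test_that("count-to-activity calibration matches the hand-worked factor", {
  g <- gridGeometry(c(10L, 10L, 10L), 4.48)
  wl <- array(TRUE, dim = c(10, 10, 10))
  arr <- array(9900 / 999, dim = c(10, 10, 10)); arr[1, 1, 1] <- 100
  # one voxel of 100 counts in a 10000-count liver, LSF 10%, 2 GBq
  act <- calibrateActivity(countImage(arr, g), wl,
                           treatmentRecord(2, 10))
  expect_equal(voxelValues(act)[1, 1, 1], 0.018, tolerance = 1e-12)
  expect_equal(sum(voxelValues(act)), 2 * 0.9, tolerance = 1e-9)
})

test_that("activity is conserved and extrahepatic counts are excluded", {
  g <- gridGeometry(c(8L, 8L, 8L), 4.48)
  wl <- array(FALSE, dim = c(8, 8, 8)); wl[2:7, 2:7, 2:7] <- TRUE
  set.seed(3)
  arr <- array(runif(512, 0, 50), dim = c(8, 8, 8))
  tr <- treatmentRecord(1.7, 8.2)
  expect_warning(act <- calibrateActivity(countImage(arr, g), wl, tr),
                 "outside the whole liver")
  expect_equal(sum(voxelValues(act)), 1.7 * (1 - 8.2 / 100),
               tolerance = 1e-9)
  expect_true(all(voxelValues(act)[!wl] == 0))
  expect_error(
    calibrateActivity(countImage(array(0, dim = c(8, 8, 8)), g), wl, tr),
    "no counts")
})

test_that("cumulated activity integrates the physical decay", {
  g <- gridGeometry(c(2L, 2L, 2L), 4.48)
  zero <- cumulateActivity(activityMap(array(0, dim = c(2, 2, 2)), g))
  expect_true(all(voxelValues(zero) == 0))

  a <- activityMap(array(0.018, dim = c(2, 2, 2)), g)
  cum <- cumulateActivity(a)
  expect_equal(max(voxelValues(cum)), 1.443 * 64.2 * 3600 * 0.018,
               tolerance = 1e-12)
  expect_equal(max(voxelValues(cum)), 6003.1, tolerance = 1e-4)

  doubled <- physicsConstants(halfLifeH = 2 * 64.2)
  expect_equal(voxelValues(cumulateActivity(a, doubled)),
               2 * voxelValues(cum), tolerance = 1e-12)
})

test_that("the local-deposition S-value matches the canonical figures", {
  expect_equal(round(ldmSValue(4.48), 3), 1.603)
  expect_equal(round(ldmSValue(4.48, physicsConstants(voxelDensity = 1)), 3),
               1.651)
  expect_equal(ldmSValue(8.96), ldmSValue(4.48) / 8, tolerance = 1e-12)
})

test_that("local deposition scales cumulated activity and needs cubic voxels", {
  g <- gridGeometry(c(3L, 3L, 3L), 4.48)
  cum <- cumulatedActivityMap(array(0.1, dim = c(3, 3, 3)), g)
  d <- ldmDose(cum)
  expect_equal(max(voxelValues(d)), 0.1603, tolerance = 1e-3)
  expect_true(all(voxelValues(ldmDose(
    cumulatedActivityMap(array(0, dim = c(3, 3, 3)), g))) == 0))

  gAniso <- gridGeometry(c(3L, 3L, 3L), c(4.48, 4.48, 5))
  expect_error(ldmDose(cumulatedActivityMap(array(1, dim = c(3, 3, 3)),
                                            gAniso)), "cubic")
})

test_that("kernel convolution with a delta kernel is the LDM", {
  g <- gridGeometry(c(6L, 6L, 6L), 4.48)
  set.seed(5)
  cum <- cumulatedActivityMap(array(runif(216), dim = c(6, 6, 6)), g)
  expect_identical(voxelValues(dpkDose(cum, deltaKernel(4.48))),
                   voxelValues(ldmDose(cum)))
})

test_that("kernel convolution equals the brute-force oracle", {
  set.seed(17)
  for (rep in 1:4) {
    d <- sample(3:8, 3, replace = TRUE)
    g <- gridGeometry(as.integer(d), 4.48)
    a <- array(runif(prod(d)), dim = d)
    k <- array(runif(27), dim = c(3, 3, 3))
    got <- voxelValues(dpkDose(cumulatedActivityMap(a, g),
                               doseKernel(k, 4.48)))
    want <- bruteConv3d(a, k)
    expect_lt(max(abs(got - want)), 1e-12 * max(want))
  }
})

test_that("uniform activity far from edges sees the full kernel sum", {
  g <- gridGeometry(c(11L, 11L, 11L), 4.48)
  a <- array(0.2, dim = c(11, 11, 11))
  k <- buildDefaultKernel(4.48, seed = 9, nSamples = 5e4)
  dose <- voxelValues(dpkDose(cumulatedActivityMap(a, g), k))
  expect_equal(dose[6, 6, 6], 0.2 * sum(sValues(k)), tolerance = 1e-10)
})

test_that("kernel geometry is validated before convolving", {
  g <- gridGeometry(c(4L, 4L, 4L), 4.48)
  cum <- cumulatedActivityMap(array(1, dim = c(4, 4, 4)), g)
  expect_error(dpkDose(cum, deltaKernel(4.0)), "spacing")
  expect_error(doseKernel(array(1, dim = c(2, 3, 3)), 4.48), "odd")
  expect_error(doseKernel(array(-1, dim = c(1, 1, 1)), 4.48),
               "non-negative")
})

test_that("the default kernel is energy-closed, leaky and deterministic", {
  pc <- physicsConstants()
  k <- buildDefaultKernel(4.48, pc, seed = 21, nSamples = 1e5)
  massKg <- 4.48^3 / 1000 * pc@voxelDensity / 1000
  closure <- sum(sValues(k)) * massKg / (0.9267 * 1.6022e-13 * 1e9)
  expect_gte(closure, 0.98)
  expect_lte(closure, 1.001)
  c0 <- (dim(sValues(k)) + 1L) %/% 2L
  expect_lt(sValues(k)[c0[1], c0[2], c0[3]], ldmSValue(4.48, pc))
  k2 <- buildDefaultKernel(4.48, pc, seed = 21, nSamples = 1e5)
  expect_identical(sValues(k), sValues(k2))
})

test_that("kernel text files round-trip and reject malformed input", {
  k <- buildDefaultKernel(4.48, seed = 2, nSamples = 2e4)
  f <- tempfile(fileext = ".kern")
  writeKernel(k, f)
  k2 <- readKernel(f)
  expect_equal(sValues(k2), sValues(k), tolerance = 1e-11)
  expect_equal(k2@spacingMM, k@spacingMM)

  bad <- tempfile(); writeLines(c("3 3 nonsense", "1 2 3"), bad)
  expect_error(readKernel(bad), "line 1")
  short <- tempfile(); writeLines(c("3 3 3 4.48", "1 2 3"), short)
  expect_error(readKernel(short), "data lines")
  neg <- tempfile()
  writeLines(c("1 1 1 4.48", "-5"), neg)
  expect_error(readKernel(neg), "non-negative")
})

test_that("energy is conserved by both voxel dose engines", {
  pc <- physicsConstants()
  g <- gridGeometry(c(20L, 20L, 20L), 4.48)
  wl <- array(FALSE, dim = c(20, 20, 20)); wl[8:13, 8:13, 8:13] <- TRUE
  arr <- array(0, dim = c(20, 20, 20)); arr[wl] <- 30
  tr <- treatmentRecord(1.4, 5)
  cum <- cumulateActivity(calibrateActivity(countImage(arr, g), wl, tr), pc)
  massKg <- voxelVolumeML(g) * pc@voxelDensity / 1000
  expectedJ <- 0.9267 * 1.6022e-13 * 1e9 * 1.443 * 64.2 * 3600 * 1.4 * 0.95
  ldmJ <- sum(voxelValues(ldmDose(cum, pc))) * massKg
  expect_equal(ldmJ, expectedJ, tolerance = 1e-9)

  # DPK: kernel support fits inside the padding, so no energy is clipped
  k <- buildDefaultKernel(4.48, pc, seed = 4, nSamples = 5e4)
  dpkJ <- sum(voxelValues(dpkDose(cum, k))) * massKg
  expect_equal(dpkJ, expectedJ, tolerance = 1e-3)
})
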
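test_that("the pipeline inverts a noiseless, unblurred phantom", {
  ph <- generatePhantom(twoTumorSpec(tnrs = c(1.0, 3.0)))
  ti <- tnrI(ph@counts, ph@vois)
  expect_equal(unname(ti), c(1, 3), tolerance = 1e-12)
  expect_equal(tnr(ph@counts, ph@vois), ph@trueTnr, tolerance = 1e-12)
  expect_equal(lsfFromPlanar(ph@planar), ph@spec@lsfPercent,
               tolerance = 1e-12)
})

test_that("compartment doses match closed forms on a clean phantom", {
  pc <- physicsConstants("consistent")
  ph <- generatePhantom(twoTumorSpec(tnrs = c(1.4, 2.6)))
  tr <- treatmentRecord(1.3, 5.8)
  cf <- phantomClosedFormDoses(ph, tr, pc)
  rep <- compartmentDoses(ph@counts, ph@vois, tr, constants = pc)
  expect_equal(rep@doseTLGy, cf$doseTLGy, tolerance = 1e-10)
  expect_equal(rep@doseNLtGy, cf$doseNLtGy, tolerance = 1e-10)
  expect_equal(rep@doseNLwGy, cf$doseNLwGy, tolerance = 1e-10)
  expect_equal(unname(rep@perTumor$doseGy), unname(cf$doseTiGy),
               tolerance = 1e-10)

  # in consistent mode the LDM voxel means agree with MTPM exactly
  ld <- ldmDose(cumulateActivity(
    calibrateActivity(ph@counts, ph@vois, tr), pc), pc)
  vm <- voxelMeanDoses(ld, ph@vois)
  expect_equal(unname(vm[c("T1", "T2")]), unname(cf$doseTiGy),
               tolerance = 1e-10)
})

test_that("a fixed seed makes noisy phantoms bit-reproducible", {
  s <- twoTumorSpec(poissonNoise = TRUE, seed = 99L)
  a <- generatePhantom(s); b <- generatePhantom(s)
  expect_identical(voxelValues(a@counts), voxelValues(b@counts))
  expect_identical(a@planar@anterior, b@planar@anterior)
  c <- generatePhantom(twoTumorSpec(poissonNoise = TRUE, seed = 100L))
  expect_false(identical(voxelValues(a@counts), voxelValues(c@counts)))
})

test_that("Poisson noise leaves the TNR estimate unbiased", {
  ests <- vapply(1:30, function(s) {
    ph <- generatePhantom(twoTumorSpec(tnrs = c(2, 2), poissonNoise = TRUE,
                                       seed = s))
    tnr(ph@counts, ph@vois)
  }, numeric(1))
  # ~0.9e5 liver counts per phantom: the mean estimate should sit within
  # a few standard errors of the prescribed ratio
  expect_lt(abs(mean(ests) - 2), 4 * sd(ests) / sqrt(length(ests)))
  expect_lt(sd(ests), 0.1)
})

test_that("blur alone preserves the MTPM/PM aggregation identity", {
  ph <- generatePhantom(twoTumorSpec(tnrs = c(1.2, 3.5), psfSigmaMM = 8))
  # blur moves counts across VOI boundaries, so ratios shift ...
  expect_false(isTRUE(all.equal(tnr(ph@counts, ph@vois), ph@trueTnr)))
  # ... but the volume-weighted MTPM mean still equals the PM dose
  tr <- treatmentRecord(1.1, 3)
  rep <- compartmentDoses(ph@counts, ph@vois, tr)
  vol <- rep@perTumor$volumeML
  expect_equal(sum(rep@perTumor$doseGy * vol) / sum(vol), rep@doseTLGy,
               tolerance = 1e-10)
})

test_that("tumors must stay inside the planning target volume", {
  ctr <- 32L * 6 / 2
  tum <- data.frame(name = "T1", xMM = ctr - 80, yMM = ctr, zMM = ctr,
                    radiusMM = 12, tnr = 2)
  s <- phantomSpec(shape = rep(32L, 3), spacingMM = 6, tumors = tum,
                   liverSemiAxesMM = c(85, 70, 60), ptv = "half")
  expect_error(generatePhantom(s), "outside the PTV")
})

test_that("cohorts are reproducible and respect the requested ranges", {
  mk <- function() phantomCohort(14, nTumorsRange = c(1L, 4L),
                                 volumeRangeML = c(0.6, 351), seed = 7)
  ca <- mk(); cb <- mk()
  expect_length(ca, 14L)
  expect_identical(lapply(ca, function(s) s@tumors),
                   lapply(cb, function(s) s@tumors))
  for (s in ca) {
    nt <- nrow(s@tumors)
    expect_true(nt >= 1 && nt <= 4)
    vols <- 4 / 3 * pi * s@tumors$radiusMM^3 / 1000
    expect_true(all(vols >= 0.6 - 1e-9 & vols <= 351 + 1e-9))
    expect_true(all(s@tumors$tnr >= 0.6 & s@tumors$tnr <= 4.1))
    expect_true(s@lsfPercent >= 1.4 && s@lsfPercent <= 10.7)
  }
  expect_error(phantomCohort(0), ">= 1")
  expect_error(phantomCohort(2, tnrRange = c(3, 1)), "low <= high")
})
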
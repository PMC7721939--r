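test_that("uptake ratios are concentration ratios", {
  v <- cubeVois()
  g <- geometry(v)
  uniform <- countImage(array(2.5, dim = c(10, 10, 10)), g)
  expect_equal(tnr(uniform, v), 1.0)
  expect_equal(tnrI(uniform, v, "T1"), 1.0)

  # TL: 8 voxels totalling 40 counts (5/voxel); rest 2.5/voxel
  arr <- array(2.5, dim = c(10, 10, 10)); arr[4:5, 4:5, 4:5] <- 5
  expect_equal(tnr(countImage(arr, g), v), 2.0)

  # single tumor: per-tumor ratio equals the aggregated one exactly
  expect_identical(tnrI(countImage(arr, g), v, "T1"),
                   tnr(countImage(arr, g), v))
})

test_that("per-tumor ratios resolve heterogeneous tumors", {
  g <- gridGeometry(c(10L, 10L, 10L), 4.48)
  wl <- array(TRUE, dim = c(10, 10, 10))
  t1 <- array(FALSE, dim = c(10, 10, 10)); t1[1:10, 1, 1] <- TRUE
  t2 <- array(FALSE, dim = c(10, 10, 10)); t2[1:10, 3, 1] <- TRUE
  v <- voiSet(wl, tumors = list(T1 = t1, T2 = t2), geom = g)
  # NLt concentration 1 count/voxel; tumors total 10 and 30 over 10 voxels
  arr <- array(1, dim = c(10, 10, 10)); arr[t1] <- 1; arr[t2] <- 3
  ti <- tnrI(countImage(arr, g), v)
  expect_equal(unname(ti), c(1, 3))
  # volume-weighted mean of TNRi equals TNR (algebraic identity)
  vol <- voiVolumesML(v)
  expect_equal(sum(ti * vol[c("T1", "T2")]) / vol[["TL"]],
               tnr(countImage(arr, g), v), tolerance = 1e-14)
})

test_that("uptake ratio errors on degenerate inputs", {
  v <- cubeVois()
  cold <- array(0, dim = c(10, 10, 10)); cold[4:5, 4:5, 4:5] <- 1
  expect_error(tnr(countImage(cold, geometry(v)), v), "no counts")
})

test_that("partition-model doses reproduce the worked clinical example", {
  # lobar treatment: 0.6 GBq, 10.7% shunt, TNR 1.2, 18 mL tumor, 410 mL NLt
  dTL <- pmDoseTL(0.6, 10.7, 1.2, 18, 410)
  expect_equal(round(dTL), 74)
  dNLt <- pmDoseNLt(0.6, 10.7, 1.2, 18, 410)
  expect_equal(dNLt, dTL / 1.2, tolerance = 1e-12)
  expect_equal(dNLt, 61.7, tolerance = 0.01)
  expect_equal(rescaleNLw(dNLt, 410, 1434), 17.6, tolerance = 0.01)
})

test_that("partition-model limits and hand-computed cases hold", {
  expect_equal(pmDoseTL(1, 0, 2, 100, 900), 90.31, tolerance = 1e-3)
  # TNR = 1, LSF = 0: uniform liver, dose = 49.67 A / (M_TL + M_NLt)
  expect_equal(pmDoseTL(1, 0, 1, 100, 900), 49.67 / 1.0, tolerance = 1e-12)
  # very hot tumor starves the normal liver
  expect_lt(pmDoseNLt(1, 0, 1e9, 100, 900), 1e-6)
  # rescaling: no-op when volumes agree; 1/3 for a 3x larger liver
  expect_identical(rescaleNLw(60, 500, 500), 60)
  expect_equal(rescaleNLw(60, 500, 1500), 20)
  expect_error(rescaleNLw(60, 500, 400), "smaller")
})

test_that("multi-tumor doses collapse to PM and honor cold tumors", {
  expect_equal(mtpmDoseTi(0.6, 10.7, 1.2, 1.2, 18, 410),
               pmDoseTL(0.6, 10.7, 1.2, 18, 410))
  expect_identical(mtpmDoseTi(0.6, 10.7, 1.2, 0, 18, 410), 0)
})

test_that("PM energy balance and dose ratios hold to machine precision", {
  set.seed(11)
  for (i in 1:50) {
    A <- runif(1, 0.3, 3); lsf <- runif(1, 0, 30); tnrV <- runif(1, 0.3, 5)
    vTL <- runif(1, 5, 600); vNLt <- runif(1, 200, 1800)
    dTL <- pmDoseTL(A, lsf, tnrV, vTL, vNLt)
    dNLt <- pmDoseNLt(A, lsf, tnrV, vTL, vNLt)
    expect_equal(dTL / dNLt, tnrV, tolerance = 1e-12)
    energy <- vTL / 1000 * dTL + vNLt / 1000 * dNLt
    expect_equal(energy, 49.67 * A * (1 - lsf / 100), tolerance = 1e-12)
  }
})

test_that("volume-weighted MTPM mean equals the PM aggregated dose", {
  specs <- phantomCohort(8, shape = c(24L, 24L, 24L), spacingMM = 10,
                         liverSemiAxesMM = c(95, 85, 75),
                         volumeRangeML = c(5, 150), seed = 42)
  tr <- treatmentRecord(1.2, 4)
  for (s in specs) {
    ph <- generatePhantom(s)
    rep <- compartmentDoses(ph@counts, ph@vois, tr, method = "MTPM")
    vol <- rep@perTumor$volumeML
    expect_equal(sum(rep@perTumor$doseGy * vol) / sum(vol), rep@doseTLGy,
                 tolerance = 1e-10)
  }
})

test_that("COV of per-tumor ratios uses the sample SD", {
  expect_equal(covTnri(c(3, 3, 3)), 0)
  expect_equal(covTnri(c(2, 4)), 47.14, tolerance = 1e-3)
  expect_equal(covTnri(c(1, 1, 4)), 86.60, tolerance = 1e-3)
  expect_error(covTnri(2), "at least two")
  expect_error(covTnri(c(-1, 1)), "mean")
})

test_that("dose reports carry per-tumor structure and export cleanly", {
  ph <- generatePhantom(twoTumorSpec(tnrs = c(1.5, 3)))
  tr <- treatmentRecord(1.5, 6.1)
  pm <- compartmentDoses(ph@counts, ph@vois, tr, method = "PM")
  expect_true(all(pm@perTumor$doseGy == pm@doseTLGy))
  expect_true(is.na(pm@covTnriPercent))

  mt <- compartmentDoses(ph@counts, ph@vois, tr, method = "MTPM")
  expect_true(is.finite(mt@covTnriPercent))
  expect_equal(mt@doseTLGy, pm@doseTLGy)       # aggregated dose is shared
  expect_equal(nrow(as.data.frame(mt)), 5L)    # TL, NLt, NLw + 2 tumors

  csv <- tempfile(fileext = ".csv"); json <- tempfile(fileext = ".json")
  writeDoseReport(mt, csvPath = csv, jsonPath = json)
  tab <- read.csv(csv)
  expect_named(tab, c("compartment", "volume_mL", "TNRi", "D_mean_Gy",
                      "method"))
  parsed <- jsonlite::read_json(json)
  expect_equal(parsed$D_mean_TL_Gy, mt@doseTLGy, tolerance = 1e-9)
})
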
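#' Tumor-to-normal-liver uptake ratios
#'
#' `tnr()` is the aggregated tumor-to-normal-liver activity concentration
#' ratio: the count concentration (total counts / volume) of the aggregated
#' tumor TL divided by that of the target normal liver NLt. `tnrI()` is the
#' same ratio for an individual tumor; with `tumor = NULL` it returns the
#' ratio for every tumor as a named vector.
#'
#' The volume-weighted mean of the per-tumor ratios equals the aggregated
#' ratio — an algebraic identity, since both share the NLt denominator.
#'
#' @param counts a [CountImage-class] (attenuation-corrected SPECT counts).
#' @param vois a [VoiSet-class] on the same grid.
#' @param tumor tumor name, or `NULL` for all tumors.
#' @return a numeric scalar (`tnr`) or named numeric vector (`tnrI`).
#' @examples
#' g <- gridGeometry(c(10L, 10L, 10L), 4.48)
#' wl <- array(TRUE, dim = c(10, 10, 10))
#' t1 <- array(FALSE, dim = c(10, 10, 10)); t1[4:5, 4:5, 4:5] <- TRUE
#' v <- voiSet(wl, tumors = list(T1 = t1), geom = g)
#' img <- countImage(array(1, dim = c(10, 10, 10)), g)
#' tnr(img, v)   # uniform counts: 1
#' @export
tnr <- function(counts, vois) {
  conc <- maskConcentrations(counts, vois)
  conc$tl / conc$nlt
}

#' @rdname tnr
#' @export
tnrI <- function(counts, vois, tumor = NULL) {
  conc <- maskConcentrations(counts, vois)
  vv <- voxelVolumeML(geometry(vois))
  nms <- if (is.null(tumor)) tumorNames(vois) else tumor
  out <- vapply(nms, function(nm) {
    m <- tumorMasks(vois)[[nm]]
    if (is.null(m))
      y90Stop("y90_missing_voi", "no tumor named '%s'", nm)
    if (!sum(m)) y90Stop("y90_empty_voi", "tumor '%s' mask is empty", nm)
    (sum(voxelValues(counts)[m]) / (sum(m) * vv)) / conc$nlt
  }, numeric(1))
  if (!is.null(tumor) && length(tumor) == 1L) unname(out) else out
}

# shared concentration bookkeeping; errors on degenerate inputs
maskConcentrations <- function(counts, vois) {
  if (!sameGeometry(geometry(counts), geometry(vois)))
    y90Stop("y90_geometry_mismatch",
            "counts and VOI set are on different grids")
  tl <- tlMask(vois); nlt <- nltMask(vois)
  if (!sum(tl)) y90Stop("y90_empty_voi", "aggregated tumor TL is empty")
  if (!sum(nlt)) y90Stop("y90_empty_voi", "target normal liver NLt is empty")
  vv <- voxelVolumeML(geometry(vois))
  cNlt <- sum(voxelValues(counts)[nlt])
  if (cNlt <= 0)
    y90Stop("y90_no_counts",
            "no counts in target normal liver; uptake ratio undefined")
  list(tl = sum(voxelValues(counts)[tl]) / (sum(tl) * vv),
       nlt = cNlt / (sum(nlt) * vv))
}

#' Partition-model mean doses
#'
#' The MIRD three-compartment partition model (PM). All of the administered
#' Y-90 activity that does not shunt to the lungs decays within the target
#' liver; it splits between the aggregated tumor TL and the target normal
#' liver NLt according to their masses and the uptake ratio TNR:
#' \deqn{D_{TL} = \frac{49.67 \cdot A (1 - LSF/100) \cdot TNR}
#'                     {M_{TL} \cdot TNR + M_{NLt}}}
#' with `pmDoseNLt()` the same expression without the TNR numerator (so
#' `D_TL / D_NLt = TNR` exactly), masses in kg obtained from the volumes at
#' the compartment density. `rescaleNLw()` converts the NLt dose to the
#' whole normal liver by the mass ratio `M_NLt / M_NLw`.
#'
#' @param activityGBq administered Y-90 activity, GBq.
#' @param lsfPercent lung shunt fraction, percent, in [0, 100).
#' @param tnr aggregated uptake ratio (> 0).
#' @param vTLmL,vNLtmL,vNLwmL compartment volumes, mL.
#' @param dNLtGy target-normal-liver mean dose, Gy.
#' @param constants a [PhysicsConstants-class].
#' @return mean absorbed dose in Gy.
#' @examples
#' pmDoseTL(0.6, 10.7, 1.2, 18, 410)     # ~74 Gy
#' pmDoseNLt(0.6, 10.7, 1.2, 18, 410)    # ~61.7 Gy
#' @export
pmDoseTL <- function(activityGBq, lsfPercent, tnr, vTLmL, vNLtmL,
                     constants = physicsConstants()) {
  mtpmDoseTi(activityGBq, lsfPercent, tnr, tnrI = tnr, vTLmL, vNLtmL,
             constants)
}

#' @rdname pmDoseTL
#' @export
pmDoseNLt <- function(activityGBq, lsfPercent, tnr, vTLmL, vNLtmL,
                      constants = physicsConstants()) {
  mtpmDoseTi(activityGBq, lsfPercent, tnr, tnrI = 1, vTLmL, vNLtmL,
             constants)
}

#' @rdname pmDoseTL
#' @export
rescaleNLw <- function(dNLtGy, vNLtmL, vNLwmL) {
  assertScalar(dNLtGy, "dNLtGy", lower = 0)
  assertScalar(vNLtmL, "vNLtmL", lower = 0, openLower = TRUE)
  assertScalar(vNLwmL, "vNLwmL", lower = 0, openLower = TRUE)
  if (vNLwmL < vNLtmL)
    y90Stop("y90_invalid_argument",
            "whole normal liver (%g mL) smaller than target normal liver (%g mL)",
            vNLwmL, vNLtmL)
  dNLtGy * vNLtmL / vNLwmL
}

#' Multi-tumor partition-model dose for one tumor
#'
#' The (n + 2)-compartment extension of the partition model: each tumor is
#' its own compartment with its individual uptake ratio TNRi in the
#' numerator, while the denominator keeps the aggregated TNR — so the
#' activity split between tumor and normal liver is unchanged and the
#' volume-weighted mean of the per-tumor doses equals the PM aggregated
#' dose exactly. With `tnrI = tnr` this collapses to [pmDoseTL()]; with
#' `tnrI = 1` to [pmDoseNLt()].
#'
#' @inheritParams pmDoseTL
#' @param tnrI individual tumor uptake ratio (>= 0).
#' @return mean absorbed dose to the tumor, Gy.
#' @export
mtpmDoseTi <- function(activityGBq, lsfPercent, tnr, tnrI, vTLmL, vNLtmL,
                       constants = physicsConstants()) {
  assertScalar(activityGBq, "activityGBq", lower = 0, openLower = TRUE)
  assertScalar(lsfPercent, "lsfPercent", lower = 0, upper = 100,
               openUpper = TRUE)
  assertScalar(tnr, "tnr", lower = 0, openLower = TRUE)
  assertScalar(tnrI, "tnrI", lower = 0)
  assertScalar(vTLmL, "vTLmL", lower = 0, openLower = TRUE)
  assertScalar(vNLtmL, "vNLtmL", lower = 0, openLower = TRUE)
  rho <- constants@compartmentDensity
  mTL <- vTLmL * rho / 1000       # kg
  mNLt <- vNLtmL * rho / 1000
  constants@energyPerGBqJ * activityGBq * (1 - lsfPercent / 100) * tnrI /
    (mTL * tnr + mNLt)
}

#' Coefficient of variation of per-tumor uptake ratios
#'
#' `100 * SD / mean` of the individual tumor uptake ratios, quantifying
#' inter-tumor heterogeneity. The SD is the sample (n - 1) standard
#' deviation.
#'
#' @param tnrIValues numeric vector of per-tumor ratios (length >= 2).
#' @return the COV in percent.
#' @examples
#' covTnri(c(2, 4))      # 47.1
#' @export
covTnri <- function(tnrIValues) {
  if (length(tnrIValues) < 2L)
    y90Stop("y90_invalid_argument",
            "COV(TNRi) needs at least two tumors (got %d)",
            length(tnrIValues))
  m <- mean(tnrIValues)
  if (m == 0) y90Stop("y90_invalid_argument", "COV undefined: mean TNRi is 0")
  100 * stats::sd(tnrIValues) / m
}

#' Compartmental dose report
#'
#' Runs the full compartmental dosimetry for a count image, VOI set and
#' treatment record: uptake ratios from the image, mean doses to the
#' aggregated tumor, target normal liver and whole normal liver, and —
#' for `method = "MTPM"` — an individual mean dose per tumor with the COV
#' of the per-tumor ratios. For `method = "PM"` every tumor is assigned the
#' aggregated-tumor dose. Doses are kept at full precision; rounding to
#' integer Gy is a printing concern.
#'
#' @param counts a [CountImage-class].
#' @param vois a [VoiSet-class].
#' @param treatment a [TreatmentRecord-class].
#' @param method `"MTPM"` (default) or `"PM"`.
#' @param constants a [PhysicsConstants-class].
#' @return a [CompartmentDoseReport-class].
#' @seealso [writeDoseReport()] for CSV/JSON export.
#' @export
compartmentDoses <- function(counts, vois, treatment,
                             method = c("MTPM", "PM"),
                             constants = physicsConstants()) {
  method <- match.arg(method)
  vol <- voiVolumesML(vois)
  aggTnr <- tnr(counts, vois)
  perTnr <- tnrI(counts, vois)
  A <- treatment@activityGBq; lsf <- treatment@lsfPercent
  dTL <- pmDoseTL(A, lsf, aggTnr, vol[["TL"]], vol[["NLt"]], constants)
  dNLt <- pmDoseNLt(A, lsf, aggTnr, vol[["TL"]], vol[["NLt"]], constants)
  dNLw <- rescaleNLw(dNLt, vol[["NLt"]], vol[["NLw"]])
  nms <- tumorNames(vois)
  doseTi <- if (method == "PM") rep(dTL, length(nms)) else
    vapply(perTnr, function(ti)
      mtpmDoseTi(A, lsf, aggTnr, ti, vol[["TL"]], vol[["NLt"]], constants),
      numeric(1))
  cov <- if (method == "MTPM" && length(nms) >= 2L) covTnri(perTnr)
         else NA_real_
  new("CompartmentDoseReport", method = method, doseTLGy = dTL,
      doseNLtGy = dNLt, doseNLwGy = dNLw,
      perTumor = data.frame(tumor = nms, volumeML = unname(vol[nms]),
                            tnrI = unname(perTnr),
                            doseGy = unname(doseTi),
                            stringsAsFactors = FALSE),
      tnr = aggTnr, covTnriPercent = cov)
}

setMethod("show", "CompartmentDoseReport", function(object) {
  cat(sprintf("%s dose report (TNR %.2f%s)\n", object@method, object@tnr,
              if (is.finite(object@covTnriPercent))
                sprintf(", COV(TNRi) %.0f%%", object@covTnriPercent)
              else ""))
  cat(sprintf("  D_mean TL  %6.0f Gy\n  D_mean NLt %6.1f Gy\n  D_mean NLw %6.1f Gy\n",
              round(object@doseTLGy), object@doseNLtGy, object@doseNLwGy))
  pt <- object@perTumor
  for (i in seq_len(nrow(pt)))
    cat(sprintf("  %-6s %8.1f mL  TNRi %5.2f  %6.0f Gy\n", pt$tumor[i],
                pt$volumeML[i], pt$tnrI[i], round(pt$doseGy[i])))
})

#' @describeIn compartmentDoses flatten a report to one row per compartment
#'   (name, volume mL, TNRi, mean dose Gy, method).
#' @param x a `CompartmentDoseReport`.
#' @param row.names,optional,... ignored (S3 compatibility).
#' @export
as.data.frame.CompartmentDoseReport <- function(x, row.names = NULL,
                                                optional = FALSE, ...) {
  pt <- x@perTumor
  data.frame(
    compartment = c("TL", "NLt", "NLw", pt$tumor),
    volumeML = c(NA, NA, NA, pt$volumeML),
    tnrI = c(x@tnr, NA, NA, pt$tnrI),
    doseGy = c(x@doseTLGy, x@doseNLtGy, x@doseNLwGy, pt$doseGy),
    method = x@method, stringsAsFactors = FALSE)
}

#' Export a compartmental dose report
#'
#' Writes a [CompartmentDoseReport-class] as CSV (one row per
#' compartment/tumor, units in the column names) and/or JSON.
#'
#' @param report a [CompartmentDoseReport-class].
#' @param csvPath,jsonPath output paths (either may be `NULL`).
#' @return the report, invisibly.
#' @export
writeDoseReport <- function(report, csvPath = NULL, jsonPath = NULL) {
  df <- as.data.frame(report)
  names(df) <- c("compartment", "volume_mL", "TNRi", "D_mean_Gy", "method")
  if (!is.null(csvPath)) utils::write.csv(df, csvPath, row.names = FALSE)
  if (!is.null(jsonPath)) {
    obj <- list(method = report@method, TNR = report@tnr,
                COV_TNRi_percent = report@covTnriPercent,
                D_mean_TL_Gy = report@doseTLGy,
                D_mean_NLt_Gy = report@doseNLtGy,
                D_mean_NLw_Gy = report@doseNLwGy,
                per_tumor = report@perTumor)
    jsonlite::write_json(obj, jsonPath, auto_unbox = TRUE, digits = NA,
                         na = "null", dataframe = "rows")
  }
  invisible(report)
}
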
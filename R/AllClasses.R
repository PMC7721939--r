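#' @import methods
NULL

#' Voxel grid geometry
#'
#' Shape and voxel spacing of a 3-D image grid. The voxel volume in mL is
#' derived from the spacing and never stored. Coordinates are 0-based array
#' indices; world placement is carried only through the NIfTI affine on I/O
#' and plays no role in any dose calculation.
#'
#' @slot shape integer vector (nx, ny, nz).
#' @slot spacingMM positive voxel spacing in mm per axis.
#' @export
setClass("GridGeometry",
  slots = c(shape = "integer", spacingMM = "numeric"))

setValidity("GridGeometry", function(object) {
  if (length(object@shape) != 3L || any(object@shape < 1L))
    return("shape must be three positive integers")
  if (length(object@spacingMM) != 3L || any(!is.finite(object@spacingMM)) ||
      any(object@spacingMM <= 0))
    return("spacingMM must be three positive finite values")
  TRUE
})

#' Scalar voxel images
#'
#' `ScalarImage` is the virtual parent of all per-voxel images: counts
#' (`CountImage`), Y-90 activity in GBq (`ActivityMap`), cumulated activity
#' in GBq·s (`CumulatedActivityMap`) and absorbed dose in Gy (`DoseMap`).
#' All carry a [GridGeometry-class] and a numeric array of matching shape
#' with non-negative finite values.
#'
#' @slot geometry a [GridGeometry-class].
#' @slot values numeric array, dimensions equal to `shape(geometry)`.
#' @aliases CountImage-class ActivityMap-class CumulatedActivityMap-class
#'   DoseMap-class
#' @export
setClass("ScalarImage",
  representation("VIRTUAL", geometry = "GridGeometry", values = "array"))

setValidity("ScalarImage", function(object) {
  d <- dim(object@values)
  shp <- object@geometry@shape
  if (length(d) != 3L || !all(d == shp))
    return(sprintf("values dimensions (%s) do not match geometry shape (%s)",
                   paste(d, collapse = "x"), paste(shp, collapse = "x")))
  if (!is.numeric(object@values)) return("values must be numeric")
  if (any(!is.finite(object@values))) return("values must be finite")
  if (any(object@values < 0)) return("values must be non-negative")
  TRUE
})

#' @export
setClass("CountImage", contains = "ScalarImage")
#' @export
setClass("ActivityMap", contains = "ScalarImage")
#' @export
setClass("CumulatedActivityMap", contains = "ScalarImage")
#' @export
setClass("DoseMap", contains = "ScalarImage")

#' Volume-of-interest set
#'
#' Binary voxel masks for the whole liver (WL), the planning target volume
#' (PTV) and individual tumors T_i, all on one grid. The derived masks —
#' aggregated tumor TL (union of the T_i), target normal liver NLt
#' (PTV minus TL) and whole normal liver NLw (WL minus TL) — are always
#' recomputed from the stored masks by [tlMask()], [nltMask()] and
#' [nlwMask()], so they can never go stale.
#'
#' Invariants enforced at construction: each tumor lies inside the PTV, the
#' PTV lies inside the WL, and tumors are pairwise disjoint.
#'
#' @slot geometry a [GridGeometry-class].
#' @slot wl,ptv logical arrays.
#' @slot tumors named list of logical arrays, one per tumor.
#' @export
setClass("VoiSet",
  slots = c(geometry = "GridGeometry", wl = "array", ptv = "array",
            tumors = "list"))

setValidity("VoiSet", function(object) {
  shp <- object@geometry@shape
  chk <- function(m) is.logical(m) && length(dim(m)) == 3L && all(dim(m) == shp)
  if (!chk(object@wl) || !chk(object@ptv))
    return("WL and PTV must be logical arrays on the VoiSet geometry")
  if (length(object@tumors) < 1L)
    return("at least one tumor mask is required")
  if (is.null(names(object@tumors)) || anyDuplicated(names(object@tumors)) ||
      any(!nzchar(names(object@tumors))))
    return("tumor masks must have unique non-empty names")
  if (!all(vapply(object@tumors, chk, logical(1))))
    return("every tumor mask must be a logical array on the VoiSet geometry")
  if (any(object@ptv & !object@wl))
    return(sprintf("PTV extends outside WL by %d voxel(s)",
                   sum(object@ptv & !object@wl)))
  for (nm in names(object@tumors)) {
    out <- sum(object@tumors[[nm]] & !object@ptv)
    if (out > 0)
      return(sprintf("tumor '%s' extends outside the PTV by %d voxel(s)",
                     nm, out))
  }
  if (length(object@tumors) > 1L) {
    tot <- Reduce(`+`, lapply(object@tumors, function(m) m * 1L))
    if (any(tot > 1L))
      return(sprintf("tumor masks overlap in %d voxel(s)", sum(tot > 1L)))
  }
  TRUE
})

#' Physical constants for Y-90 dosimetry
#'
#' The constants entering the compartmental and voxel dose equations.
#' The defaults are the figures used throughout clinical Y-90 planning:
#' 49.67 J of absorbed beta energy per GBq of fully decayed Y-90, physical
#' half-life 64.2 h, mean beta energy 0.9267 MeV per disintegration,
#' soft-tissue voxel density 1.03 g/mL and compartment density 1 g/mL.
#'
#' These printed constants are mutually inconsistent at the third decimal:
#' 0.9267 MeV integrated over all decays gives 49.52 J/GBq, not 49.67.
#' `mode = "paper"` keeps every constant as printed (so uniform-activity
#' voxel and compartment doses differ by a fixed ~3.3 percent).
#' `mode = "consistent"` derives the voxel beta-energy constant from
#' `energyPerGBqJ` and uses the compartment density for voxels, making the
#' local deposition method agree exactly with the partition models on
#' uniform activity; useful for validation.
#'
#' @slot energyPerGBqJ absorbed energy per unit administered activity, J/GBq.
#' @slot halfLifeH physical half-life, hours.
#' @slot meanBetaMeV mean beta energy per disintegration, MeV.
#' @slot voxelDensity tissue density used for voxel masses, g/mL.
#' @slot compartmentDensity tissue density used for compartment masses, g/mL.
#' @slot mode `"paper"` or `"consistent"`.
#' @export
setClass("PhysicsConstants",
  slots = c(energyPerGBqJ = "numeric", halfLifeH = "numeric",
            meanBetaMeV = "numeric", voxelDensity = "numeric",
            compartmentDensity = "numeric", mode = "character"))

setValidity("PhysicsConstants", function(object) {
  vals <- c(object@energyPerGBqJ, object@halfLifeH, object@meanBetaMeV,
            object@voxelDensity, object@compartmentDensity)
  if (length(vals) != 5L || any(!is.finite(vals)) || any(vals <= 0))
    return("all physical constants must be positive finite scalars")
  if (!object@mode %in% c("paper", "consistent"))
    return("mode must be 'paper' or 'consistent'")
  TRUE
})

#' Treatment record
#'
#' The prescription needed for dose calculation: administered Y-90 activity,
#' lung shunt fraction and treatment approach.
#'
#' @slot activityGBq administered Y-90 activity, GBq (> 0).
#' @slot lsfPercent lung shunt fraction, percent, in [0, 100).
#' @slot approach one of `"whole_liver"`, `"lobar"`, `"segmental"`.
#' @export
setClass("TreatmentRecord",
  slots = c(activityGBq = "numeric", lsfPercent = "numeric",
            approach = "character"))

setValidity("TreatmentRecord", function(object) {
  if (!isTRUE(is.finite(object@activityGBq)) || object@activityGBq <= 0)
    return("activityGBq must be a positive number")
  if (!isTRUE(is.finite(object@lsfPercent)) || object@lsfPercent < 0 ||
      object@lsfPercent >= 100)
    return("lsfPercent must lie in [0, 100)")
  if (!object@approach %in% c("whole_liver", "lobar", "segmental"))
    return("approach must be whole_liver, lobar or segmental")
  TRUE
})

#' Planar scintigraphy study
#'
#' Anterior and posterior 2-D count images with lung and whole-liver ROI
#' masks, as used for the lung shunt fraction.
#'
#' @slot anterior,posterior numeric count matrices of equal dimensions.
#' @slot rois named list of logical matrices (must include `lung` and
#'   `liver`).
#' @slot pixelSpacingMM pixel spacing in mm (2 values); informational only.
#' @export
setClass("PlanarStudy",
  slots = c(anterior = "matrix", posterior = "matrix", rois = "list",
            pixelSpacingMM = "numeric"))

setValidity("PlanarStudy", function(object) {
  d <- dim(object@anterior)
  if (!all(dim(object@posterior) == d))
    return("anterior and posterior images must have the same dimensions")
  if (any(object@anterior < 0) || any(object@posterior < 0))
    return("planar counts must be non-negative")
  if (is.null(names(object@rois)) || !length(object@rois))
    return("rois must be a named list of logical matrices")
  ok <- vapply(object@rois,
               function(m) is.logical(m) && all(dim(m) == d), logical(1))
  if (!all(ok)) return("every ROI must be a logical matrix matching the views")
  if (length(object@pixelSpacingMM) != 2L || any(object@pixelSpacingMM <= 0))
    return("pixelSpacingMM must be two positive values")
  TRUE
})

#' Voxel S-value kernel
#'
#' A cubic dose-point kernel: absorbed dose in a target voxel per unit
#' cumulated activity in a source voxel, in Gy/(GBq·s), for every source to
#' target voxel offset. Dimensions are odd on every axis so the kernel has a
#' central (self-dose) element; the spacing must match the grid it is
#' convolved with.
#'
#' @slot sValues non-negative numeric array with odd dimensions.
#' @slot spacingMM voxel spacing of the kernel grid, mm.
#' @export
setClass("DoseKernel",
  slots = c(sValues = "array", spacingMM = "numeric"))

setValidity("DoseKernel", function(object) {
  d <- dim(object@sValues)
  if (length(d) != 3L || any(d %% 2L == 0L))
    return("kernel must be a 3-D array with odd dimensions on every axis")
  if (any(!is.finite(object@sValues)) || any(object@sValues < 0))
    return("kernel S-values must be finite and non-negative")
  if (length(object@spacingMM) != 3L || any(object@spacingMM <= 0))
    return("spacingMM must be three positive values")
  TRUE
})

#' Cumulative dose-volume histogram
#'
#' The fraction of a VOI receiving at least each dose level. Starts at 1 at
#' 0 Gy and is non-increasing.
#'
#' @slot doseEdgesGy increasing dose grid from 0 past the maximum dose.
#' @slot volumeFraction fraction of VOI voxels with dose >= each edge.
#' @slot voiName label of the VOI.
#' @slot nVoxels number of voxels in the VOI.
#' @export
setClass("DvhCurve",
  slots = c(doseEdgesGy = "numeric", volumeFraction = "numeric",
            voiName = "character", nVoxels = "integer"))

setValidity("DvhCurve", function(object) {
  if (length(object@doseEdgesGy) != length(object@volumeFraction))
    return("doseEdgesGy and volumeFraction lengths differ")
  if (is.unsorted(object@doseEdgesGy, strictly = TRUE))
    return("doseEdgesGy must be strictly increasing")
  v <- object@volumeFraction
  if (any(v < 0) || any(v > 1) || is.unsorted(rev(v)))
    return("volumeFraction must be non-increasing within [0, 1]")
  if (abs(v[1] - 1) > 1e-12) return("curve must start at 1 at dose 0")
  TRUE
})

#' Compartmental dose report
#'
#' Mean absorbed doses per compartment from the partition model (PM) or the
#' multi-tumor partition model (MTPM), with the per-tumor uptake ratios that
#' produced them. For PM every per-tumor dose equals the aggregated-tumor
#' dose; for MTPM with two or more tumors the coefficient of variation of
#' the per-tumor uptake ratios is reported.
#'
#' @slot method `"PM"` or `"MTPM"`.
#' @slot doseTLGy,doseNLtGy,doseNLwGy mean doses, Gy.
#' @slot perTumor data.frame with columns tumor, volumeML, tnrI, doseGy.
#' @slot tnr aggregated tumor-to-normal-liver concentration ratio.
#' @slot covTnriPercent COV of the per-tumor ratios, percent (NA for a
#'   single tumor or for PM).
#' @export
setClass("CompartmentDoseReport",
  slots = c(method = "character", doseTLGy = "numeric", doseNLtGy = "numeric",
            doseNLwGy = "numeric", perTumor = "data.frame", tnr = "numeric",
            covTnriPercent = "numeric"))

setValidity("CompartmentDoseReport", function(object) {
  if (!object@method %in% c("PM", "MTPM")) return("method must be PM or MTPM")
  dose <- c(object@doseTLGy, object@doseNLtGy, object@doseNLwGy,
            object@perTumor$doseGy)
  if (any(!is.finite(dose)) || any(dose < 0))
    return("doses must be finite and non-negative")
  need <- c("tumor", "volumeML", "tnrI", "doseGy")
  if (!all(need %in% names(object@perTumor)))
    return("perTumor must have columns tumor, volumeML, tnrI, doseGy")
  if (object@method == "PM" &&
      any(abs(object@perTumor$doseGy - object@doseTLGy) >
          1e-9 * max(1, object@doseTLGy)))
    return("for PM every per-tumor dose must equal the TL dose")
  if (object@method == "MTPM" && nrow(object@perTumor) >= 2L &&
      !isTRUE(is.finite(object@covTnriPercent)))
    return("MTPM with >= 2 tumors must report covTnriPercent")
  TRUE
})

#' Method-agreement report
#'
#' Bland-Altman summary of paired dose measurements: bias (mean of
#' differences), sample SD of differences, limits of agreement at bias
#' plus/minus 2 SD, the percentage of points beyond the limits, plus Pearson
#' correlation and Lin concordance of the paired values.
#'
#' @slot biasGy mean of x - y, Gy.
#' @slot sdDiffGy sample SD of the differences, Gy.
#' @slot limitsGy bias -/+ 2 SD, Gy.
#' @slot percentBeyondLimits percent of pairs outside the limits.
#' @slot pearsonR Pearson correlation of x and y.
#' @slot linCCC Lin concordance correlation coefficient.
#' @slot n number of pairs.
#' @export
setClass("AgreementReport",
  slots = c(biasGy = "numeric", sdDiffGy = "numeric", limitsGy = "numeric",
            percentBeyondLimits = "numeric", pearsonR = "numeric",
            linCCC = "numeric", n = "integer"))

setValidity("AgreementReport", function(object) {
  if (length(object@limitsGy) != 2L)
    return("limitsGy must hold lower and upper limits")
  if (abs(mean(object@limitsGy) - object@biasGy) >
      1e-9 * max(1, abs(object@biasGy), abs(object@limitsGy)))
    return("limits must be symmetric about the bias")
  if (object@percentBeyondLimits < 0 || object@percentBeyondLimits > 100)
    return("percentBeyondLimits must lie in [0, 100]")
  TRUE
})

#' Synthetic phantom specification
#'
#' Parameters of the synthetic SPECT-like liver phantom: an ellipsoidal
#' liver, a planning target volume (the whole liver or a half-plane cut),
#' spherical tumors with prescribed per-tumor uptake ratios, a normal-liver
#' count concentration, a prescribed lung shunt fraction for the matching
#' planar study, optional Gaussian PSF blur and optional Poisson noise.
#'
#' @slot geometry a [GridGeometry-class].
#' @slot liverCenterMM,liverSemiAxesMM ellipsoid center and semi-axes, mm.
#' @slot ptv `"whole"` or `"half"` (half-plane cut at the liver center,
#'   keeping the +x side).
#' @slot tumors data.frame with columns name, xMM, yMM, zMM, radiusMM, tnr.
#' @slot nlConcentration normal-liver counts per mL.
#' @slot lsfPercent prescribed lung shunt fraction, percent.
#' @slot psfSigmaMM Gaussian PSF sigma, mm (0 = no blur).
#' @slot poissonNoise whether to Poisson-sample the counts.
#' @slot seed RNG seed used for noise.
#' @export
setClass("PhantomSpec",
  slots = c(geometry = "GridGeometry", liverCenterMM = "numeric",
            liverSemiAxesMM = "numeric", ptv = "character",
            tumors = "data.frame", nlConcentration = "numeric",
            lsfPercent = "numeric", psfSigmaMM = "numeric",
            poissonNoise = "logical", seed = "integer"))

setValidity("PhantomSpec", function(object) {
  if (!object@ptv %in% c("whole", "half"))
    return("ptv must be 'whole' or 'half'")
  need <- c("name", "xMM", "yMM", "zMM", "radiusMM", "tnr")
  if (!all(need %in% names(object@tumors)) || nrow(object@tumors) < 1L)
    return("tumors must have >= 1 row with columns name,xMM,yMM,zMM,radiusMM,tnr")
  if (any(object@tumors$radiusMM <= 0)) return("tumor radii must be positive")
  if (any(object@tumors$tnr < 0)) return("tumor uptake ratios must be >= 0")
  if (object@nlConcentration < 0) return("nlConcentration must be >= 0")
  if (object@lsfPercent < 0 || object@lsfPercent >= 100)
    return("lsfPercent must lie in [0, 100)")
  if (object@psfSigmaMM < 0) return("psfSigmaMM must be >= 0")
  TRUE
})

#' Phantom with ground truth
#'
#' A generated phantom: its VOI set and count image, a consistent planar
#' study, and the ground-truth uptake ratios. On a noiseless, unblurred
#' phantom the estimation pipeline recovers every truth value exactly.
#'
#' @slot spec the generating [PhantomSpec-class].
#' @slot vois a [VoiSet-class].
#' @slot counts a [CountImage-class].
#' @slot planar a [PlanarStudy-class] consistent with the prescribed lung
#'   shunt fraction.
#' @slot trueTnr aggregated uptake ratio implied by the prescription.
#' @slot trueTnrI named per-tumor uptake ratios as prescribed.
#' @export
setClass("PhantomTruth",
  slots = c(spec = "PhantomSpec", vois = "VoiSet", counts = "CountImage",
            planar = "PlanarStudy", trueTnr = "numeric", trueTnrI = "numeric"))
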
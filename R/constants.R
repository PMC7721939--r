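#' Physical constants
#'
#' Constructor for [PhysicsConstants-class]. Defaults are the standard
#' Y-90 planning figures; see the class documentation for the meaning of
#' `mode`. In `mode = "consistent"` the voxel density defaults to the
#' compartment density and the voxel beta-energy constant is derived from
#' `energyPerGBqJ`, so that voxel and compartment dosimetry agree exactly
#' on uniform activity.
#'
#' @param mode `"paper"` (constants as printed) or `"consistent"`.
#' @param energyPerGBqJ absorbed energy per unit activity, J/GBq.
#' @param halfLifeH Y-90 half-life in hours.
#' @param meanBetaMeV mean beta energy per disintegration, MeV.
#' @param voxelDensity voxel tissue density, g/mL. Default 1.03 in paper
#'   mode (the value consistent with the canonical 1.603 Gy/(GBq·s) voxel
#'   S-value at 4.48 mm); defaults to `compartmentDensity` in consistent
#'   mode.
#' @param compartmentDensity compartment tissue density, g/mL (1 g/mL:
#'   volumes in liters convert directly to masses in kg).
#' @return a [PhysicsConstants-class] object.
#' @examples
#' physicsConstants()
#' physicsConstants("consistent")
#' @export
physicsConstants <- function(mode = c("paper", "consistent"),
                             energyPerGBqJ = 49.67,
                             halfLifeH = 64.2,
                             meanBetaMeV = 0.9267,
                             voxelDensity = NULL,
                             compartmentDensity = 1.0) {
  mode <- match.arg(mode)
  if (is.null(voxelDensity))
    voxelDensity <- if (mode == "paper") 1.03 else compartmentDensity
  new("PhysicsConstants", energyPerGBqJ = energyPerGBqJ,
      halfLifeH = halfLifeH, meanBetaMeV = meanBetaMeV,
      voxelDensity = voxelDensity, compartmentDensity = compartmentDensity,
      mode = mode)
}

# J/(GBq·s): energy deposited per second per GBq of activity.
# paper mode: <E_beta> MeV/decay x 1.6022e-13 J/MeV x 1e9 decay/(s GBq);
# consistent mode: back-derived from the integrated 49.67 J/GBq so that
# E * 1.443 * T1/2 == energyPerGBqJ exactly.
betaEnergyJPerGBqS <- function(constants) {
  if (constants@mode == "paper")
    constants@meanBetaMeV * 1.6022e-13 * 1e9
  else
    constants@energyPerGBqJ / (1.443 * halfLifeSeconds(constants))
}

halfLifeSeconds <- function(constants) constants@halfLifeH * 3600

setMethod("show", "PhysicsConstants", function(object) {
  cat(sprintf(paste0(
    "PhysicsConstants (mode '%s')\n",
    "  energy per GBq:       %.4g J/GBq\n",
    "  half-life:            %.4g h\n",
    "  mean beta energy:     %.4g MeV/decay\n",
    "  voxel density:        %.4g g/mL\n",
    "  compartment density:  %.4g g/mL\n"),
    object@mode, object@energyPerGBqJ, object@halfLifeH,
    object@meanBetaMeV, object@voxelDensity, object@compartmentDensity))
})

#' Treatment record
#'
#' Constructor for [TreatmentRecord-class]: the administered Y-90 activity,
#' the lung shunt fraction and the treatment approach.
#'
#' @param activityGBq administered Y-90 activity, GBq.
#' @param lsfPercent lung shunt fraction in percent, in [0, 100).
#' @param approach `"whole_liver"`, `"lobar"` or `"segmental"`.
#' @return a [TreatmentRecord-class] object.
#' @examples
#' treatmentRecord(0.6, lsfPercent = 10.7)
#' @export
treatmentRecord <- function(activityGBq, lsfPercent = 0,
                            approach = c("lobar", "whole_liver",
                                         "segmental")) {
  approach <- match.arg(approach)
  new("TreatmentRecord", activityGBq = as.numeric(activityGBq),
      lsfPercent = as.numeric(lsfPercent), approach = approach)
}

setMethod("show", "TreatmentRecord", function(object) {
  cat(sprintf("TreatmentRecord: %.3g GBq Y-90, LSF %.3g%%, %s approach\n",
              object@activityGBq, object@lsfPercent, object@approach))
})
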
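#' Count-to-activity calibration
#'
#' Converts SPECT-like counts to per-voxel Y-90 activity with the
#' patient-specific self-calibration factor: every count inside the whole
#' liver gets the same GBq-per-count factor such that the liver total
#' equals the administered activity reduced by the lung shunt,
#' `A_voxel = C_voxel * (1 - LSF/100) * A / C_WL`.
#' Counts outside the whole liver carry no activity; if present they are
#' zeroed with a warning (no extrahepatic dose model is provided).
#' Identical Tc-99m-MAA and Y-90 microsphere biodistributions are assumed.
#'
#' @param counts a [CountImage-class].
#' @param wlMask logical whole-liver mask on the same grid (or a
#'   [VoiSet-class], whose WL mask is used).
#' @param treatment a [TreatmentRecord-class].
#' @return an [ActivityMap-class]; its sum over the liver equals
#'   `A * (1 - LSF/100)`.
#' @export
calibrateActivity <- function(counts, wlMask, treatment) {
  if (is(wlMask, "VoiSet")) wlMask <- wlMask@wl
  geom <- geometry(counts)
  checkMask(wlMask, geom, "WL mask")
  v <- voxelValues(counts)
  cWL <- sum(v[wlMask])
  if (cWL <= 0)
    y90Stop("y90_no_counts", "no counts inside the whole-liver mask")
  outside <- sum(v[!wlMask])
  if (outside > 0)
    y90Warn("%.4g counts (%.2f%%) outside the whole liver are excluded from dosimetry",
            outside, 100 * outside / (outside + cWL))
  act <- array(0, dim = dim(v))
  act[wlMask] <- v[wlMask] *
    (1 - treatment@lsfPercent / 100) * treatment@activityGBq / cWL
  activityMap(act, geom)
}

#' Cumulated activity
#'
#' Time-integrated activity per voxel for permanently trapped microspheres:
#' no biological clearance, so the integral of the mono-exponential decay
#' is `1.443 * T1/2 * A_voxel`, with the half-life in seconds. No
#' time-activity curve fitting is involved.
#'
#' @param activity an [ActivityMap-class] (GBq per voxel).
#' @param constants a [PhysicsConstants-class] supplying the half-life.
#' @return a [CumulatedActivityMap-class] (GBq·s per voxel).
#' @examples
#' g <- gridGeometry(c(2L, 2L, 2L), 4.48)
#' a <- activityMap(array(0.018, dim = c(2, 2, 2)), g)
#' max(voxelValues(cumulateActivity(a)))   # 1.443 * 64.2 h * 0.018 ~ 6003 GBq.s
#' @export
cumulateActivity <- function(activity, constants = physicsConstants()) {
  cumulatedActivityMap(
    voxelValues(activity) * 1.443 * halfLifeSeconds(constants),
    geometry(activity))
}

#' Local-deposition voxel S-value
#'
#' The self-dose S-value used by the local deposition method: the mean beta
#' energy per disintegration, converted to J/(GBq·s), divided by the mass
#' of one cubic voxel at the voxel tissue density. At the 4.48 mm voxel and
#' 1.03 g/mL this is the canonical 1.603 Gy/(GBq·s).
#'
#' @param voxelSideMM cubic voxel side, mm.
#' @param constants a [PhysicsConstants-class].
#' @return the S-value, Gy/(GBq·s).
#' @examples
#' ldmSValue(4.48)   # 1.603
#' @export
ldmSValue <- function(voxelSideMM, constants = physicsConstants()) {
  assertScalar(voxelSideMM, "voxelSideMM", lower = 0, openLower = TRUE)
  massKg <- voxelSideMM^3 / 1000 * constants@voxelDensity / 1000
  betaEnergyJPerGBqS(constants) / massKg
}

#' Local deposition method dose map
#'
#' Absorbed dose assuming all beta energy is deposited in the emitting
#' voxel: the cumulated-activity map times the scalar [ldmSValue()].
#' Requires cubic voxels (an anisotropic self-dose S-value is undefined).
#'
#' @param cumulated a [CumulatedActivityMap-class].
#' @param constants a [PhysicsConstants-class].
#' @return a [DoseMap-class] in Gy.
#' @export
ldmDose <- function(cumulated, constants = physicsConstants()) {
  sp <- spacingMM(cumulated)
  if (max(abs(sp - sp[1])) > 1e-6 * sp[1])
    y90Stop("y90_anisotropic_grid",
            "local deposition needs cubic voxels; got %s mm",
            paste(format(sp), collapse = " x "))
  doseMap(voxelValues(cumulated) * ldmSValue(sp[1], constants),
          geometry(cumulated))
}

#' Dose-point-kernel convolution dose map
#'
#' Absorbed dose accounting for beta transport to neighboring voxels:
#' the 3-D discrete convolution of the cumulated-activity map with a voxel
#' S-value kernel, with zero padding outside the grid (energy carried past
#' the grid edge is lost; in practice the liver lies in the interior).
#' The kernel spacing must match the grid spacing. Convolving with a delta
#' kernel whose central element is [ldmSValue()] reproduces [ldmDose()]
#' exactly.
#'
#' @param cumulated a [CumulatedActivityMap-class].
#' @param kernel a [DoseKernel-class] on the same voxel spacing.
#' @return a [DoseMap-class] in Gy.
#' @export
dpkDose <- function(cumulated, kernel) {
  sp <- spacingMM(cumulated)
  if (max(abs(kernel@spacingMM - sp) / sp) > 1e-6)
    y90Stop("y90_kernel_mismatch",
            "kernel spacing (%s mm) does not match grid spacing (%s mm)",
            paste(format(kernel@spacingMM), collapse = " x "),
            paste(format(sp), collapse = " x "))
  doseMap(convolve3dZeroPad(voxelValues(cumulated), kernel@sValues),
          geometry(cumulated))
}

# Direct 3-D convolution with zero padding: for every kernel offset, shift
# the activity array and accumulate. Deterministic and exact to rounding;
# cost is (kernel voxels) x (grid voxels), fine for beta-range kernels.
convolve3dZeroPad <- function(a, k) {
  d <- dim(a); kd <- dim(k); h <- (kd - 1L) %/% 2L
  out <- array(0, dim = d)
  idx <- function(n, s) {            # target/source ranges for shift s
    t0 <- max(1L, 1L + s); t1 <- min(n, n + s)
    if (t0 > t1) NULL else list(t = t0:t1, s = (t0 - s):(t1 - s))
  }
  for (dz in -h[3]:h[3]) {
    iz <- idx(d[3], dz); if (is.null(iz)) next
    for (dy in -h[2]:h[2]) {
      iy <- idx(d[2], dy); if (is.null(iy)) next
      for (dx in -h[1]:h[1]) {
        w <- k[h[1] + 1L + dx, h[2] + 1L + dy, h[3] + 1L + dz]
        if (w == 0) next
        ix <- idx(d[1], dx); if (is.null(ix)) next
        out[ix$t, iy$t, iz$t] <- out[ix$t, iy$t, iz$t] +
          w * a[ix$s, iy$s, iz$s]
      }
    }
  }
  out
}

#' Mean dose, total energy and per-VOI summaries of a dose map
#'
#' `voxelMeanDoses()` reports the mean absorbed dose of a [DoseMap-class]
#' within each VOI of a [VoiSet-class] (TL, NLt, NLw and each tumor),
#' mirroring the compartmental report so voxel and compartment methods can
#' be compared per VOI.
#'
#' @param dose a [DoseMap-class].
#' @param vois a [VoiSet-class] on the same grid.
#' @return named numeric vector of mean doses in Gy.
#' @export
voxelMeanDoses <- function(dose, vois) {
  if (!sameGeometry(geometry(dose), geometry(vois)))
    y90Stop("y90_geometry_mismatch", "dose map and VOI set grids differ")
  v <- voxelValues(dose)
  masks <- c(list(TL = tlMask(vois), NLt = nltMask(vois),
                  NLw = nlwMask(vois)), tumorMasks(vois))
  vapply(masks, function(m) mean(v[m]), numeric(1))
}
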
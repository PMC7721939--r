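#' Cumulative dose-volume histogram
#'
#' Builds the cumulative DVH of a dose map within a VOI: the fraction of
#' VOI voxels receiving at least each dose level, evaluated on a regular
#' dose grid from 0 to just past the maximum dose. Endpoint metrics
#' ([dvhDx()], [dvhVx()]) are computed from the raw voxel doses, not from
#' the binned curve.
#'
#' @param dose a [DoseMap-class].
#' @param voi logical mask on the dose-map grid (non-empty).
#' @param binWidthGy dose bin width in Gy (default 0.5).
#' @param voiName label stored in the curve.
#' @return a [DvhCurve-class].
#' @export
computeDvh <- function(dose, voi, binWidthGy = 0.5, voiName = "VOI") {
  d <- voiDoses(dose, voi)
  assertScalar(binWidthGy, "binWidthGy", lower = 0, openLower = TRUE)
  edges <- seq(0, max(d) + binWidthGy, by = binWidthGy)
  frac <- vapply(edges, function(e) mean(d >= e), numeric(1))
  new("DvhCurve", doseEdgesGy = edges, volumeFraction = frac,
      voiName = voiName, nVoxels = length(d))
}

voiDoses <- function(dose, voi) {
  checkMask(voi, geometry(dose), "VOI")
  if (!sum(voi)) y90Stop("y90_empty_voi", "VOI mask is empty")
  voxelValues(dose)[voi]
}

#' DVH endpoint metrics
#'
#' `dvhDx()` is the minimum dose received by the hottest x percent of the
#' VOI — the largest dose d such that at least x percent of the VOI voxels
#' receive at least d. It is rank-based without interpolation: voxel doses
#' are sorted in descending order and the value at rank `ceiling(x*N/100)`
#' is returned, so results are bit-exactly reproducible. `dvhVx()` is the
#' percentage of the VOI receiving at least a dose threshold, and
#' `meanDose()` the arithmetic mean voxel dose in the VOI.
#'
#' By construction `dvhVx(dose, voi, dvhDx(dose, voi, x)) >= x`, and the
#' endpoints are monotone: D5 >= D25 >= D50 >= D70 >= D95.
#'
#' @param dose a [DoseMap-class].
#' @param voi logical mask (non-empty).
#' @param x percent of the VOI, in (0, 100].
#' @param thresholdGy dose threshold in Gy (>= 0).
#' @return Gy for `dvhDx()`/`meanDose()`; percent for `dvhVx()`.
#' @examples
#' g <- gridGeometry(c(2L, 1L, 1L), 4.48)
#' dm <- doseMap(array(c(10, 20), dim = c(2, 1, 1)), g)
#' voi <- array(TRUE, dim = c(2, 1, 1))
#' dvhDx(dm, voi, 50)    # 20
#' dvhDx(dm, voi, 95)    # 10
#' dvhVx(dm, voi, 15)    # 50
#' @export
dvhDx <- function(dose, voi, x) {
  assertScalar(x, "x", lower = 0, upper = 100, openLower = TRUE)
  d <- voiDoses(dose, voi)
  sort(d, decreasing = TRUE)[ceiling(x * length(d) / 100)]
}

#' @rdname dvhDx
#' @export
dvhVx <- function(dose, voi, thresholdGy) {
  assertScalar(thresholdGy, "thresholdGy", lower = 0)
  100 * mean(voiDoses(dose, voi) >= thresholdGy)
}

#' @rdname dvhDx
#' @export
meanDose <- function(dose, voi) mean(voiDoses(dose, voi))

#' DVH endpoint panel
#'
#' The endpoint set used for method comparison: D5, D25, D50, D70, D95
#' (Gy), the mean dose, and V20/V100 (percent of the VOI receiving at
#' least 20/100 Gy).
#'
#' @inheritParams dvhDx
#' @return named numeric vector.
#' @export
dvhEndpoints <- function(dose, voi) {
  c(D5_Gy = dvhDx(dose, voi, 5), D25_Gy = dvhDx(dose, voi, 25),
    D50_Gy = dvhDx(dose, voi, 50), D70_Gy = dvhDx(dose, voi, 70),
    D95_Gy = dvhDx(dose, voi, 95), Dmean_Gy = meanDose(dose, voi),
    V20_percent = dvhVx(dose, voi, 20),
    V100_percent = dvhVx(dose, voi, 100))
}

#' @describeIn computeDvh curve as a two-column data.frame
#'   (dose_Gy, volume_fraction).
#' @param x a `DvhCurve`.
#' @param row.names,optional,... ignored (S3 compatibility).
#' @export
as.data.frame.DvhCurve <- function(x, row.names = NULL, optional = FALSE,
                                   ...) {
  data.frame(dose_Gy = x@doseEdgesGy, volume_fraction = x@volumeFraction)
}

#' @describeIn computeDvh write the curve as two-column CSV.
#' @param curve a [DvhCurve-class].
#' @param path output CSV path.
#' @export
writeDvh <- function(curve, path) {
  utils::write.csv(as.data.frame(curve), path, row.names = FALSE)
  invisible(path)
}

setMethod("show", "DvhCurve", function(object) {
  cat(sprintf("DvhCurve '%s': %d voxels, max dose %.1f Gy, %d bins\n",
              object@voiName, object@nVoxels,
              max(object@doseEdgesGy), length(object@doseEdgesGy)))
})
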
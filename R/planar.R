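#' Planar scintigraphy study
#'
#' Constructor for [PlanarStudy-class]: matching anterior and posterior
#' count images plus lung and whole-liver ROI masks for the lung shunt
#' fraction calculation.
#'
#' @param anterior,posterior numeric count matrices of equal size.
#' @param rois named list of logical matrices; must contain `lung` and
#'   `liver`.
#' @param pixelSpacingMM pixel spacing in mm (informational).
#' @return a [PlanarStudy-class] object.
#' @export
planarStudy <- function(anterior, posterior, rois, pixelSpacingMM = 4.8) {
  if (length(pixelSpacingMM) == 1L)
    pixelSpacingMM <- rep(pixelSpacingMM, 2L)
  new("PlanarStudy", anterior = as.matrix(anterior),
      posterior = as.matrix(posterior), rois = rois,
      pixelSpacingMM = as.numeric(pixelSpacingMM))
}

setMethod("show", "PlanarStudy", function(object) {
  cat(sprintf("PlanarStudy: %s pixels, ROIs: %s\n",
              paste(dim(object@anterior), collapse = " x "),
              paste(names(object@rois), collapse = ", ")))
})

#' Geometric-mean counts in a planar ROI
#'
#' The geometric mean of the total counts registered within an ROI on the
#' anterior and posterior views: `sqrt(sum_ant * sum_post)`. The mean is
#' taken of the ROI totals, not pixel-wise.
#'
#' @param study a [PlanarStudy-class].
#' @param roi name of an ROI present in the study.
#' @return total geometric-mean counts (numeric scalar).
#' @examples
#' ant <- matrix(4, 8, 8); post <- matrix(1, 8, 8)
#' roi <- matrix(TRUE, 8, 8)
#' st <- planarStudy(ant, post, list(lung = roi, liver = roi))
#' geometricMeanCounts(st, "lung")  # sqrt(256 * 64) = 128
#' @export
geometricMeanCounts <- function(study, roi) {
  if (!roi %in% names(study@rois))
    y90Stop("y90_missing_roi", "ROI '%s' not present (have: %s)", roi,
            paste(names(study@rois), collapse = ", "))
  m <- study@rois[[roi]]
  sqrt(sum(study@anterior[m]) * sum(study@posterior[m]))
}

#' Lung shunt fraction
#'
#' `lsfPercent()` computes the lung shunt fraction from geometric-mean lung
#' and whole-liver counts, `100 * C_lung / (C_lung + C_WL)`.
#' `lsfFromPlanar()` applies it to a [PlanarStudy-class], taking the
#' geometric means of the `lung` and `liver` ROI totals. No attenuation or
#' scatter correction is applied to the planar views.
#'
#' The result is scale-invariant (common rescaling of both inputs cancels)
#' and increases monotonically with the lung counts.
#'
#' @param cLung,cWL geometric-mean counts in the lung and whole-liver ROIs
#'   (non-negative; not both zero).
#' @param study a [PlanarStudy-class] with `lung` and `liver` ROIs.
#' @return the lung shunt fraction in percent, within [0, 100].
#' @examples
#' lsfPercent(2000, 18000)  # 10
#' @export
lsfPercent <- function(cLung, cWL) {
  assertScalar(cLung, "cLung", lower = 0)
  assertScalar(cWL, "cWL", lower = 0)
  if (cLung == 0 && cWL == 0)
    y90Stop("y90_no_counts", "no counts in lung or liver ROI")
  100 * cLung / (cLung + cWL)
}

#' @rdname lsfPercent
#' @export
lsfFromPlanar <- function(study) {
  lsfPercent(geometricMeanCounts(study, "lung"),
             geometricMeanCounts(study, "liver"))
}
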
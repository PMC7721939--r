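#' Bland-Altman agreement analysis
#'
#' Agreement between two methods measured on the same units: differences
#' `x - y`, their mean (bias), the sample SD of the differences, limits of
#' agreement at bias +/- 2 SD (2, not 1.96), and the percentage of pairs
#' beyond the limits. Pearson correlation and Lin concordance of the
#' paired values are included in the report.
#'
#' The bracketed interval printed alongside the bias in comparison tables
#' is these limits of agreement (the bias +/- 2 SD span), not a confidence
#' interval of the bias; [agreementTable()] emits both, labeled.
#'
#' @param x,y paired measurements (equal length >= 2, finite), Gy.
#' @return an [AgreementReport-class].
#' @examples
#' blandAltman(c(1, 2, 3), c(2, 2, 2))   # diffs -1, 0, 1: bias 0, limits +/- 2
#' @export
blandAltman <- function(x, y) {
  checkPairs(x, y)
  d <- x - y
  bias <- mean(d)
  s <- stats::sd(d)
  lim <- bias + c(-2, 2) * s
  beyond <- if (s == 0) 0 else 100 * mean(d < lim[1] | d > lim[2])
  new("AgreementReport", biasGy = bias, sdDiffGy = s, limitsGy = lim,
      percentBeyondLimits = beyond,
      pearsonR = if (stats::sd(x) > 0 && stats::sd(y) > 0)
        stats::cor(x, y) else NA_real_,
      linCCC = linCCC(x, y), n = length(x))
}

checkPairs <- function(x, y) {
  if (length(x) != length(y) || length(x) < 2L)
    y90Stop("y90_invalid_argument",
            "paired series must have equal length >= 2 (got %d and %d)",
            length(x), length(y))
  if (any(!is.finite(x)) || any(!is.finite(y)))
    y90Stop("y90_invalid_argument", "paired series must be finite")
  invisible(NULL)
}

#' Lin concordance correlation coefficient
#'
#' Concordance between paired measurements:
#' `2 s_xy / (s_x^2 + s_y^2 + (mean(x) - mean(y))^2)` with population
#' (1/n) moments. Equals 1 only for exact agreement and never exceeds the
#' absolute Pearson correlation; location or scale shifts lower it.
#' Two identical constant series give 1 by convention; a constant series
#' against a varying one is degenerate and errors.
#'
#' @param x,y paired measurements (equal length >= 2, finite).
#' @return the coefficient, in [-1, 1].
#' @examples
#' linCCC(1:3, 2:4)   # 4/7: perfect correlation, shifted location
#' @export
linCCC <- function(x, y) {
  checkPairs(x, y)
  n <- length(x)
  mx <- mean(x); my <- mean(y)
  sx2 <- sum((x - mx)^2) / n; sy2 <- sum((y - my)^2) / n
  sxy <- sum((x - mx) * (y - my)) / n
  if (sx2 == 0 && sy2 == 0) {
    if (mx == my) return(1)
    y90Stop("y90_degenerate", "both series constant with different means")
  }
  2 * sxy / (sx2 + sy2 + (mx - my)^2)
}

#' Normalized mean square error between dose maps
#'
#' `100 * sum((test - reference)^2) / sum(reference^2)` over the voxels of
#' a VOI, in percent. By convention the local-deposition map serves as the
#' reference when comparing the two voxel methods.
#'
#' @param reference,test [DoseMap-class] objects on the same grid.
#' @param voi logical mask; `NULL` uses the full grid.
#' @return NMSE in percent.
#' @export
nmse <- function(reference, test, voi = NULL) {
  if (!sameGeometry(geometry(reference), geometry(test)))
    y90Stop("y90_geometry_mismatch", "dose maps are on different grids")
  r <- voxelValues(reference); t <- voxelValues(test)
  if (!is.null(voi)) {
    checkMask(voi, geometry(reference), "VOI")
    r <- r[voi]; t <- t[voi]
  }
  denom <- sum(r^2)
  if (denom == 0)
    y90Stop("y90_degenerate", "reference map is zero within the VOI")
  100 * sum((t - r)^2) / denom
}

#' Signed voxel difference maps
#'
#' The voxel-based subtraction used to visualise where one dose map
#' exceeds the other: returns the positive parts of `a - b` and of
#' `b - a` as two dose maps. Their sum is `|a - b|` elementwise.
#'
#' @param a,b [DoseMap-class] objects on the same grid.
#' @return list with elements `aMinusB` and `bMinusA`.
#' @export
doseDifferenceMaps <- function(a, b) {
  if (!sameGeometry(geometry(a), geometry(b)))
    y90Stop("y90_geometry_mismatch", "dose maps are on different grids")
  d <- voxelValues(a) - voxelValues(b)
  list(aMinusB = doseMap(pmax(d, 0), geometry(a)),
       bMinusA = doseMap(pmax(-d, 0), geometry(a)))
}

#' Pairwise method-comparison table
#'
#' Summarises the agreement of several method pairs as one row per pair,
#' mirroring the layout of published comparison tables: mean difference,
#' bias, limits of agreement (bias +/- 2 SD), percent of points beyond the
#' limits, Pearson r and Lin concordance.
#'
#' @param pairs named list; each element a list/data.frame with numeric
#'   elements `x` and `y` of equal length.
#' @param csvPath optional path to write the table as CSV.
#' @return a data.frame.
#' @export
agreementTable <- function(pairs, csvPath = NULL) {
  rows <- lapply(names(pairs), function(nm) {
    p <- pairs[[nm]]
    r <- blandAltman(p$x, p$y)
    data.frame(pair = nm, n = r@n, bias_Gy = r@biasGy,
               loa_low_Gy = r@limitsGy[1], loa_high_Gy = r@limitsGy[2],
               beyond_2SD_percent = r@percentBeyondLimits,
               pearson_r = r@pearsonR, lin_ccc = r@linCCC,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (!is.null(csvPath)) utils::write.csv(out, csvPath, row.names = FALSE)
  out
}

setMethod("show", "AgreementReport", function(object) {
  cat(sprintf(paste0(
    "AgreementReport (n = %d)\n",
    "  bias %.3g Gy, limits of agreement [%.3g, %.3g] Gy (bias +/- 2 SD)\n",
    "  %.1f%% of points beyond limits; Pearson r %.3f, Lin CCC %.3f\n"),
    object@n, object@biasGy, object@limitsGy[1], object@limitsGy[2],
    object@percentBeyondLimits, object@pearsonR, object@linCCC))
})
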
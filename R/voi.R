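#' Build a VOI set from raw masks
#'
#' Assembles whole-liver (WL), planning-target (PTV) and per-tumor masks
#' into a validated [VoiSet-class]. The derived volumes — aggregated tumor
#' TL, target normal liver NLt (PTV minus TL) and whole normal liver NLw
#' (WL minus TL) — are obtained by set algebra through [tlMask()],
#' [nltMask()] and [nlwMask()] and are recomputed on every call, never
#' stored.
#'
#' Construction fails if a tumor leaves the PTV, the PTV leaves the WL, or
#' two tumors overlap; the error names the offending voxel count.
#'
#' @param wl,ptv logical arrays on `geom`. `ptv = NULL` uses the whole
#'   liver as the target (whole-liver treatment).
#' @param tumors named list of logical arrays, one per tumor.
#' @param geom a [GridGeometry-class].
#' @param x a `VoiSet`.
#' @return `voiSet()` a [VoiSet-class]; mask accessors logical arrays;
#'   `voiVolumesML()` a named numeric vector of volumes in mL (WL, PTV, TL,
#'   NLt, NLw and one entry per tumor).
#' @examples
#' g <- gridGeometry(c(12L, 12L, 12L), 4.48)
#' wl <- array(TRUE, dim = c(12, 12, 12))
#' t1 <- array(FALSE, dim = c(12, 12, 12)); t1[5:6, 5:6, 5:6] <- TRUE
#' v <- voiSet(wl, tumors = list(T1 = t1), geom = g)
#' voiVolumesML(v)
#' @name voiSet
#' @aliases wlMask ptvMask tumorMasks tumorNames
#' @export
voiSet <- function(wl, ptv = NULL, tumors, geom) {
  checkMask(wl, geom, "WL")
  if (is.null(ptv)) ptv <- wl else checkMask(ptv, geom, "PTV")
  if (!is.list(tumors) || !length(tumors))
    y90Stop("y90_missing_voi", "at least one tumor mask is required")
  if (is.null(names(tumors)))
    names(tumors) <- paste0("T", seq_along(tumors))
  for (nm in names(tumors)) checkMask(tumors[[nm]], geom, nm)
  obj <- new("VoiSet", geometry = geom, wl = wl, ptv = ptv, tumors = tumors)
  obj
}

#' @rdname voiSet
#' @export
setMethod("wlMask", "VoiSet", function(x) x@wl)

#' @rdname voiSet
#' @export
setMethod("ptvMask", "VoiSet", function(x) x@ptv)

#' @rdname voiSet
#' @export
setMethod("tumorMasks", "VoiSet", function(x) x@tumors)

#' @rdname voiSet
#' @export
setMethod("tumorNames", "VoiSet", function(x) names(x@tumors))

#' @rdname gridGeometry
#' @export
setMethod("geometry", "VoiSet", function(x) x@geometry)

#' Derived VOI algebra
#'
#' `tlMask()` is the union of the individual tumor masks (aggregated
#' tumor), `nltMask()` the PTV with the aggregated tumor removed (target
#' normal liver), `nlwMask()` the whole liver with the aggregated tumor
#' removed (whole normal liver). `voiVolumesML()` reports all VOI volumes
#' in mL. Because these are recomputed from the stored masks on each call,
#' they are idempotent and can never be stale.
#'
#' @param x a [VoiSet-class].
#' @return logical arrays; `voiVolumesML()` a named numeric vector (mL).
#' @name voiAlgebra
#' @aliases nltMask nlwMask voiVolumesML
#' @export
setMethod("tlMask", "VoiSet", function(x) {
  Reduce(`|`, x@tumors)
})

#' @rdname voiAlgebra
#' @export
setMethod("nltMask", "VoiSet", function(x) x@ptv & !tlMask(x))

#' @rdname voiAlgebra
#' @export
setMethod("nlwMask", "VoiSet", function(x) x@wl & !tlMask(x))

#' @rdname voiAlgebra
#' @export
setMethod("voiVolumesML", "VoiSet", function(x) {
  vv <- voxelVolumeML(x@geometry)
  tum <- vapply(x@tumors, sum, numeric(1)) * vv
  c(WL = sum(x@wl) * vv, PTV = sum(x@ptv) * vv,
    TL = sum(tlMask(x)) * vv, NLt = sum(nltMask(x)) * vv,
    NLw = sum(nlwMask(x)) * vv, tum)
})

setMethod("show", "VoiSet", function(object) {
  v <- voiVolumesML(object)
  cat(sprintf("VoiSet on %s grid: %d tumor(s)\n",
              paste(object@geometry@shape, collapse = "x"),
              length(object@tumors)))
  cat("  volumes (mL): ",
      paste(sprintf("%s=%.1f", names(v), v), collapse = ", "), "\n")
})
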
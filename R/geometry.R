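#' Grid geometry and voxel volumes
#'
#' `gridGeometry()` builds the voxel-grid descriptor shared by every image
#' in a study. `voxelVolumeML()` returns the voxel volume in mL
#' (product of the spacings in mm divided by 1000), and `volumeML()` the
#' volume of a binary mask, i.e. its voxel count times the voxel volume.
#'
#' @param shape integer vector (nx, ny, nz).
#' @param spacingMM voxel spacing in mm; a scalar is recycled to all axes.
#' @param x a `GridGeometry` or any `ScalarImage`.
#' @param mask logical array on `geom`.
#' @param geom a `GridGeometry`.
#'
#' @return `gridGeometry()` a [GridGeometry-class]; `voxelVolumeML()` and
#'   `volumeML()` numeric scalars in mL.
#'
#' @examples
#' g <- gridGeometry(c(64L, 64L, 64L), 4.48)
#' voxelVolumeML(g)            # 4.48^3 / 1000 = 0.0899 mL
#' m <- array(FALSE, dim = c(64, 64, 64)); m[1:10, 1, 1] <- TRUE
#' volumeML(m, g)              # 10 voxels = 0.899 mL
#' @name gridGeometry
#' @aliases geometry spacingMM voxelVolumeML
#' @export
gridGeometry <- function(shape, spacingMM) {
  if (length(spacingMM) == 1L) spacingMM <- rep(spacingMM, 3L)
  new("GridGeometry", shape = as.integer(shape),
      spacingMM = as.numeric(spacingMM))
}

#' @rdname gridGeometry
#' @export
setMethod("voxelVolumeML", "GridGeometry", function(x) prod(x@spacingMM) / 1000)

#' @rdname gridGeometry
#' @export
setMethod("geometry", "GridGeometry", function(x) x)

#' @rdname gridGeometry
#' @export
setMethod("spacingMM", "GridGeometry", function(x) x@spacingMM)

#' @rdname gridGeometry
#' @export
volumeML <- function(mask, geom) {
  checkMask(mask, geom)
  n <- sum(mask)
  if (n == 0L) y90Warn("volumeML: empty mask, volume is 0 mL")
  n * voxelVolumeML(geom)
}

setMethod("show", "GridGeometry", function(object) {
  cat(sprintf("GridGeometry: %s voxels, spacing %s mm, voxel %.5f mL\n",
              paste(object@shape, collapse = " x "),
              paste(format(object@spacingMM), collapse = " x "),
              voxelVolumeML(object)))
})
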
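#' Scalar image constructors and accessors
#'
#' Constructors for the per-voxel image classes: `countImage()` (SPECT-like
#' counts), `activityMap()` (Y-90 GBq per voxel), `cumulatedActivityMap()`
#' (GBq·s per voxel) and `doseMap()` (Gy per voxel). `voxelValues()` returns
#' the raw array.
#'
#' @param values numeric 3-D array of non-negative values.
#' @param geom a [GridGeometry-class] matching `dim(values)`.
#' @param x a `ScalarImage`.
#' @return an object of the corresponding image class.
#' @examples
#' g <- gridGeometry(c(4L, 4L, 4L), 4.48)
#' img <- countImage(array(1, dim = c(4, 4, 4)), g)
#' sum(voxelValues(img))
#' @name scalarImages
#' @aliases voxelValues
#' @export
countImage <- function(values, geom) {
  new("CountImage", geometry = geom, values = asImageArray(values))
}

#' @rdname scalarImages
#' @export
activityMap <- function(values, geom) {
  new("ActivityMap", geometry = geom, values = asImageArray(values))
}

#' @rdname scalarImages
#' @export
cumulatedActivityMap <- function(values, geom) {
  new("CumulatedActivityMap", geometry = geom, values = asImageArray(values))
}

#' @rdname scalarImages
#' @export
doseMap <- function(values, geom) {
  new("DoseMap", geometry = geom, values = asImageArray(values))
}

asImageArray <- function(values) {
  v <- as.array(values)
  storage.mode(v) <- "double"
  v
}

#' @rdname scalarImages
#' @export
setMethod("voxelValues", "ScalarImage", function(x) x@values)

#' @rdname gridGeometry
#' @export
setMethod("geometry", "ScalarImage", function(x) x@geometry)

#' @rdname gridGeometry
#' @export
setMethod("spacingMM", "ScalarImage", function(x) x@geometry@spacingMM)

#' @rdname gridGeometry
#' @export
setMethod("voxelVolumeML", "ScalarImage",
          function(x) voxelVolumeML(x@geometry))

setMethod("show", "ScalarImage", function(object) {
  v <- object@values
  cat(sprintf("%s: %s voxels at %s mm; total %.6g, max %.6g\n",
              class(object), paste(dim(v), collapse = " x "),
              paste(format(object@geometry@spacingMM), collapse = " x "),
              sum(v), max(v)))
})
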
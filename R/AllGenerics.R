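#' @rdname gridGeometry
#' @export
setGeneric("geometry", function(x) standardGeneric("geometry"))

#' @rdname gridGeometry
#' @export
setGeneric("spacingMM", function(x) standardGeneric("spacingMM"))

#' @rdname gridGeometry
#' @export
setGeneric("voxelVolumeML", function(x) standardGeneric("voxelVolumeML"))

#' @rdname scalarImages
#' @export
setGeneric("voxelValues", function(x) standardGeneric("voxelValues"))

#' @rdname voiSet
#' @export
setGeneric("wlMask", function(x) standardGeneric("wlMask"))

#' @rdname voiSet
#' @export
setGeneric("ptvMask", function(x) standardGeneric("ptvMask"))

#' @rdname voiSet
#' @export
setGeneric("tumorMasks", function(x) standardGeneric("tumorMasks"))

#' @rdname voiSet
#' @export
setGeneric("tumorNames", function(x) standardGeneric("tumorNames"))

#' @rdname voiAlgebra
#' @export
setGeneric("tlMask", function(x) standardGeneric("tlMask"))

#' @rdname voiAlgebra
#' @export
setGeneric("nltMask", function(x) standardGeneric("nltMask"))

#' @rdname voiAlgebra
#' @export
setGeneric("nlwMask", function(x) standardGeneric("nlwMask"))

#' @rdname voiAlgebra
#' @export
setGeneric("voiVolumesML", function(x) standardGeneric("voiVolumesML"))

#' @rdname doseKernel
#' @export
setGeneric("sValues", function(x) standardGeneric("sValues"))
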
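#' NIfTI image input/output
#'
#' Thin NIfTI-1 wrappers (via RNifti; both plain and gzipped files work).
#' Voxel spacing is taken from the header `pixdim`; the affine is carried
#' through on write but plays no role in any calculation. `writeImage()`
#' writes any [ScalarImage-class] and records the value units in a JSON
#' sidecar (`<path>.json`) alongside.
#'
#' @param path NIfTI file path (`.nii` or `.nii.gz`).
#' @param img a [ScalarImage-class].
#' @return `readCountImage()` a [CountImage-class]; `readDoseMap()` a
#'   [DoseMap-class]; `writeImage()` the path, invisibly.
#' @name niftiIO
#' @export
readCountImage <- function(path) {
  r <- readNiftiArray(path)
  countImage(r$values, r$geom)
}

#' @rdname niftiIO
#' @export
readDoseMap <- function(path) {
  r <- readNiftiArray(path)
  doseMap(r$values, r$geom)
}

readNiftiArray <- function(path) {
  if (!file.exists(path))
    y90Stop("y90_missing_file", "file not found: %s", path)
  img <- RNifti::readNifti(path)
  v <- array(as.numeric(img), dim = dim(img))
  if (length(dim(v)) == 2L) dim(v) <- c(dim(v), 1L)
  if (length(dim(v)) != 3L)
    y90Stop("y90_invalid_image", "%s: expected a 2-D or 3-D image, got %d-D",
            path, length(dim(v)))
  sp <- RNifti::pixdim(img)
  if (length(sp) == 2L) sp <- c(sp, 1)
  list(values = v, geom = gridGeometry(dim(v), sp[1:3]))
}

#' @rdname niftiIO
#' @export
writeImage <- function(img, path) {
  n <- RNifti::asNifti(voxelValues(img))
  RNifti::pixdim(n) <- spacingMM(img)
  RNifti::writeNifti(n, path)
  units <- switch(class(img),
                  CountImage = "counts", ActivityMap = "GBq",
                  CumulatedActivityMap = "GBq.s", DoseMap = "Gy", "unknown")
  jsonlite::write_json(
    list(class = class(img)[1], units = units,
         spacing_mm = spacingMM(img), shape = dim(voxelValues(img))),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Label-map VOI input/output
#'
#' A VOI set on disk is an integer NIfTI label image plus a JSON role map
#' binding roles to label values, e.g.
#' `{"WL": [1,2,3], "PTV": [2,3], "T1": [2], "T2": [3]}` — each role's
#' mask is the union of its labels, so nested VOIs (tumor inside PTV
#' inside WL) are expressible with one label per region. `WL` and at least
#' one `T<i>` role are required; a missing `PTV` defaults to the whole
#' liver.
#'
#' @param path NIfTI label image.
#' @param rolesPath JSON role map.
#' @param vois a [VoiSet-class] to write.
#' @return `readLabelMap()` a [VoiSet-class]; `writeLabelMap()` the image
#'   path, invisibly.
#' @export
readLabelMap <- function(path, rolesPath) {
  r <- readNiftiArray(path)
  lab <- round(r$values)
  roles <- jsonlite::read_json(rolesPath, simplifyVector = TRUE)
  if (!"WL" %in% names(roles))
    y90Stop("y90_missing_voi", "role map %s lacks the required WL role",
            rolesPath)
  roleMask <- function(nm) array(lab %in% roles[[nm]], dim = dim(lab))
  tumorRoles <- grep("^T", names(roles), value = TRUE)
  if (!length(tumorRoles))
    y90Stop("y90_missing_voi", "role map %s lacks tumor roles (T1, T2, ...)",
            rolesPath)
  voiSet(roleMask("WL"),
         if ("PTV" %in% names(roles)) roleMask("PTV") else NULL,
         stats::setNames(lapply(tumorRoles, roleMask), tumorRoles),
         r$geom)
}

#' @rdname readLabelMap
#' @export
writeLabelMap <- function(vois, path, rolesPath) {
  # disjoint partition: NLw outside PTV=1, NLt=2, tumors 3..; roles union
  lab <- array(0L, dim = geometry(vois)@shape)
  lab[nlwMask(vois)] <- 1L
  lab[nltMask(vois)] <- 2L
  tn <- tumorNames(vois)
  for (i in seq_along(tn)) lab[tumorMasks(vois)[[i]]] <- 2L + i
  roles <- list(WL = 1:(2L + length(tn)), PTV = 2:(2L + length(tn)))
  for (i in seq_along(tn)) roles[[tn[i]]] <- 2L + i
  n <- RNifti::asNifti(lab)
  RNifti::pixdim(n) <- spacingMM(geometry(vois))
  RNifti::writeNifti(n, path)
  jsonlite::write_json(roles, rolesPath, auto_unbox = FALSE)
  invisible(path)
}

#' Planar study input
#'
#' Reads a [PlanarStudy-class] from four 2-D NIfTI images: anterior and
#' posterior count views and lung/liver ROI masks (non-zero = inside).
#'
#' @param anteriorPath,posteriorPath 2-D count images.
#' @param lungRoiPath,liverRoiPath 2-D mask images.
#' @return a [PlanarStudy-class].
#' @export
readPlanarStudy <- function(anteriorPath, posteriorPath, lungRoiPath,
                            liverRoiPath) {
  rd2 <- function(p) {
    r <- readNiftiArray(p)
    list(m = r$values[, , 1], sp = r$geom@spacingMM[1:2])
  }
  ant <- rd2(anteriorPath); post <- rd2(posteriorPath)
  planarStudy(ant$m, post$m,
              list(lung = rd2(lungRoiPath)$m != 0,
                   liver = rd2(liverRoiPath)$m != 0),
              pixelSpacingMM = ant$sp)
}

#' @rdname readPlanarStudy
#' @param study a [PlanarStudy-class].
#' @param dir output directory; files `anterior.nii.gz`,
#'   `posterior.nii.gz`, `roi_lung.nii.gz`, `roi_liver.nii.gz`.
#' @export
writePlanarStudy <- function(study, dir) {
  wr <- function(m, name) {
    n <- RNifti::asNifti(m * 1)
    RNifti::pixdim(n) <- study@pixelSpacingMM
    RNifti::writeNifti(n, file.path(dir, name))
  }
  wr(study@anterior, "anterior.nii.gz")
  wr(study@posterior, "posterior.nii.gz")
  wr(study@rois$lung, "roi_lung.nii.gz")
  wr(study@rois$liver, "roi_liver.nii.gz")
  invisible(dir)
}
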
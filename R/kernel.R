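#' Dose kernels
#'
#' `doseKernel()` validates and wraps a voxel S-value table (see
#' [DoseKernel-class]). `deltaKernel()` builds the 1x1x1 kernel whose only
#' element is the local-deposition S-value — convolving with it reproduces
#' [ldmDose()] exactly. `sValues()` returns the raw array.
#'
#' Published voxel S-value tables are the intended input for
#' [dpkDose()]; drop them in through [readKernel()]. The built-in
#' [buildDefaultKernel()] exists so the pipeline runs without external
#' data.
#'
#' @param sValues 3-D non-negative array, odd-sized on every axis,
#'   Gy/(GBq·s).
#' @param spacingMM kernel voxel spacing, mm (scalar recycled to 3).
#' @param voxelSideMM cubic voxel side for the delta kernel, mm.
#' @param constants a [PhysicsConstants-class].
#' @param x a `DoseKernel`.
#' @return a [DoseKernel-class].
#' @name doseKernel
#' @aliases sValues
#' @export
doseKernel <- function(sValues, spacingMM) {
  if (length(spacingMM) == 1L) spacingMM <- rep(spacingMM, 3L)
  new("DoseKernel", sValues = asImageArray(sValues),
      spacingMM = as.numeric(spacingMM))
}

#' @rdname doseKernel
#' @export
deltaKernel <- function(voxelSideMM, constants = physicsConstants()) {
  doseKernel(array(ldmSValue(voxelSideMM, constants), dim = c(1L, 1L, 1L)),
             voxelSideMM)
}

#' @rdname doseKernel
#' @export
setMethod("sValues", "DoseKernel", function(x) x@sValues)

setMethod("show", "DoseKernel", function(object) {
  d <- dim(object@sValues); c0 <- (d + 1L) %/% 2L
  cat(sprintf("DoseKernel: %s at %s mm; center %.4g, sum %.4g Gy/(GBq.s)\n",
              paste(d, collapse = " x "),
              paste(format(object@spacingMM), collapse = " x "),
              object@sValues[c0[1], c0[2], c0[3]], sum(object@sValues)))
})

#' Default Y-90 voxel S-value kernel (synthetic)
#'
#' Builds a voxel S-value kernel by Monte-Carlo voxel-pair integration of
#' an analytic radial energy-deposition profile for Y-90 beta particles in
#' soft tissue: emission points are sampled uniformly in the source voxel,
#' deposition radii from a Weibull profile (shape 2) scaled so that 90
#' percent of the beta energy is deposited within 5.3 mm and truncated at
#' the 11.3 mm maximum beta range, and directions isotropically. Each
#' sample deposits its energy share at a point, binned into the target
#' voxel. The kernel is normalized exactly: summed over all offsets, the
#' deposited energy per decay equals the mean beta energy, so the total
#' energy closure of [dpkDose()] matches [ldmDose()].
#'
#' This is a synthetic stand-in profile, not a published transport kernel;
#' its purpose is a physically sensible, energy-closed default. For
#' clinical work load a published table with [readKernel()].
#'
#' @param voxelSideMM cubic voxel side, mm, in (1, 10).
#' @param constants a [PhysicsConstants-class] (beta energy and voxel
#'   density).
#' @param seed integer seed; the same seed gives a bit-identical kernel.
#' @param nSamples Monte-Carlo sample count.
#' @return a [DoseKernel-class].
#' @export
buildDefaultKernel <- function(voxelSideMM = 4.48,
                               constants = physicsConstants(),
                               seed = 1L, nSamples = 2e5) {
  assertScalar(voxelSideMM, "voxelSideMM", lower = 1, upper = 10,
               openLower = TRUE, openUpper = TRUE)
  maxRangeMM <- 11.3                       # maximum Y-90 beta range
  r90MM <- 5.3                             # 90% energy radius
  lambda <- r90MM / sqrt(log(10))          # Weibull(k=2) scale
  side <- voxelSideMM
  h <- as.integer(ceiling(maxRangeMM / side + 1))
  dims <- rep(2L * h + 1L, 3L)

  old <- globalenv()$.Random.seed
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))

  n <- as.integer(nSamples)
  src <- matrix(stats::runif(3L * n, -side / 2, side / 2), ncol = 3L)
  fmax <- 1 - exp(-(maxRangeMM / lambda)^2)          # truncation mass
  r <- lambda * sqrt(-log(1 - stats::runif(n) * fmax))
  u <- stats::rnorm(n); v <- stats::rnorm(n); w <- stats::rnorm(n)
  nrm <- sqrt(u^2 + v^2 + w^2)
  dep <- src + r * cbind(u, v, w) / nrm
  off <- round(dep / side)                           # voxel offset per axis
  lin <- (off[, 1] + h) + dims[1] * ((off[, 2] + h) +
                                       dims[2] * (off[, 3] + h)) + 1
  frac <- tabulate(lin, nbins = prod(dims)) / n
  massKg <- side^3 / 1000 * constants@voxelDensity / 1000
  s <- array(betaEnergyJPerGBqS(constants) * frac / massKg, dim = dims)
  doseKernel(s, side)
}

#' Kernel text file I/O
#'
#' Plain-text kernel format: line 1 holds `nx ny nz spacing_mm`, followed
#' by nz blocks of ny lines of nx whitespace-separated S-values in
#' Gy/(GBq·s), x varying fastest. Values are written with 12 significant
#' digits, so a save/load round trip is lossless at that precision.
#'
#' @param path file path.
#' @param kernel a [DoseKernel-class].
#' @return `readKernel()` a [DoseKernel-class]; `writeKernel()` the path,
#'   invisibly.
#' @export
readKernel <- function(path) {
  lines <- readLines(path)
  if (!length(lines)) y90Stop("y90_kernel_format", "empty kernel file")
  hdr <- suppressWarnings(as.numeric(strsplit(trimws(lines[1]), "\\s+")[[1]]))
  if (length(hdr) != 4L || any(is.na(hdr)))
    y90Stop("y90_kernel_format",
            "line 1: header must be 'nx ny nz spacing_mm' (got '%s')",
            lines[1])
  d <- as.integer(hdr[1:3]); sp <- hdr[4]
  body <- lines[-1][nzchar(trimws(lines[-1]))]
  if (length(body) != d[2] * d[3])
    y90Stop("y90_kernel_format",
            "expected %d data lines after the header, found %d",
            d[2] * d[3], length(body))
  vals <- lapply(seq_along(body), function(i) {
    row <- suppressWarnings(as.numeric(strsplit(trimws(body[i]), "\\s+")[[1]]))
    if (length(row) != d[1] || any(is.na(row)))
      y90Stop("y90_kernel_format", "line %d: expected %d numeric values",
              i + 1L, d[1])
    row
  })
  doseKernel(array(unlist(vals), dim = d), sp)
}

#' @rdname readKernel
#' @export
writeKernel <- function(kernel, path) {
  d <- dim(kernel@sValues)
  con <- file(path, "w"); on.exit(close(con))
  writeLines(sprintf("%d %d %d %.12g", d[1], d[2], d[3],
                     kernel@spacingMM[1]), con)
  for (z in seq_len(d[3])) for (y in seq_len(d[2]))
    writeLines(paste(sprintf("%.12g", kernel@sValues[, y, z]),
                     collapse = " "), con)
  invisible(path)
}
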
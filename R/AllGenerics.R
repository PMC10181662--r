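#' Number of spectral bands
#' @param x a WavelengthGrid, Hypercube or SeedCube.
#' @return integer band count.
#' @export
setGeneric("nBands", function(x) standardGeneric("nBands"))

#' Wavelength vector (nm)
#' @param x a WavelengthGrid, Hypercube or SeedCube.
#' @return numeric vector of band-centre wavelengths in nanometres.
#' @export
setGeneric("wavelengths", function(x) standardGeneric("wavelengths"))

#' Cube data array
#' @param x a Hypercube or SeedCube.
#' @return the underlying 3-D numeric array.
#' @export
setGeneric("cubeData", function(x) standardGeneric("cubeData"))

#' Cube metadata list
#' @param x a Hypercube.
#' @export
setGeneric("cubeMeta", function(x) standardGeneric("cubeMeta"))

#' Is a cube calibrated to reflectance?
#' @param x a Hypercube.
#' @return logical(1).
#' @export
setGeneric("isCalibrated", function(x) standardGeneric("isCalibrated"))

#' Convert raw intensity to reflectance (Shafer model)
#'
#' @param raw a raw-intensity [Hypercube-class].
#' @param refs a [CalibrationRefs-class] (white and dark references).
#' @param ... further arguments; see the Hypercube method.
#' @return a calibrated reflectance [Hypercube-class].
#' @export
setGeneric("calibrate", function(raw, refs, ...) standardGeneric("calibrate"))

#' Mean spectrum of masked seed pixels
#' @param x a [SeedCube-class].
#' @return numeric vector, one per-band mean over masked pixels.
#' @export
setGeneric("meanSpectrum", function(x) standardGeneric("meanSpectrum"))

#' Mean intensity of masked seed pixels
#'
#' Band-averages each masked pixel first, then averages over pixels.
#' @param x a [SeedCube-class].
#' @return numeric(1).
#' @export
setGeneric("meanIntensity", function(x) standardGeneric("meanIntensity"))

setMethod("nBands", "WavelengthGrid", function(x) x@count)
setMethod("nBands", "Hypercube", function(x) x@grid@count)
setMethod("nBands", "SeedCube", function(x) x@grid@count)

setMethod("wavelengths", "WavelengthGrid",
  function(x) x@startNm + (seq_len(x@count) - 1) * x@stepNm)
setMethod("wavelengths", "Hypercube", function(x) wavelengths(x@grid))
setMethod("wavelengths", "SeedCube", function(x) wavelengths(x@grid))

setMethod("cubeData", "Hypercube", function(x) x@data)
setMethod("cubeData", "SeedCube", function(x) x@data)
setMethod("cubeMeta", "Hypercube", function(x) x@metadata)
setMethod("isCalibrated", "Hypercube", function(x) isTRUE(x@metadata$calibrated))

#' @export
setMethod("dim", "Hypercube", function(x) dim(x@data))

setMethod("show", "WavelengthGrid", function(object) {
  cat(sprintf("WavelengthGrid: %d bands, %.2f-%.2f nm, step %.2f nm\n",
              object@count, object@startNm,
              object@startNm + (object@count - 1) * object@stepNm, object@stepNm))
})

setMethod("show", "Hypercube", function(object) {
  d <- dim(object@data)
  cat(sprintf("Hypercube: %d x %d pixels, %d bands (%.2f-%.2f nm)\n",
              d[1], d[2], d[3], object@grid@startNm,
              object@grid@startNm + (d[3] - 1) * object@grid@stepNm))
  cat(sprintf("  %s, range [%.4g, %.4g]\n",
              if (isCalibrated(object)) "reflectance (calibrated)" else "raw intensity",
              min(object@data), max(object@data)))
  extra <- setdiff(names(object@metadata), "calibrated")
  if (length(extra))
    cat("  metadata:", paste(extra, collapse = ", "), "\n")
})

setMethod("show", "SeedRegion", function(object) {
  cat(sprintf("SeedRegion #%d: %d px, bbox [%d:%d, %d:%d], centroid (%.1f, %.1f)\n",
              object@labelId, object@areaPx, object@bbox[1], object@bbox[3],
              object@bbox[2], object@bbox[4], object@centroid[1], object@centroid[2]))
})

setMethod("show", "SeedCube", function(object) {
  d <- dim(object@data)
  cat(sprintf("SeedCube [%s]: %d x %d x %d, class %s, exposure %s h, %d seed px\n",
              object@source, d[1], d[2], d[3], object@classLabel,
              format(object@exposureLabel), sum(object@mask)))
})

setMethod("show", "LabeledSeedSet", function(object) {
  cat(sprintf("LabeledSeedSet: %d cubes, %d classes\n",
              length(object@cubes), nlevels(object@labels)))
  print(table(class = object@labels, split = object@split, useNA = "ifany"))
})

setMethod("show", "PixelDataset", function(object) {
  cat(sprintf("PixelDataset: %d pixels x %d bands, %d classes\n",
              nrow(object@X), ncol(object@X), nlevels(object@y)))
})

setMethod("show", "EvaluationReport", function(object) {
  cat(sprintf("EvaluationReport: %d classes, n = %d\n",
              nrow(object@confusion), sum(object@confusion)))
  cat(sprintf("  OA %.4f  AA %.4f  kappa %.4f\n", object@OA, object@AA, object@kappa))
  print(object@perClass, digits = 4)
})

setMethod("show", "CNN3DModel", function(object) {
  cat(sprintf("CNN3DModel: input %s, %d classes (%s)\n",
              paste(object@inputDim, collapse = "x"), length(object@classLevels),
              paste(object@classLevels, collapse = ", ")))
  if (nrow(object@history))
    cat(sprintf("  trained %d epochs, final train loss %.4f\n",
                nrow(object@history), object@history$trainLoss[nrow(object@history)]))
})

setMethod("show", "DNNModel", function(object) {
  cat(sprintf("DNNModel: %d bands -> %s -> %d classes\n",
              length(object@bandMean),
              paste(object@config$hiddenWidths, collapse = "-"),
              length(object@classLevels)))
  if (nrow(object@history))
    cat(sprintf("  trained %d epochs, final train loss %.4f\n",
                nrow(object@history), object@history$trainLoss[nrow(object@history)]))
})
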
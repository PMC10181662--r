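#' @importFrom methods new validObject is slot setClass setGeneric setMethod setValidity show
#' @importFrom stats prcomp rnorm runif sd quantile
#' @importFrom utils head write.csv read.csv
NULL

#' WavelengthGrid: a uniform spectral sampling grid
#'
#' Describes the wavelength axis of a hypercube as a uniform grid:
#' `wavelength(i) = startNm + (i - 1) * stepNm` for `i = 1, ..., count`
#' (1-based band indices throughout the package).
#'
#' @slot startNm numeric(1), wavelength of the first band in nanometres.
#' @slot stepNm numeric(1), inter-band sampling interval in nanometres (> 0).
#' @slot count integer(1), number of bands (>= 1).
#'
#' @examples
#' g <- wavelengthGrid(597.21, 4.14, 268)
#' nBands(g)
#' head(wavelengths(g))
#' @export
setClass("WavelengthGrid",
  representation(startNm = "numeric", stepNm = "numeric", count = "integer"))

setValidity("WavelengthGrid", function(object) {
  msg <- NULL
  if (length(object@startNm) != 1L || !is.finite(object@startNm))
    msg <- c(msg, "startNm must be a single finite number")
  if (length(object@stepNm) != 1L || !is.finite(object@stepNm) || object@stepNm <= 0)
    msg <- c(msg, "stepNm must be a single positive number")
  if (length(object@count) != 1L || is.na(object@count) || object@count < 1L)
    msg <- c(msg, "count must be a single integer >= 1")
  if (is.null(msg)) TRUE else msg
})

#' @rdname WavelengthGrid-class
#' @param startNm wavelength of the first band (nm).
#' @param stepNm sampling interval (nm).
#' @param count number of bands.
#' @export
wavelengthGrid <- function(startNm, stepNm, count) {
  new("WavelengthGrid", startNm = as.numeric(startNm), stepNm = as.numeric(stepNm),
      count = as.integer(count))
}

#' Hypercube: a hyperspectral data cube
#'
#' A 3-D array of raw intensity or reflectance with axis convention
#' (row, col, band), plus its [WavelengthGrid-class] and free-form provenance
#' metadata. The `calibrated` metadata flag marks reflectance cubes produced
#' by [calibrate()].
#'
#' @slot data 3-D numeric array, rows x cols x bands; all values finite.
#' @slot grid a [WavelengthGrid-class]; `count` must equal `dim(data)[3]`.
#' @slot metadata list of provenance fields (e.g. `calibrated`, `class`,
#'   `exposure_h`, `panel`).
#'
#' @examples
#' cube <- hypercube(array(0.5, c(4, 5, 3)), wavelengthGrid(600, 10, 3))
#' dim(cube)
#' @export
setClass("Hypercube",
  representation(data = "array", grid = "WavelengthGrid", metadata = "list"))

setValidity("Hypercube", function(object) {
  msg <- NULL
  d <- dim(object@data)
  if (length(d) != 3L)
    msg <- c(msg, "data must be a 3-D array (row, col, band)")
  else if (d[3] != object@grid@count)
    msg <- c(msg, sprintf("band dimension (%d) must equal grid count (%d)",
                          d[3], object@grid@count))
  if (!all(is.finite(object@data)))
    msg <- c(msg, "all cube values must be finite")
  if (is.null(msg)) TRUE else msg
})

#' @rdname Hypercube-class
#' @param data 3-D numeric array (row, col, band).
#' @param grid a [WavelengthGrid-class].
#' @param metadata list of provenance fields.
#' @export
hypercube <- function(data, grid, metadata = list()) {
  storage.mode(data) <- "double"
  if (is.null(metadata$calibrated)) metadata$calibrated <- FALSE
  new("Hypercube", data = data, grid = grid, metadata = metadata)
}

#' CalibrationRefs: white and dark reference cubes
#'
#' Holds the white reference (100% reflectance target, e.g. a Teflon tile)
#' and the dark reference (shutter closed, 0% reflectance) used by the
#' Shafer reflectance model. References may be full-frame (same rows x cols
#' as the target cube) or a single-line column profile (1 x cols x bands,
#' the line-scan convention) which is broadcast over rows.
#'
#' @slot white a [Hypercube-class] of raw white-reference intensities.
#' @slot dark a [Hypercube-class] of raw dark-reference intensities.
#' @export
setClass("CalibrationRefs",
  representation(white = "Hypercube", dark = "Hypercube"))

setValidity("CalibrationRefs", function(object) {
  dw <- dim(object@white@data); dd <- dim(object@dark@data)
  if (!identical(dw, dd))
    return("white and dark references must share dimensions")
  if (object@white@grid@count != object@dark@grid@count)
    return("white and dark references must share the wavelength grid")
  TRUE
})

#' @rdname CalibrationRefs-class
#' @param white,dark white and dark reference [Hypercube-class] objects.
#' @export
calibrationRefs <- function(white, dark) new("CalibrationRefs", white = white, dark = dark)

#' SeedRegion: one segmented seed in a panel frame
#'
#' @slot labelId positive integer id, unique within a panel.
#' @slot mask logical matrix in panel-frame coordinates.
#' @slot bbox integer(4) `c(rowMin, colMin, rowMax, colMax)`, 1-based
#'   inclusive, tightly bounding the mask.
#' @slot centroid numeric(2) `c(row, col)` centre of mass of the mask.
#' @slot areaPx integer(1), number of TRUE mask pixels.
#' @export
setClass("SeedRegion",
  representation(labelId = "integer", mask = "matrix", bbox = "integer",
                 centroid = "numeric", areaPx = "integer"))

setValidity("SeedRegion", function(object) {
  msg <- NULL
  if (!is.logical(object@mask)) msg <- c(msg, "mask must be logical")
  if (object@areaPx != sum(object@mask)) msg <- c(msg, "areaPx must equal sum(mask)")
  if (length(object@bbox) != 4L) msg <- c(msg, "bbox must have 4 entries")
  else if (object@areaPx > 0L) {
    rr <- range(which(rowSums(object@mask) > 0))
    cc <- range(which(colSums(object@mask) > 0))
    if (!identical(object@bbox, as.integer(c(rr[1], cc[1], rr[2], cc[2]))))
      msg <- c(msg, "bbox must tightly bound the mask")
  }
  if (is.null(msg)) TRUE else msg
})

#' @rdname SeedRegion-class
#' @param labelId positive integer region id.
#' @param mask logical matrix of seed pixels in the panel frame.
#' @export
seedRegion <- function(labelId, mask) {
  area <- sum(mask)
  rr <- range(which(rowSums(mask) > 0)); cc <- range(which(colSums(mask) > 0))
  idx <- which(mask, arr.ind = TRUE)
  new("SeedRegion", labelId = as.integer(labelId), mask = mask,
      bbox = as.integer(c(rr[1], cc[1], rr[2], cc[2])),
      centroid = c(mean(idx[, 1]), mean(idx[, 2])), areaPx = as.integer(area))
}

#' SeedCube: one extracted seed sub-cube
#'
#' A fixed-spatial-size crop of a calibrated panel around one seed, with
#' background pixels zeroed by the seed mask, plus its class and exposure
#' labels.
#'
#' @slot data 3-D array H x W x bands (reflectance), background zeroed.
#' @slot mask logical H x W matrix marking seed pixels inside the chip.
#' @slot grid the source panel's [WavelengthGrid-class].
#' @slot classLabel character(1) treatment class.
#' @slot exposureLabel numeric(1) exposure duration in hours (NA if unknown).
#' @slot source character(1) provenance id, `"<panel>#<labelId>"`.
#' @slot offset numeric(2) panel-frame coordinates of the chip's pixel (1, 1)
#'   (NA when unknown, e.g. after resizing or augmentation), used to place
#'   pixel predictions back into the panel.
#' @export
setClass("SeedCube",
  representation(data = "array", mask = "matrix", grid = "WavelengthGrid",
                 classLabel = "character", exposureLabel = "numeric",
                 source = "character", offset = "numeric"),
  prototype(offset = c(NA_real_, NA_real_)))

setValidity("SeedCube", function(object) {
  d <- dim(object@data)
  if (length(d) != 3L) return("data must be H x W x bands")
  if (!identical(dim(object@mask), d[1:2])) return("mask must match spatial dims")
  if (d[3] != object@grid@count) return("band dimension must equal grid count")
  TRUE
})

#' LabeledSeedSet: a collection of seed cubes with labels and split
#'
#' @slot cubes list of [SeedCube-class], all sharing dimensions.
#' @slot labels factor, one class label per cube.
#' @slot split factor with levels train/val/test (NA before splitting).
#' @export
setClass("LabeledSeedSet",
  representation(cubes = "list", labels = "factor", split = "factor"))

setValidity("LabeledSeedSet", function(object) {
  if (length(object@cubes) != length(object@labels))
    return("labels must match number of cubes")
  if (length(object@split) && length(object@split) != length(object@cubes))
    return("split must match number of cubes")
  TRUE
})

#' @rdname LabeledSeedSet-class
#' @param cubes list of [SeedCube-class].
#' @param labels class label per cube.
#' @param split optional split factor (levels train/val/test).
#' @export
labeledSeedSet <- function(cubes, labels, split = NULL) {
  if (is.null(split))
    split <- factor(rep(NA_character_, length(cubes)), levels = c("train", "val", "test"))
  new("LabeledSeedSet", cubes = cubes, labels = as.factor(labels), split = split)
}

#' PixelDataset: per-pixel spectra with labels and panel origins
#'
#' The pixel-by-band matrix used by the pixel-level classifier: one row per
#' masked (seed) pixel, columns are spectral bands.
#'
#' @slot X numeric matrix n_pixels x n_bands, finite.
#' @slot y factor, class label per pixel.
#' @slot origin data.frame with columns `panel`, `row`, `col`, `seed` used to
#'   render classification maps.
#' @export
setClass("PixelDataset",
  representation(X = "matrix", y = "factor", origin = "data.frame"))

setValidity("PixelDataset", function(object) {
  msg <- NULL
  if (nrow(object@X) != length(object@y)) msg <- c(msg, "y must match rows of X")
  if (nrow(object@X) != nrow(object@origin)) msg <- c(msg, "origin must match rows of X")
  if (!all(is.finite(object@X))) msg <- c(msg, "X must be finite")
  if (is.null(msg)) TRUE else msg
})

#' @rdname PixelDataset-class
#' @param X pixels x bands matrix.
#' @param y class label per pixel.
#' @param origin data.frame with `panel`, `row`, `col`, `seed` per pixel.
#' @export
pixelDataset <- function(X, y, origin) {
  new("PixelDataset", X = X, y = as.factor(y), origin = origin)
}

#' EvaluationReport: multi-class classification metrics
#'
#' @slot confusion k x k count matrix, rows = truth, cols = prediction.
#' @slot perClass data.frame with per-class precision, recall, f1, support
#'   and an `undefined` flag for zero-denominator metrics.
#' @slot macroAvg named numeric, unweighted mean of per-class metrics.
#' @slot weightedAvg named numeric, support-weighted mean of per-class metrics.
#' @slot AA numeric(1), average accuracy (mean one-vs-rest accuracy).
#' @slot OA numeric(1), overall accuracy (trace / total).
#' @slot kappa numeric(1), Cohen's kappa.
#' @export
setClass("EvaluationReport",
  representation(confusion = "matrix", perClass = "data.frame",
                 macroAvg = "numeric", weightedAvg = "numeric",
                 AA = "numeric", OA = "numeric", kappa = "numeric"))

#' ClassificationMap: per-pixel class labels in a panel frame
#'
#' @slot labels integer matrix; 0 is the background sentinel, positive values
#'   index `classLevels`.
#' @slot classLevels character vector of class names.
#' @slot palette named character vector of hex colours, one per class.
#' @export
setClass("ClassificationMap",
  representation(labels = "matrix", classLevels = "character", palette = "character"))

#' CNN3DModel: a trained seed-level 3-D convolutional network
#'
#' @slot params list of weight arrays (conv kernels/biases, dense layers).
#' @slot config the training configuration list (see [cnn3dConfig()]).
#' @slot classLevels character vector mapping output units to class names.
#' @slot inputDim integer(3) expected seed-cube dimension H x W x bands.
#' @slot history data.frame of per-epoch train/val loss and accuracy.
#' @export
setClass("CNN3DModel",
  representation(params = "list", config = "list", classLevels = "character",
                 inputDim = "integer", history = "data.frame"))

#' DNNModel: a trained pixel-level fully-connected network
#'
#' @slot params list of dense layer weights and biases.
#' @slot config the training configuration list (see [dnnConfig()]).
#' @slot classLevels character vector mapping output units to class names.
#' @slot bandMean,bandSd numeric vectors used for per-band standardization
#'   (fitted on the training split, applied at prediction time).
#' @slot history data.frame of per-epoch train/val loss and accuracy.
#' @export
setClass("DNNModel",
  representation(params = "list", config = "list", classLevels = "character",
                 bandMean = "numeric", bandSd = "numeric", history = "data.frame"))

#' SpectralClassModel: generative model of one treatment class
#'
#' Mean reflectance is a shared smooth baseline plus class-specific Gaussian
#' bumps; exposure duration scales the bump amplitudes slightly (a
#' within-class shift); pixels add i.i.d. Gaussian noise.
#'
#' @slot name character(1) class name.
#' @slot bumps data.frame with columns `centerNm`, `widthNm`, `amplitude`
#'   (amplitudes are signed deviations; the resulting mean is clamped to 0..1).
#' @slot slope numeric(1) global linear trend across the spectral range.
#' @slot noiseSd numeric(1) pixel noise standard deviation (reflectance units).
#' @slot exposureCoef numeric(1) relative amplitude change per hour from the
#'   centre of the exposure schedule.
#' @export
setClass("SpectralClassModel",
  representation(name = "character", bumps = "data.frame", slope = "numeric",
                 noiseSd = "numeric", exposureCoef = "numeric"))
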
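## Pixel-level classification: each seed pixel's full spectrum (one row of
## the pixels x bands matrix) is classified by a fully-connected network
## with 12 ReLU hidden layers and a softmax output, trained with Adam on
## categorical cross-entropy. Spectra are standardized per band using
## training-split statistics stored with the model.

#' Build a pixel dataset from seed cubes
#'
#' Collects every masked (seed) pixel of every seed into the pixels x bands
#' matrix, labelling each pixel with its seed's class (or exposure). Row
#' order is deterministic: seeds in the given order, pixels by (row, col)
#' within each chip.
#'
#' @param seeds list of [SeedCube-class] sharing a wavelength grid.
#' @param labelBy `"class"` (default) or `"exposure"`.
#' @return a [PixelDataset-class]; `origin` records panel, row, col and seed
#'   id per pixel.
#' @export
buildPixelDataset <- function(seeds, labelBy = c("class", "exposure")) {
  labelBy <- match.arg(labelBy)
  if (!length(seeds)) stop("no seeds supplied")
  nb <- nBands(seeds[[1]])
  rowsX <- vector("list", length(seeds))
  lab <- vector("list", length(seeds))
  org <- vector("list", length(seeds))
  for (i in seq_along(seeds)) {
    sc <- seeds[[i]]
    if (nBands(sc) != nb) stop("all seeds must share the band count")
    idx <- which(sc@mask, arr.ind = TRUE)
    if (!nrow(idx)) next
    idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
    flat <- matrix(sc@data, ncol = nb)
    rowsX[[i]] <- flat[(idx[, 2] - 1L) * nrow(sc@mask) + idx[, 1], , drop = FALSE]
    labVal <- if (labelBy == "class") sc@classLabel else as.character(sc@exposureLabel)
    lab[[i]] <- rep(labVal, nrow(idx))
    panel <- sub("#.*$", "", sc@source)
    ## panel-frame coordinates when the chip offset is known, chip-frame otherwise
    rc <- if (all(is.finite(sc@offset)))
      cbind(sc@offset[1] + idx[, 1] - 1L, sc@offset[2] + idx[, 2] - 1L)
    else idx
    org[[i]] <- data.frame(panel = panel, row = rc[, 1], col = rc[, 2],
                           seed = sc@source, stringsAsFactors = FALSE)
  }
  X <- do.call(rbind, rowsX)
  if (is.null(X) || !nrow(X)) stop("no masked pixels in any seed")
  pixelDataset(X, unlist(lab), do.call(rbind, org))
}

#' Per-seed stratified train/validation pixel split
#'
#' Splits the pixels of each seed independently: `round(trainFrac * n)` go to
#' training, the rest to validation (so every seed contributes to both sides
#' where size permits). A seed with fewer than 2 pixels is assigned wholly to
#' training with a message. With `perSeed = FALSE` the split is a single
#' global draw over all pixels instead.
#'
#' @param ds a [PixelDataset-class].
#' @param trainFrac training fraction (default 0.7).
#' @param rngSeed seed for the shuffles.
#' @param perSeed split within each seed (default TRUE).
#' @return list with `train` and `val` [PixelDataset-class] objects; their
#'   row sets are disjoint and their union is `ds`.
#' @export
splitPixels <- function(ds, trainFrac = 0.7, rngSeed = 0L, perSeed = TRUE) {
  stopifnot(is(ds, "PixelDataset"), trainFrac > 0, trainFrac < 1)
  set.seed(rngSeed)
  n <- nrow(ds@X)
  trainRows <- logical(n)
  if (perSeed) {
    for (sid in unique(ds@origin$seed)) {
      idx <- which(ds@origin$seed == sid)
      if (length(idx) < 2L) {
        message("seed '", sid, "' has ", length(idx),
                " pixel(s); assigned wholly to training")
        trainRows[idx] <- TRUE
        next
      }
      nTr <- round(trainFrac * length(idx))
      nTr <- min(max(nTr, 1L), length(idx) - 1L)
      trainRows[sample(idx)[seq_len(nTr)]] <- TRUE
    }
  } else {
    nTr <- round(trainFrac * n)
    trainRows[sample.int(n)[seq_len(nTr)]] <- TRUE
  }
  subset <- function(keep) {
    pixelDataset(ds@X[keep, , drop = FALSE],
                 factor(ds@y[keep], levels = levels(ds@y)),
                 ds@origin[keep, , drop = FALSE])
  }
  list(train = subset(trainRows), val = subset(!trainRows))
}

#' Configuration for the pixel-level DNN
#'
#' @param hiddenWidths widths of the 12 ReLU hidden layers (default a taper
#'   256, 256, 128, 128, 128, 64, 64, 64, 32, 32, 32, 16).
#' @param lr Adam learning rate (default 1e-3).
#' @param epochs training epochs (default 30).
#' @param batchSize minibatch size (default 256).
#' @param rngSeed master seed for init and shuffling.
#' @return a config list used by [trainDNN()].
#' @export
dnnConfig <- function(hiddenWidths = c(256L, 256L, 128L, 128L, 128L,
                                       64L, 64L, 64L, 32L, 32L, 32L, 16L),
                      lr = 1e-3, epochs = 30L, batchSize = 256L, rngSeed = 0L) {
  hiddenWidths <- as.integer(hiddenWidths)
  if (any(hiddenWidths < 1L)) stop("hidden widths must be >= 1")
  list(hiddenWidths = hiddenWidths, lr = lr, epochs = as.integer(epochs),
       batchSize = as.integer(batchSize), rngSeed = as.integer(rngSeed))
}

#' Train the pixel-level DNN
#'
#' Input layer (one unit per band), 12 ReLU hidden layers, softmax output;
#' Adam on categorical cross-entropy. Per-band standardization is fitted on
#' the training data and stored with the model. Deterministic for a fixed
#' `rngSeed` on a single thread.
#'
#' @param ds training [PixelDataset-class] (>= 2 classes).
#' @param cfg a [dnnConfig()] list.
#' @param val optional validation [PixelDataset-class] for per-epoch metrics.
#' @return a [DNNModel-class] with per-epoch history.
#' @export
trainDNN <- function(ds, cfg = dnnConfig(), val = NULL) {
  stopifnot(is(ds, "PixelDataset"))
  y <- droplevels(ds@y)
  classLevels <- levels(y)
  k <- length(classLevels)
  if (k < 2L) stop("need at least 2 classes to train a classifier")
  nb <- ncol(ds@X)
  bandMean <- colMeans(ds@X)
  bandSd <- apply(ds@X, 2, sd)
  bandSd[bandSd < 1e-12] <- 1
  X <- sweep(sweep(ds@X, 2, bandMean), 2, bandSd, `/`)
  yInt <- as.integer(y)

  set.seed(cfg$rngSeed)
  widths <- c(nb, cfg$hiddenWidths, k)
  params <- list(W = list(), b = list())
  for (l in seq_len(length(widths) - 1L)) {
    params$W[[l]] <- .heInit(widths[l], widths[l + 1L])
    params$b[[l]] <- numeric(widths[l + 1L])
  }
  adam <- .adamInit(c(params$W, params$b))
  L <- length(params$W)

  valX <- NULL; valY <- NULL
  if (!is.null(val)) {
    valX <- sweep(sweep(val@X, 2, bandMean), 2, bandSd, `/`)
    valY <- as.integer(factor(as.character(val@y), levels = classLevels))
  }
  n <- nrow(X)
  history <- data.frame()
  for (epoch in seq_len(cfg$epochs)) {
    ord <- sample.int(n)
    batches <- split(ord, ceiling(seq_along(ord) / cfg$batchSize))
    epLoss <- 0; epAcc <- 0
    for (bt in batches) {
      A <- .mlpForward(X[bt, , drop = FALSE], params)
      P <- A[[L + 1L]]
      loss <- .crossEntropy(P, yInt[bt])
      if (!is.finite(loss)) stop("training diverged: non-finite loss")
      epLoss <- epLoss + loss * length(bt)
      epAcc <- epAcc + sum(max.col(P, ties.method = "first") == yInt[bt])
      g <- .mlpBackward(A, params, .oneHot(yInt[bt], k))
      upd <- .adamStep(c(params$W, params$b), c(g$W, g$b), adam, cfg$lr)
      adam <- upd$state
      params$W <- upd$params[seq_len(L)]
      params$b <- lapply(upd$params[L + seq_len(L)], as.numeric)
    }
    row <- data.frame(epoch = epoch, trainLoss = epLoss / n, trainAcc = epAcc / n,
                      valLoss = NA_real_, valAcc = NA_real_)
    if (!is.null(valX) && nrow(valX)) {
      Pv <- .mlpForward(valX, params)[[L + 1L]]
      row$valLoss <- .crossEntropy(Pv, valY)
      row$valAcc <- mean(max.col(Pv, ties.method = "first") == valY)
    }
    history <- rbind(history, row)
  }
  new("DNNModel", params = params, config = cfg, classLevels = classLevels,
      bandMean = bandMean, bandSd = bandSd, history = history)
}

#' Predict classes for pixel spectra
#'
#' @param model a [DNNModel-class].
#' @param ds a [PixelDataset-class] or a bare pixels x bands matrix with the
#'   training band count.
#' @return list with `labels` (factor) and `prob` (n x k matrix, rows sum
#'   to 1). Probability ties resolve to the lowest class index.
#' @export
predictPixels <- function(model, ds) {
  stopifnot(is(model, "DNNModel"))
  X <- if (is(ds, "PixelDataset")) ds@X else as.matrix(ds)
  if (ncol(X) != length(model@bandMean))
    stop("pixel spectra have ", ncol(X), " bands but the model expects ",
         length(model@bandMean))
  X <- sweep(sweep(X, 2, model@bandMean), 2, model@bandSd, `/`)
  P <- .mlpForward(X, model@params)[[length(model@params$W) + 1L]]
  colnames(P) <- model@classLevels
  idx <- apply(P, 1, which.max)
  list(labels = factor(model@classLevels[idx], levels = model@classLevels),
       prob = P)
}
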
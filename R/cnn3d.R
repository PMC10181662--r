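## Seed-level classification with a 3-D convolutional network. Topology:
## two [conv3d -> ReLU -> maxpool] blocks, flatten, a fully-connected ReLU
## layer, and a softmax output. The spectral (band) axis is mapped to the
## convolution depth D; the seed chip's H x W are the spatial axes; input
## channel count is 1. Valid (no-padding) convolution throughout; pooling
## windows at the far border are clipped (replication-equivalent).

#' 3-D convolution (valid, single sample)
#'
#' `O[c',i,j,k] = sum_{c,d,h,w} I[c, i+d, j+h, k+w] * K[c',c,d,h,w] + bias[c']`
#' over all valid positions (no padding).
#'
#' @param input 4-D array `C x D x H x W`.
#' @param kernel 5-D array `C' x C x D' x H' x W'`; each kernel dim must not
#'   exceed the corresponding input dim.
#' @param bias numeric vector length `C'`.
#' @return 4-D array `C' x (D-D'+1) x (H-H'+1) x (W-W'+1)`.
#' @export
conv3dForward <- function(input, kernel, bias = NULL) {
  if (length(dim(input)) != 4L) stop("input must be a 4-D array C x D x H x W")
  if (length(dim(kernel)) != 5L) stop("kernel must be a 5-D array C' x C x D' x H' x W'")
  if (is.null(bias)) bias <- numeric(dim(kernel)[1])
  if (any(dim(kernel)[3:5] > dim(input)[2:4]))
    stop("kernel larger than input in at least one spatial dimension")
  storage.mode(input) <- "double"; storage.mode(kernel) <- "double"
  .conv3dFwd(input, kernel, as.numeric(bias))
}

#' 3-D max pooling (stride = window)
#'
#' Per-window maximum with stride equal to the window. Dimensions not
#' divisible by the pool size are handled by clipping the last window at the
#' border, which is equivalent to replication padding for a maximum.
#'
#' @param input 4-D array `C x D x H x W`.
#' @param pool integer(3) window `(d, h, w)`.
#' @return 4-D array `C x ceil(D/d) x ceil(H/h) x ceil(W/w)`.
#' @export
maxPool3d <- function(input, pool) {
  if (length(dim(input)) != 4L) stop("input must be a 4-D array C x D x H x W")
  pool <- as.integer(pool)
  if (length(pool) != 3L || any(pool < 1L)) stop("pool must be 3 positive integers")
  storage.mode(input) <- "double"
  .maxpool3dFwd(input, pool)$out
}

#' Configuration for the seed-level 3-D CNN
#'
#' @param convBlocks list of blocks, each `list(outChannels, kernel, pool)`
#'   with `kernel = c(D', H', W')` (band axis first) and `pool = c(d, h, w)`.
#'   Default: two blocks, 8 channels with 7x3x3 kernel then 16 channels with
#'   5x3x3, both pooled 2x2x2.
#' @param fcWidth width of the fully-connected hidden layer (default 64).
#' @param lr Adam learning rate (default 1e-3).
#' @param epochs training epochs (default 50).
#' @param batchSize minibatch size (default 8).
#' @param rngSeed master seed driving weight init and batch shuffling.
#' @return a config list used by [trainCNN3D()].
#' @export
cnn3dConfig <- function(convBlocks = list(
                          list(outChannels = 8L, kernel = c(7L, 3L, 3L), pool = c(2L, 2L, 2L)),
                          list(outChannels = 16L, kernel = c(5L, 3L, 3L), pool = c(2L, 2L, 2L))),
                        fcWidth = 64L, lr = 1e-3, epochs = 50L, batchSize = 8L,
                        rngSeed = 0L) {
  for (blk in convBlocks) {
    stopifnot(is.list(blk), all(c("outChannels", "kernel", "pool") %in% names(blk)),
              length(blk$kernel) == 3L, length(blk$pool) == 3L)
  }
  list(convBlocks = convBlocks, fcWidth = as.integer(fcWidth), lr = lr,
       epochs = as.integer(epochs), batchSize = as.integer(batchSize),
       rngSeed = as.integer(rngSeed))
}

#' Stratified train/validation/test split of a seed set
#'
#' Splits each class independently with largest-remainder rounding of the
#' requested fractions, so 40 items at `c(0.8, 0.1, 0.1)` give 32/4/4.
#' Remainder ties are broken in split order (train, val, test).
#'
#' @param set a [LabeledSeedSet-class].
#' @param fractions numeric(3) summing to 1 (default `c(0.8, 0.1, 0.1)`).
#' @param rngSeed seed for the within-class shuffle.
#' @return the set with its `split` slot assigned.
#' @export
splitDataset <- function(set, fractions = c(0.8, 0.1, 0.1), rngSeed = 0L) {
  stopifnot(is(set, "LabeledSeedSet"), length(fractions) == 3L)
  if (abs(sum(fractions) - 1) > 1e-9) stop("fractions must sum to 1")
  set.seed(rngSeed)
  split <- factor(rep(NA_character_, length(set@cubes)),
                  levels = c("train", "val", "test"))
  for (cl in levels(set@labels)) {
    idx <- which(set@labels == cl)
    n <- length(idx)
    target <- n * fractions
    counts <- floor(target)
    rem <- target - counts
    short <- n - sum(counts)
    if (short > 0) {
      give <- order(-rem, seq_along(rem))[seq_len(short)]
      counts[give] <- counts[give] + 1
    }
    if (any(counts < 1))
      stop("class '", cl, "' too small (", n,
           " items) for at least one item per split")
    idx <- sample(idx)
    split[idx[seq_len(counts[1])]] <- "train"
    split[idx[counts[1] + seq_len(counts[2])]] <- "val"
    split[idx[counts[1] + counts[2] + seq_len(counts[3])]] <- "test"
  }
  set@split <- split
  set
}

#' Spatial transform of a seed cube
#'
#' Applies one of the augmentation transforms to the spatial axes of a seed
#' chip; the spectral axis is untouched. Shifts fill with zeros (background).
#'
#' @param seed a [SeedCube-class].
#' @param type one of `"hflip"`, `"vflip"`, `"rot180"`, `"shift"`.
#' @param shift integer(2) `c(dr, dc)` used when `type = "shift"`.
#' @return a transformed [SeedCube-class].
#' @export
seedTransform <- function(seed, type = c("hflip", "vflip", "rot180", "shift"),
                          shift = c(0L, 0L)) {
  type <- match.arg(type)
  d <- dim(seed@data)
  a <- seed@data; m <- seed@mask
  if (type == "hflip") { a <- a[, d[2]:1, , drop = FALSE]; m <- m[, d[2]:1, drop = FALSE] }
  if (type == "vflip") { a <- a[d[1]:1, , , drop = FALSE]; m <- m[d[1]:1, , drop = FALSE] }
  if (type == "rot180") {
    a <- a[d[1]:1, d[2]:1, , drop = FALSE]; m <- m[d[1]:1, d[2]:1, drop = FALSE]
  }
  if (type == "shift") {
    dr <- as.integer(shift[1]); dc <- as.integer(shift[2])
    a2 <- array(0, d); m2 <- matrix(FALSE, d[1], d[2])
    srcR <- seq_len(d[1]) - dr; srcC <- seq_len(d[2]) - dc
    okR <- srcR >= 1 & srcR <= d[1]; okC <- srcC >= 1 & srcC <= d[2]
    a2[which(okR), which(okC), ] <- a[srcR[okR], srcC[okC], , drop = FALSE]
    m2[which(okR), which(okC)] <- m[srcR[okR], srcC[okC]]
    a <- a2; m <- m2
  }
  new("SeedCube", data = a, mask = m, grid = seed@grid,
      classLabel = seed@classLabel, exposureLabel = seed@exposureLabel,
      source = seed@source, offset = c(NA_real_, NA_real_))
}

#' Augment a seed set to a per-class total
#'
#' Adds spatially transformed copies (horizontal/vertical flips, 180-degree
#' rotation, small shifts of up to 2 px) of training originals until every
#' class reaches `perClassTotal` items. Originals are preserved untouched;
#' augmented items inherit their source's labels and are assigned to the
#' training split.
#'
#' @param set a [LabeledSeedSet-class].
#' @param perClassTotal target number of items per class (>= current count).
#' @param rngSeed seed for transform/source sampling.
#' @return the augmented [LabeledSeedSet-class].
#' @export
augmentSeedSet <- function(set, perClassTotal, rngSeed = 0L) {
  stopifnot(is(set, "LabeledSeedSet"))
  set.seed(rngSeed)
  transforms <- list(
    list(type = "hflip"), list(type = "vflip"), list(type = "rot180"),
    list(type = "shift", shift = c(2L, 0L)), list(type = "shift", shift = c(-2L, 0L)),
    list(type = "shift", shift = c(0L, 2L)), list(type = "shift", shift = c(0L, -2L)))
  haveSplit <- any(!is.na(set@split))
  newCubes <- list(); newLabels <- character(0); newSplit <- character(0)
  for (cl in levels(set@labels)) {
    clIdx <- which(set@labels == cl)
    if (length(clIdx) > perClassTotal)
      stop("class '", cl, "' already has ", length(clIdx),
           " items, more than perClassTotal = ", perClassTotal)
    srcIdx <- if (haveSplit) clIdx[set@split[clIdx] == "train"] else clIdx
    srcIdx <- srcIdx[!is.na(srcIdx)]
    if (!length(srcIdx)) stop("class '", cl, "' has no training originals to augment")
    need <- perClassTotal - length(clIdx)
    for (i in seq_len(need)) {
      src <- set@cubes[[srcIdx[sample.int(length(srcIdx), 1L)]]]
      tr <- transforms[[sample.int(length(transforms), 1L)]]
      aug <- seedTransform(src, tr$type, shift = tr$shift %||% c(0L, 0L))
      aug@source <- sprintf("%s:aug%d", src@source, i)
      newCubes[[length(newCubes) + 1L]] <- aug
      newLabels <- c(newLabels, cl)
      newSplit <- c(newSplit, "train")
    }
  }
  labels <- factor(c(as.character(set@labels), newLabels),
                   levels = levels(set@labels))
  split <- factor(c(as.character(set@split), newSplit),
                  levels = c("train", "val", "test"))
  new("LabeledSeedSet", cubes = c(set@cubes, newCubes), labels = labels,
      split = split)
}

## seed chip (H x W x B) -> network input array (C=1, D=B, H, W)
.cubeToInput <- function(sc) {
  a <- aperm(sc@data, c(3, 1, 2))
  dim(a) <- c(1L, dim(a))
  a
}

## forward through the conv stack for one sample, keeping caches for backprop
.convStackForward <- function(x, params, nBlocks) {
  caches <- vector("list", nBlocks)
  for (l in seq_len(nBlocks)) {
    z <- .conv3dFwd(x, params$K[[l]], params$cb[[l]])
    a <- pmax(z, 0)
    pl <- .maxpool3dFwd(a, params$pool[[l]])
    caches[[l]] <- list(input = x, pre = z, argmax = pl$argmax,
                        reluDim = dim(a), outDim = dim(pl$out))
    x <- pl$out
  }
  list(out = x, caches = caches)
}

.convStackBackward <- function(gOut, params, caches, nBlocks) {
  gK <- vector("list", nBlocks); gcb <- vector("list", nBlocks)
  g <- gOut
  for (l in rev(seq_len(nBlocks))) {
    ch <- caches[[l]]
    dim(g) <- ch$outDim
    g <- .maxpool3dBwd(g, ch$argmax, ch$reluDim)
    g <- g * (ch$pre > 0)
    bw <- .conv3dBwd(ch$input, params$K[[l]], g)
    gK[[l]] <- bw$gradKernel; gcb[[l]] <- bw$gradBias
    g <- bw$gradInput
  }
  list(gK = gK, gcb = gcb)
}

#' Train the seed-level 3-D CNN
#'
#' Trains the two-block 3-D convolutional classifier on the training split of
#' a labeled seed set with Adam on categorical cross-entropy. Deterministic
#' for a fixed `rngSeed` on a single thread.
#'
#' @param set a [LabeledSeedSet-class]; if its split is assigned, training
#'   uses the `train` items and reports validation metrics on `val`,
#'   otherwise all items are used for training.
#' @param cfg a [cnn3dConfig()] list.
#' @return a [CNN3DModel-class] with per-epoch history.
#' @export
trainCNN3D <- function(set, cfg = cnn3dConfig()) {
  stopifnot(is(set, "LabeledSeedSet"))
  classLevels <- levels(droplevels(set@labels))
  k <- length(classLevels)
  if (k < 2L) stop("need at least 2 classes to train a classifier")
  labels <- factor(as.character(set@labels), levels = classLevels)
  d1 <- dim(set@cubes[[1]]@data)
  for (sc in set@cubes)
    if (!identical(dim(sc@data), d1)) stop("all seed cubes must share dimensions")
  haveSplit <- any(!is.na(set@split))
  trIdx <- if (haveSplit) which(set@split == "train") else seq_along(set@cubes)
  vaIdx <- if (haveSplit) which(set@split == "val") else integer(0)
  if (!length(trIdx)) stop("no training items")

  set.seed(cfg$rngSeed)
  nBlocks <- length(cfg$convBlocks)
  params <- list(K = list(), cb = list(), pool = list())
  inDim <- c(1L, d1[3], d1[1], d1[2])   # C, D(bands), H, W
  for (l in seq_len(nBlocks)) {
    blk <- cfg$convBlocks[[l]]
    kd <- as.integer(blk$kernel); Cp <- as.integer(blk$outChannels)
    if (any(kd > inDim[2:4]))
      stop("conv block ", l, " kernel (", paste(kd, collapse = "x"),
           ") does not fit its input (", paste(inDim[2:4], collapse = "x"), ")")
    fanIn <- inDim[1] * prod(kd)
    params$K[[l]] <- array(rnorm(Cp * inDim[1] * prod(kd), sd = sqrt(2 / fanIn)),
                           c(Cp, inDim[1], kd))
    params$cb[[l]] <- numeric(Cp)
    params$pool[[l]] <- as.integer(blk$pool)
    convOut <- inDim[2:4] - kd + 1L
    poolOut <- as.integer(ceiling(convOut / params$pool[[l]]))
    inDim <- c(Cp, poolOut)
  }
  flatN <- prod(inDim)
  params$W1 <- .heInit(flatN, cfg$fcWidth); params$b1 <- numeric(cfg$fcWidth)
  params$W2 <- .heInit(cfg$fcWidth, k); params$b2 <- numeric(k)

  flatParams <- function(p) c(p$K, p$cb, list(p$W1, p$b1, p$W2, p$b2))
  unflat <- function(v, p) {
    p$K <- v[seq_len(nBlocks)]
    p$cb <- v[nBlocks + seq_len(nBlocks)]
    p$W1 <- v[[2 * nBlocks + 1]]; p$b1 <- as.numeric(v[[2 * nBlocks + 2]])
    p$W2 <- v[[2 * nBlocks + 3]]; p$b2 <- as.numeric(v[[2 * nBlocks + 4]])
    p
  }
  adam <- .adamInit(flatParams(params))

  inputs <- lapply(set@cubes, .cubeToInput)
  yInt <- as.integer(labels)
  history <- data.frame()
  for (epoch in seq_len(cfg$epochs)) {
    ord <- sample(trIdx)
    batches <- split(ord, ceiling(seq_along(ord) / cfg$batchSize))
    epLoss <- 0; epAcc <- 0; nSeen <- 0
    for (bt in batches) {
      nb <- length(bt)
      feats <- matrix(0, nb, flatN)
      caches <- vector("list", nb)
      for (s in seq_len(nb)) {
        fw <- .convStackForward(inputs[[bt[s]]], params, nBlocks)
        feats[s, ] <- as.numeric(fw$out)
        caches[[s]] <- fw$caches
      }
      Z1 <- sweep(feats %*% params$W1, 2, params$b1, `+`)
      A1 <- pmax(Z1, 0)
      P <- .softmaxRows(sweep(A1 %*% params$W2, 2, params$b2, `+`))
      Y <- .oneHot(yInt[bt], k)
      loss <- .crossEntropy(P, yInt[bt])
      if (!is.finite(loss)) stop("training diverged: non-finite loss")
      epLoss <- epLoss + loss * nb
      epAcc <- epAcc + sum(max.col(P, ties.method = "first") == yInt[bt])
      nSeen <- nSeen + nb
      delta2 <- (P - Y) / nb
      gW2 <- crossprod(A1, delta2); gb2 <- colSums(delta2)
      delta1 <- (delta2 %*% t(params$W2)) * (Z1 > 0)
      gW1 <- crossprod(feats, delta1); gb1 <- colSums(delta1)
      gFeat <- delta1 %*% t(params$W1)
      gK <- lapply(params$K, function(kk) array(0, dim(kk)))
      gcb <- lapply(params$cb, function(bb) numeric(length(bb)))
      for (s in seq_len(nb)) {
        bwd <- .convStackBackward(gFeat[s, ], params, caches[[s]], nBlocks)
        for (l in seq_len(nBlocks)) {
          gK[[l]] <- gK[[l]] + bwd$gK[[l]]
          gcb[[l]] <- gcb[[l]] + bwd$gcb[[l]]
        }
      }
      upd <- .adamStep(flatParams(params),
                       c(gK, gcb, list(gW1, gb1, gW2, gb2)),
                       adam, cfg$lr)
      adam <- upd$state
      params <- unflat(upd$params, params)
    }
    row <- data.frame(epoch = epoch, trainLoss = epLoss / nSeen,
                      trainAcc = epAcc / nSeen,
                      valLoss = NA_real_, valAcc = NA_real_)
    if (length(vaIdx)) {
      vp <- .cnnPredictRaw(params, cfg, inputs[vaIdx], flatN)
      row$valLoss <- .crossEntropy(vp, yInt[vaIdx])
      row$valAcc <- mean(max.col(vp, ties.method = "first") == yInt[vaIdx])
    }
    history <- rbind(history, row)
  }
  new("CNN3DModel", params = params, config = cfg, classLevels = classLevels,
      inputDim = as.integer(d1), history = history)
}

.cnnPredictRaw <- function(params, cfg, inputs, flatN) {
  nBlocks <- length(cfg$convBlocks)
  feats <- matrix(0, length(inputs), flatN)
  for (s in seq_along(inputs))
    feats[s, ] <- as.numeric(.convStackForward(inputs[[s]], params, nBlocks)$out)
  A1 <- pmax(sweep(feats %*% params$W1, 2, params$b1, `+`), 0)
  .softmaxRows(sweep(A1 %*% params$W2, 2, params$b2, `+`))
}

#' Predict classes for seed cubes
#'
#' @param model a [CNN3DModel-class].
#' @param cubes list of [SeedCube-class] (or a [LabeledSeedSet-class]) with
#'   dimensions matching the training cubes.
#' @return list with `labels` (factor) and `prob` (n x k matrix, rows sum
#'   to 1). Probability ties resolve to the lowest class index.
#' @export
predictCNN3D <- function(model, cubes) {
  stopifnot(is(model, "CNN3DModel"))
  if (is(cubes, "LabeledSeedSet")) cubes <- cubes@cubes
  if (is(cubes, "SeedCube")) cubes <- list(cubes)
  for (sc in cubes)
    if (!identical(as.integer(dim(sc@data)), model@inputDim))
      stop("seed cube dimensions ", paste(dim(sc@data), collapse = "x"),
           " do not match training dimensions ",
           paste(model@inputDim, collapse = "x"))
  inputs <- lapply(cubes, .cubeToInput)
  P <- .cnnPredictRaw(model@params, model@config, inputs, nrow(model@params$W1))
  colnames(P) <- model@classLevels
  idx <- apply(P, 1, which.max)           # first max: ties -> lowest index
  list(labels = factor(model@classLevels[idx], levels = model@classLevels),
       prob = P)
}
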
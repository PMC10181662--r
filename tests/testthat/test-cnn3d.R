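# small labeled set builder: k classes of n seeds each, dims h x w x nb
tinySeedSet <- function(nPer = 10L, classes = c("A", "B"), h = 8L, w = 8L,
                        nb = 6L, sepScale = 1, seed = 1L) {
  set.seed(seed)
  cubes <- list(); labels <- character(0)
  for (ci in seq_along(classes)) {
    mu <- 0.3 + 0.25 * sepScale * sin(seq_len(nb) / nb * pi + ci)
    for (i in seq_len(nPer)) {
      sc <- seedCubeFixture(h, w, nb, value = 0, a = h / 3, b = w / 4,
                            class = classes[ci],
                            source = sprintf("p%d#%d", ci, i))
      noise <- array(rnorm(h * w * nb, sd = 0.02), c(h, w, nb))
      for (k in seq_len(nb))
        sc@data[, , k][sc@mask] <- mu[k] + noise[, , k][sc@mask]
      cubes[[length(cubes) + 1L]] <- sc
      labels <- c(labels, classes[ci])
    }
  }
  seedHSI:::labeledSeedSet(cubes, factor(labels, levels = classes))
}

test_that("splitDataset applies stratified largest-remainder rounding", {
  set40 <- tinySeedSet(40L, c("A"), nb = 2L)
  # single class cannot be trained but can be split
  sp <- splitDataset(set40, c(0.8, 0.1, 0.1), rngSeed = 1)
  expect_equal(as.integer(table(sp@split)), c(32L, 4L, 4L))
  set5x40 <- tinySeedSet(40L, c("A", "B", "C", "D", "E"), nb = 2L)
  sp5 <- splitDataset(set5x40, c(0.8, 0.1, 0.1), rngSeed = 1)
  expect_equal(as.integer(table(sp5@split)), c(160L, 20L, 20L))
  for (cl in levels(sp5@labels))
    expect_equal(as.integer(table(sp5@split[sp5@labels == cl])), c(32L, 4L, 4L))
  # deterministic given the seed; every cube in exactly one split
  sp5b <- splitDataset(set5x40, c(0.8, 0.1, 0.1), rngSeed = 1)
  expect_identical(sp5@split, sp5b@split)
  expect_false(any(is.na(sp5@split)))
  expect_error(splitDataset(tinySeedSet(5L, c("A", "B"), nb = 2L),
                            c(0.8, 0.1, 0.1)), "too small")
  expect_error(splitDataset(set40, c(0.5, 0.2, 0.2)), "sum to 1")
})

test_that("augmentation reaches the per-class total preserving originals", {
  set30 <- tinySeedSet(30L, c("A", "B"), nb = 3L)
  sp <- splitDataset(set30, c(0.8, 0.1, 0.1), rngSeed = 2)
  aug <- augmentSeedSet(sp, perClassTotal = 40L, rngSeed = 2)
  expect_equal(as.integer(table(aug@labels)), c(40L, 40L))
  # the 60 originals are untouched and keep their split
  for (i in seq_along(sp@cubes)) {
    expect_identical(aug@cubes[[i]]@data, sp@cubes[[i]]@data)
    expect_identical(aug@split[i], sp@split[i])
  }
  # new items are training items with labels equal to their source class
  newIdx <- seq(length(sp@cubes) + 1L, length(aug@cubes))
  expect_true(all(aug@split[newIdx] == "train"))
  for (i in newIdx) {
    srcName <- sub(":aug.*$", "", aug@cubes[[i]]@source)
    src <- Find(function(s) s@source == srcName, sp@cubes)
    expect_identical(as.character(aug@cubes[[i]]@classLabel), src@classLabel)
  }
  expect_error(augmentSeedSet(sp, perClassTotal = 10L), "more than")
})

test_that("flip transforms are involutions and spectra are untouched", {
  sc <- seedCubeFixture(8, 6, 4, value = 0)
  set.seed(3)
  sc@data <- array(runif(8 * 6 * 4), c(8, 6, 4))
  for (type in c("hflip", "vflip", "rot180")) {
    once <- seedTransform(sc, type)
    twice <- seedTransform(once, type)
    expect_identical(twice@data, sc@data, info = type)
    expect_identical(twice@mask, sc@mask, info = type)
    # per-band content is permuted spatially, never mixed across bands
    for (k in 1:4)
      expect_equal(sort(as.numeric(once@data[, , k])),
                   sort(as.numeric(sc@data[, , k])), info = type)
  }
  shifted <- seedTransform(sc, "shift", shift = c(2, 0))
  expect_equal(shifted@data[3:8, , ], sc@data[1:6, , ])
  expect_true(all(shifted@data[1:2, , ] == 0))
})

test_that("training runs, declines in loss, and predicts deterministically", {
  set <- tinySeedSet(12L, c("A", "B", "C"), h = 8L, w = 8L, nb = 6L, seed = 4L)
  cfg <- cnn3dConfig(convBlocks = list(
                       list(outChannels = 4L, kernel = c(3L, 2L, 2L), pool = c(2L, 2L, 2L)),
                       list(outChannels = 6L, kernel = c(2L, 2L, 2L), pool = c(2L, 2L, 2L))),
                     fcWidth = 16L, epochs = 3L, batchSize = 6L, rngSeed = 7L)
  m <- trainCNN3D(set, cfg)
  expect_equal(nrow(m@history), 3)
  # optimization makes progress over the first epochs on this easy fixture
  expect_lt(m@history$trainLoss[3], m@history$trainLoss[1])
  pr <- predictCNN3D(m, set@cubes)
  expect_equal(rowSums(pr$prob), rep(1, length(set@cubes)), tolerance = 1e-6)
  # bit-reproducible given the seed
  m2 <- trainCNN3D(set, cfg)
  expect_identical(m@params$W2, m2@params$W2)
  expect_identical(predictCNN3D(m2, set@cubes)$labels, pr$labels)
  # a duplicated cube gets the duplicate's prediction
  dup <- c(set@cubes[1], set@cubes[1])
  prd <- predictCNN3D(m, dup)
  expect_identical(prd$labels[1], prd$labels[2])
  # zero-epoch training still yields a working (untrained) model
  m0 <- trainCNN3D(set, cnn3dConfig(convBlocks = cfg$convBlocks, fcWidth = 16L,
                                    epochs = 0L, rngSeed = 7L))
  expect_equal(nrow(m0@history), 0)
  expect_length(predictCNN3D(m0, set@cubes[1:2])$labels, 2)
})

test_that("training rejects invalid inputs and prediction checks dimensions", {
  single <- tinySeedSet(6L, "A", nb = 4L)
  expect_error(trainCNN3D(single), "at least 2 classes")
  set <- tinySeedSet(6L, c("A", "B"), h = 8L, w = 8L, nb = 4L)
  expect_error(trainCNN3D(set, cnn3dConfig(convBlocks = list(
    list(outChannels = 2L, kernel = c(9L, 3L, 3L), pool = c(2L, 2L, 2L))),
    epochs = 1L)), "does not fit")
  cfgSmall <- cnn3dConfig(convBlocks = list(
    list(outChannels = 2L, kernel = c(2L, 2L, 2L), pool = c(2L, 2L, 2L))),
    fcWidth = 8L, epochs = 1L, batchSize = 4L, rngSeed = 1L)
  m <- trainCNN3D(set, cfgSmall)
  other <- seedCubeFixture(10, 10, 4)
  expect_error(predictCNN3D(m, list(other)), "do not match")
})

test_that("equal logits tie-break to the lowest class index", {
  set <- tinySeedSet(6L, c("A", "B"), nb = 4L)
  m0 <- trainCNN3D(set, cnn3dConfig(convBlocks = list(
    list(outChannels = 2L, kernel = c(2L, 2L, 2L), pool = c(2L, 2L, 2L))),
    fcWidth = 4L, epochs = 0L, rngSeed = 1L))
  # force identical logits by zeroing the output layer
  m0@params$W2[] <- 0; m0@params$b2[] <- 0
  pr <- predictCNN3D(m0, set@cubes[1:3])
  expect_true(all(pr$labels == "A"))
  expect_equal(pr$prob[1, ], c(A = 0.5, B = 0.5))
})
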
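# gaussian-bump pixel classes: easy fixture for classifier sanity checks
tinyPixels <- function(nPer = 200L, k = 3L, nb = 16L, sep = 1, noise = 0.05,
                       seed = 1L, nSeeds = 4L) {
  set.seed(seed)
  X <- NULL; y <- character(0); org <- NULL
  for (ci in seq_len(k)) {
    mu <- 0.4 + 0.2 * sep * sin(seq_len(nb) / nb * 2 * pi + ci * 2)
    Xc <- matrix(rep(mu, each = nPer), nPer) +
      matrix(rnorm(nPer * nb, sd = noise), nPer)
    X <- rbind(X, Xc)
    y <- c(y, rep(paste0("C", ci), nPer))
    org <- rbind(org, data.frame(
      panel = "p1", row = seq_len(nPer), col = ci,
      seed = paste0("p1#", (ci - 1L) * nSeeds + rep(seq_len(nSeeds),
                                                    length.out = nPer))))
  }
  seedHSI:::pixelDataset(X, y, org)
}

test_that("buildPixelDataset emits one row per masked pixel in stable order", {
  s1 <- seedCubeFixture(8, 8, 3, value = 0.5, source = "p1#1")
  s2 <- seedCubeFixture(8, 8, 3, value = 0.7, source = "p1#2")
  ds <- buildPixelDataset(list(s1, s2))
  expect_equal(nrow(ds@X), sum(s1@mask) + sum(s2@mask))
  expect_equal(ncol(ds@X), 3)
  # background never appears: every row carries seed reflectance, not zero
  expect_true(all(ds@X %in% c(0.5, 0.7)))
  # row order: seeds in order, then (row, col); origins in panel coordinates
  expect_equal(ds@origin$seed[1], "p1#1")
  expect_true(!is.unsorted(order(match(ds@origin$seed, c("p1#1", "p1#2")))))
  # label by exposure instead of class
  dse <- buildPixelDataset(list(s1, s2), labelBy = "exposure")
  expect_equal(levels(dse@y), "168")
  empty <- seedCubeFixture(); empty@mask[,] <- FALSE
  expect_error(buildPixelDataset(list(empty)), "no masked pixels")
})

test_that("pixel row count equals the summed region areas", {
  models <- makeClassModels(2, rngSeed = 3, classNames = c("A", "B"))
  sp <- panelSpec(70, 70, tinyGrid(5L),
                  data.frame(class = c("A", "B"), exposure = c(168, 204),
                             a = c(7, 6), b = c(4, 5), centerRow = c(20, 52),
                             centerCol = c(20, 52), theta = c(0, 0.8)),
                  rngSeed = 3)
  pan <- generatePanel(sp, models)
  calib <- calibrate(pan$raw, pan$refs)
  seeds <- extractSeedCubes(calib, pan$truth$regions, canonicalHW = c(24, 24))
  ds <- buildPixelDataset(seeds)
  expect_equal(nrow(ds@X),
               sum(vapply(pan$truth$regions, function(r) r@areaPx, integer(1))))
})

test_that("splitPixels splits each seed 70/30 deterministically", {
  ds <- tinyPixels(100L, k = 2L, nSeeds = 10L)   # each seed: 10 pixels
  sp <- splitPixels(ds, 0.7, rngSeed = 5)
  for (sid in unique(ds@origin$seed)) {
    expect_equal(sum(sp$train@origin$seed == sid), 7)
    expect_equal(sum(sp$val@origin$seed == sid), 3)
  }
  # identical on repeat; union is everything, disjoint
  sp2 <- splitPixels(ds, 0.7, rngSeed = 5)
  expect_identical(sp$train@X, sp2$train@X)
  expect_equal(nrow(sp$train@X) + nrow(sp$val@X), nrow(ds@X))
  key <- function(d) paste(d@origin$seed, d@origin$row, d@origin$col)
  expect_length(intersect(key(sp$train), key(sp$val)), 0)
  # a 1-pixel seed goes wholly to training, with a message
  one <- seedHSI:::pixelDataset(ds@X[1, , drop = FALSE],
                                factor("C1"), ds@origin[1, ])
  expect_message(sp1 <- splitPixels(one, 0.7), "wholly to training")
  expect_equal(nrow(sp1$train@X), 1)
  # global split mode
  spg <- splitPixels(ds, 0.7, rngSeed = 5, perSeed = FALSE)
  expect_equal(nrow(spg$train@X), round(0.7 * nrow(ds@X)))
})

test_that("the DNN learns separable pixel classes and fails on permuted labels", {
  ds <- tinyPixels(250L, k = 3L, nb = 12L, seed = 6L)
  sp <- splitPixels(ds, 0.7, rngSeed = 6)
  cfg <- dnnConfig(hiddenWidths = c(64L, 64L, 32L, 32L, 32L, 16L,
                                    16L, 16L, 8L, 8L, 8L, 8L),
                   epochs = 8L, batchSize = 64L, rngSeed = 6L)
  m <- trainDNN(sp$train, cfg, val = sp$val)
  pr <- predictPixels(m, sp$val)
  acc <- mean(as.character(pr$labels) == as.character(sp$val@y))
  expect_gte(acc, 0.95)
  # loss decreases over the first epochs
  expect_lt(m@history$trainLoss[3], m@history$trainLoss[1])
  # negative control: permuting the labels destroys the class signal, so
  # held-out accuracy collapses toward chance (far below the true-label fit)
  set.seed(7)
  perm <- seedHSI:::pixelDataset(sp$train@X, sample(sp$train@y), sp$train@origin)
  mp <- trainDNN(perm, cfg)
  accPerm <- mean(as.character(predictPixels(mp, sp$val)$labels) ==
                  as.character(sp$val@y))
  expect_lt(accPerm, 0.6)
})

test_that("DNN training is reproducible and prediction validates shapes", {
  ds <- tinyPixels(80L, k = 2L, nb = 8L)
  cfg <- dnnConfig(hiddenWidths = rep(8L, 12L), epochs = 2L, batchSize = 32L,
                   rngSeed = 9L)
  m1 <- trainDNN(ds, cfg)
  m2 <- trainDNN(ds, cfg)
  expect_identical(m1@params$W[[1]], m2@params$W[[1]])
  expect_identical(m1@history, m2@history)
  pr <- predictPixels(m1, ds)
  expect_equal(rowSums(pr$prob), rep(1, nrow(ds@X)), tolerance = 1e-6)
  expect_identical(pr$labels, predictPixels(m1, ds)$labels)
  expect_error(predictPixels(m1, matrix(0, 3, 5)), "expects")
  single <- seedHSI:::pixelDataset(ds@X, factor(rep("C1", nrow(ds@X))),
                                   ds@origin)
  expect_error(trainDNN(single, cfg), "at least 2 classes")
})

test_that("equal logits tie-break to the lowest class and the net is 12 layers deep", {
  ds <- tinyPixels(40L, k = 2L, nb = 6L)
  cfg <- dnnConfig(hiddenWidths = rep(4L, 12L), epochs = 0L, rngSeed = 1L)
  m <- trainDNN(ds, cfg)
  expect_length(m@params$W, 13)          # 12 hidden + softmax output
  last <- length(m@params$W)
  m@params$W[[last]][] <- 0; m@params$b[[last]][] <- 0
  pr <- predictPixels(m, ds@X[1:5, ])
  expect_true(all(pr$labels == "C1"))
})
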
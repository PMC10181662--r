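test_that("confusionMatrix tallies truth x prediction", {
  M <- confusionMatrix(c(1, 1, 2), c(1, 2, 2), k = 2)
  expect_equal(unname(M), matrix(c(1L, 0L, 1L, 1L), 2))
  expect_true(all(confusionMatrix(integer(0), integer(0), k = 3) == 0))
  perfect <- confusionMatrix(rep(1:3, each = 4), rep(1:3, each = 4), k = 3)
  expect_equal(unname(perfect), diag(4L, 3))
  expect_error(confusionMatrix(1:3, 1:2), "equal length")
  # brute-force tally oracle on random seeded labels
  set.seed(21)
  truth <- sample(1:4, 300, replace = TRUE)
  pred <- sample(1:4, 300, replace = TRUE)
  M <- confusionMatrix(truth, pred, k = 4)
  for (i in 1:4) for (j in 1:4)
    expect_equal(M[i, j], sum(truth == i & pred == j))
})

test_that("binaryMetrics computes the exact formulas with undefined flags", {
  bm <- binaryMetrics(8, 2, 9, 1)
  expect_equal(bm$precision, 0.8)
  expect_equal(bm$recall, 8 / 9)
  expect_equal(bm$f1, 2 * 0.8 * (8 / 9) / (0.8 + 8 / 9))
  expect_equal(round(bm$f1, 5), 0.84211)
  expect_equal(bm$accuracy, 0.85)
  expect_length(bm$undefined, 0)
  perfect <- binaryMetrics(5, 0, 7, 0)
  expect_true(all(unlist(perfect[c("precision", "recall", "f1", "accuracy")]) == 1))
  flagged <- binaryMetrics(0, 3, 5, 0)
  expect_equal(flagged$precision, 0)
  expect_true("recall" %in% flagged$undefined)   # TP + FN = 0
  expect_error(binaryMetrics(-1, 0, 0, 0), "non-negative")
})

test_that("multiclassReport reproduces the hand-computed kappa fixture", {
  # rows are truth: [[45, 5], [15, 35]] -> Po 0.8, Pe 0.5, kappa 0.6
  M <- matrix(c(45, 15, 5, 35), 2)
  rep <- multiclassReport(M)
  expect_equal(rep@OA, 0.8)
  expect_equal(rep@kappa, 0.6)
  expect_equal(rep@AA, 0.8)        # both one-vs-rest accuracies are 0.8 here
  # k = 2 rows agree exactly with the binary formulas
  bm <- binaryMetrics(45, 15, 35, 5)
  expect_equal(rep@perClass$precision[1], bm$precision)
  expect_equal(rep@perClass$recall[1], bm$recall)
  expect_equal(rep@perClass$f1[1], bm$f1)
})

test_that("multiclassReport degenerate and identity cases", {
  I3 <- diag(10L, 3)
  rep <- multiclassReport(I3)
  expect_equal(rep@OA, 1); expect_equal(rep@AA, 1); expect_equal(rep@kappa, 1)
  # everything predicted as one class on balanced 2-class truth: kappa 0
  one <- matrix(c(50, 50, 0, 0), 2)
  expect_equal(multiclassReport(one)@kappa, 0)
  expect_error(multiclassReport(matrix(0, 2, 2)), "empty")
  expect_error(multiclassReport(matrix(1, 2, 3)), "square")
})

test_that("overall accuracy equals support-weighted recall and kappa stays bounded", {
  set.seed(22)
  for (rep in 1:10) {
    k <- sample(2:5, 1)
    M <- matrix(rpois(k * k, lambda = 8), k)
    if (sum(M) == 0) next
    r <- multiclassReport(M)
    expect_equal(r@OA, unname(r@weightedAvg["recall"]), tolerance = 1e-12)
    expect_gte(r@kappa, -1); expect_lte(r@kappa, 1)
    offDiag <- sum(M) - sum(diag(M))
    if (r@kappa == 1) expect_equal(offDiag, 0)
    if (offDiag == 0 && sum(M) > 0) expect_equal(r@kappa, 1)
  }
})

test_that("renderMap paints predictions into the panel frame", {
  origins <- data.frame(row = c(2, 2, 3, 5), col = c(2, 3, 2, 5))
  preds <- factor(c("A", "A", "A", "B"))
  map <- renderMap(c(6, 7), origins, preds)
  expect_equal(dim(map@labels), c(6, 7))
  expect_equal(sum(map@labels > 0), 4)
  expect_equal(map@labels[2, 2], 1L)
  expect_equal(map@labels[5, 5], 2L)
  expect_equal(map@labels[1, 1], 0L)     # background sentinel
  # all-one-class: a single colour over the foreground
  mono <- renderMap(c(6, 7), origins, factor(rep("A", 4)))
  expect_equal(sort(unique(as.vector(mono@labels))), c(0L, 1L))
  expect_error(renderMap(c(4, 4), data.frame(row = 5, col = 1), factor("A")),
               "outside")
  # PNG + legend sidecar are written
  f <- tempfile(fileext = ".png")
  renderMap(c(6, 7), origins, preds, pngPath = f)
  expect_true(file.exists(f))
  legend <- jsonlite::read_json(paste0(f, ".legend.json"))
  expect_equal(legend$classes$A, 1L)
})

test_that("the ground-truth map of a generated panel equals the generator raster", {
  models <- makeClassModels(2, separation = 1, rngSeed = 1, noiseSd = 0,
                            classNames = c("A", "B"))
  sp <- panelSpec(80, 80, tinyGrid(6L),
                  data.frame(class = c("A", "B"), exposure = c(168, 240),
                             a = c(8, 7), b = c(5, 4), centerRow = c(25, 60),
                             centerCol = c(25, 60), theta = c(0.3, 1.2)),
                  rngSeed = 1)
  pan <- generatePanel(sp, models)
  calib <- calibrate(pan$raw, pan$refs)
  seeds <- extractSeedCubes(calib, pan$truth$regions, canonicalHW = c(24, 24),
                            panelId = "p")
  for (i in seq_along(seeds)) seeds[[i]]@classLabel <- pan$truth$seedInfo$class[i]
  px <- buildPixelDataset(seeds)
  map <- renderMap(dim(pan$truth$raster), px@origin, px@y)
  classIdx <- match(c("A", "B"), levels(px@y))
  expected <- pan$truth$raster
  expected[expected > 0] <- classIdx[expected[expected > 0]]
  expect_identical(unname(map@labels), unname(expected))
})

test_that("pcaTsneEmbed returns 2-D coordinates with PCA variance ordering", {
  set.seed(23)
  n <- 240
  cls <- rep(1:3, each = n / 3)
  X <- matrix(rnorm(n * 20, sd = 0.05), n, 20) + outer(cls, 1:20, function(c, b)
    0.3 * sin(b / 3 + c))
  emb <- suppressWarnings(pcaTsneEmbed(X, nComponents = 10, rngSeed = 1,
                                       perplexity = 20))
  expect_equal(dim(emb$coords), c(n, 2))
  expect_true(all(diff(emb$explainedVariance) <= 1e-9))
  # classes separate: between-class mean distance exceeds within-class
  D <- as.matrix(dist(emb$coords))
  same <- outer(cls, cls, `==`) & upper.tri(D)
  diff <- outer(cls, cls, `!=`) & upper.tri(D)
  expect_gt(mean(D[diff]), mean(D[same]))
  # component count shrinks with warning when n is small
  expect_warning(pcaTsneEmbed(X[1:20, ], nComponents = 50, rngSeed = 1,
                              perplexity = 5),
                 "reducing components")
})
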
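test_that("class mean distances scale linearly with separation", {
  g <- tinyGrid(24L)
  m0 <- makeClassModels(3, separation = 0, rngSeed = 5)
  mus0 <- lapply(m0, classMeanSpectrum, grid = g)
  expect_equal(mus0[[1]], mus0[[2]])
  expect_equal(mus0[[2]], mus0[[3]])
  d12 <- function(models) {
    mus <- lapply(models, classMeanSpectrum, grid = g)
    sqrt(sum((mus[[1]] - mus[[2]])^2))
  }
  d1 <- d12(makeClassModels(3, separation = 0.4, rngSeed = 5))
  d2 <- d12(makeClassModels(3, separation = 0.8, rngSeed = 5))
  expect_equal(d2 / d1, 2, tolerance = 1e-6)
  # deterministic per seed
  expect_equal(d1, d12(makeClassModels(3, separation = 0.4, rngSeed = 5)))
  # amplitudes non-negative, means within [0, 1]
  for (m in makeClassModels(4, separation = 1.5, rngSeed = 2)) {
    expect_true(all(m@bumps$amplitude >= 0))
    mu <- classMeanSpectrum(m, g)
    expect_true(all(mu >= 0 & mu <= 1))
  }
})

test_that("exposure applies a small within-class amplitude shift", {
  g <- tinyGrid(24L)
  m <- makeClassModels(2, rngSeed = 1)[[1]]
  lo <- classMeanSpectrum(m, g, exposure = 168)
  mid <- classMeanSpectrum(m, g, exposure = 204)
  hi <- classMeanSpectrum(m, g, exposure = 240)
  withinShift <- sqrt(sum((hi - lo)^2))
  expect_gt(withinShift, 0)
  ms <- makeClassModels(2, rngSeed = 1)
  between <- sqrt(sum((classMeanSpectrum(ms[[1]], g) -
                       classMeanSpectrum(ms[[2]], g))^2))
  expect_lt(withinShift, between)      # exposure effect smaller than class effect
})

test_that("calibration inverts the panel generator exactly at zero noise", {
  models <- makeClassModels(2, rngSeed = 4, noiseSd = 0, classNames = c("A", "B"))
  sp <- panelSpec(60, 60, tinyGrid(8L),
                  data.frame(class = c("A", "B"), exposure = c(168, 240),
                             a = c(7, 6), b = c(4, 4), centerRow = c(18, 44),
                             centerCol = c(18, 44), theta = c(0.2, 1.0)),
                  rngSeed = 4)
  pan <- generatePanel(sp, models)
  calib <- calibrate(pan$raw, pan$refs)
  expect_equal(cubeData(calib), cubeData(pan$reflectance), tolerance = 1e-12)
  expect_equal(length(pan$truth$regions), 2)
  expect_equal(sort(unique(as.vector(pan$truth$raster))), c(0L, 1L, 2L))
})

test_that("calibrated seed spectra estimate the class means within sampling error", {
  models <- makeClassModels(2, rngSeed = 8, noiseSd = 0.02, classNames = c("A", "B"))
  sp <- panelSpec(60, 60, tinyGrid(8L),
                  data.frame(class = c("A", "B"), exposure = c(204, 204),
                             a = c(8, 8), b = c(5, 5), centerRow = c(18, 44),
                             centerCol = c(18, 44), theta = c(0, 0)),
                  rngSeed = 8)
  pan <- generatePanel(sp, models)
  calib <- calibrate(pan$raw, pan$refs)
  for (i in 1:2) {
    reg <- pan$truth$regions[[i]]
    cls <- pan$truth$seedInfo$class[i]
    mu <- classMeanSpectrum(models[[match(cls, c("A", "B"))]], tinyGrid(8L), 204)
    n <- reg@areaPx
    est <- vapply(1:8, function(k) mean(cubeData(calib)[, , k][reg@mask]),
                  numeric(1))
    expect_true(all(abs(est - mu) < 3 * 0.02 / sqrt(n) + 1e-9))
  }
})

test_that("overlapping or near-touching seeds are rejected", {
  models <- makeClassModels(2, rngSeed = 1, classNames = c("A", "B"))
  sp <- panelSpec(50, 50, tinyGrid(4L),
                  data.frame(class = c("A", "B"), exposure = c(168, 168),
                             a = c(8, 8), b = c(6, 6), centerRow = c(25, 25),
                             centerCol = c(20, 32), theta = c(0, 0)),
                  rngSeed = 1)
  expect_error(generatePanel(sp, models), "overlap")
})

test_that("generateDataset delivers the requested class totals deterministically", {
  ds <- generateDataset(4, classNames = c("A", "B", "C"),
                        grid = tinyGrid(6L), canonicalHW = c(32, 32),
                        aRange = c(6, 8), bRange = c(4, 5),
                        seedsPerPanel = 6L, rngSeed = 11)
  expect_equal(as.integer(table(ds$seedSet@labels)), rep(4L, 3))
  expect_length(ds$seedSet@cubes, 12)
  expect_equal(nlevels(ds$pixels@y), 3)
  # exposures cycle through the schedule
  expos <- vapply(ds$seedSet@cubes, function(s) s@exposureLabel, numeric(1))
  expect_true(all(expos %in% riceExposures()))
  # bit-identical rebuild with the same seed
  ds2 <- generateDataset(4, classNames = c("A", "B", "C"),
                         grid = tinyGrid(6L), canonicalHW = c(32, 32),
                         aRange = c(6, 8), bRange = c(4, 5),
                         seedsPerPanel = 6L, rngSeed = 11)
  expect_identical(ds$pixels@X, ds2$pixels@X)
  expect_identical(ds$seedSet@cubes[[5]]@data, ds2$seedSet@cubes[[5]]@data)
})

test_that("segmentation recovers generated seeds across simulation seeds", {
  found <- 0L; expected <- 0L
  for (seed in 0:9) {
    set.seed(seed)
    seeds <- seedHSI:::.layoutSeeds(110L, 110L, 4L, c(6, 9), c(4, 5),
                                    rep(c("A", "B"), 2), rep(168, 4))
    models <- makeClassModels(2, rngSeed = seed, classNames = c("A", "B"))
    pan <- generatePanel(panelSpec(110L, 110L, tinyGrid(6L), seeds,
                                   rngSeed = seed), models)
    calib <- calibrate(pan$raw, pan$refs)
    regions <- segmentPanel(calib, minArea = 20)
    expected <- expected + 4L
    found <- found + length(regions)
  }
  expect_gte(found / expected, 0.95)
})
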
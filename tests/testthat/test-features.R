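test_that("boundaryDiameter matches analytic cases", {
  sq <- rbind(c(0, 0), c(0, 1), c(1, 0), c(1, 1))
  res <- boundaryDiameter(sq)
  expect_equal(res$diameter, sqrt(2))
  expect_equal(boundaryDiameter(rbind(c(0, 0), c(3, 4)))$diameter, 5)
  expect_equal(boundaryDiameter(rbind(c(2, 7)))$diameter, 0)
  expect_error(boundaryDiameter(matrix(0, 0, 2)), "at least one")
  # ties broken by lexicographically smallest index pair: the unit square has
  # two diagonals; points 1 (0,0) and 4 (1,1) beat 2-3
  expect_identical(res$indices, c(1L, 4L))
})

test_that("boundaryDiameter agrees with the O(n^2) brute force on random sets", {
  brute <- function(pts) {
    best <- 0
    for (i in seq_len(nrow(pts))) for (j in seq_len(nrow(pts)))
      best <- max(best, sum((pts[i, ] - pts[j, ])^2))
    sqrt(best)
  }
  set.seed(11)
  for (rep in 1:12) {
    n <- sample(2:200, 1)
    pts <- matrix(rnorm(2 * n, sd = 10), ncol = 2)
    expect_equal(boundaryDiameter(pts)$diameter, brute(pts), tolerance = 1e-12)
  }
})

test_that("axesFromRegion recovers generated ellipse half-axes within a pixel", {
  m <- ellipseMaskFixture(61, 61, 20, 10, theta = 0.6)
  ax <- axesFromRegion(seedRegion(1L, m))
  expect_equal(ax$a, 20, tolerance = 0.075)
  expect_equal(ax$b, 10, tolerance = 0.12)
  expect_false(ax$degenerate)
  # a disk: both half-axes near the radius
  dm <- ellipseMaskFixture(41, 41, 15, 15)
  axd <- axesFromRegion(seedRegion(1L, dm))
  expect_equal(axd$a, 15, tolerance = 0.08)
  expect_equal(axd$b, 15, tolerance = 0.08)
  # a 1-px line: degenerate with b = 0
  lm <- matrix(FALSE, 9, 9); lm[5, 2:8] <- TRUE
  axl <- axesFromRegion(seedRegion(1L, lm))
  expect_true(axl$degenerate)
  expect_equal(axl$b, 0)
  expect_equal(axl$a, 3, tolerance = 1e-9)
  expect_error(axesFromRegion(seedRegion(1L, matrix(c(TRUE, rep(FALSE, 8)), 3))),
               "at least 3")
})

test_that("ellipseFeatures evaluates the descriptor formulas exactly", {
  circ <- ellipseFeatures(1, 1)
  expect_equal(circ$eccentricity, 0)
  expect_equal(circ$area, pi)
  expect_equal(circ$perimeter, 2 * pi)
  expect_equal(circ$compactness, 4 * pi)
  expect_equal(circ$roundness, 1)
  e21 <- ellipseFeatures(2, 1)
  expect_equal(e21$eccentricity, sqrt(0.75))
  expect_equal(e21$area, 2 * pi)
  expect_equal(e21$perimeter, 3 * pi)
  expect_equal(e21$compactness, 4.5 * pi)
  expect_equal(e21$roundness, 8 / 9)
  # degenerate minor axis flags rather than silently returning
  dg <- ellipseFeatures(3, 0)
  expect_true(dg$degenerate)
  expect_equal(dg$eccentricity, 1)
  expect_error(ellipseFeatures(1, 2), "a >= b")
  expect_error(ellipseFeatures(0, 0), "positive")
  # Ramanujan perimeter is closer to the true circumference for elongation
  expect_gt(ellipseFeatures(5, 1, "ramanujan")$perimeter,
            ellipseFeatures(5, 1)$perimeter)
})

test_that("roundness x compactness equals 4*pi across a parameter grid", {
  for (a in c(1, 2, 5, 13.7)) for (b in c(0.3, 1, 2)) {
    if (b > a) next
    f <- ellipseFeatures(a, b)
    expect_equal(f$roundness * f$compactness, 4 * pi, tolerance = 1e-12)
  }
})

test_that("recovered eccentricity tracks the analytic value over an (a, b) grid", {
  for (ab in list(c(18, 9), c(15, 12), c(20, 6), c(12, 12))) {
    m <- ellipseMaskFixture(51, 51, ab[1], ab[2], theta = 0.3)
    ax <- axesFromRegion(seedRegion(1L, m))
    f <- ellipseFeatures(ax$a, min(ax$b, ax$a))
    expect_equal(f$eccentricity, sqrt(1 - (ab[2] / ab[1])^2), tolerance = 0.05)
  }
})

test_that("mean intensity and mean spectrum honour the mask and reduction order", {
  sc <- seedCubeFixture(nb = 2L, value = 0)
  # one masked pixel with spectrum (0.2, 0.4): band-average then pixel-average
  sc@mask[,] <- FALSE; sc@mask[4, 4] <- TRUE
  sc@data[4, 4, ] <- c(0.2, 0.4)
  expect_equal(meanIntensity(sc), 0.3)
  expect_equal(meanSpectrum(sc), c(0.2, 0.4))
  # constant cube: mean equals the constant; spectrum is constant
  scc <- seedCubeFixture(value = 0.7)
  expect_equal(meanIntensity(scc), 0.7)
  expect_equal(meanSpectrum(scc), rep(0.7, 3))
  # bright background outside the mask does not leak in
  dirty <- seedCubeFixture(value = 0.5)
  dirty@data[!array(dirty@mask, dim(dirty@data))] <- 99
  expect_equal(meanIntensity(dirty), 0.5)
  expect_equal(meanSpectrum(dirty), rep(0.5, 3))
  empty <- seedCubeFixture()
  empty@mask[,] <- FALSE
  expect_error(meanIntensity(empty), "no masked")
  expect_error(meanSpectrum(empty), "no masked")
})

test_that("featureTable emits one stable row per seed", {
  expect_equal(nrow(featureTable(list())), 0)
  expect_named(featureTable(list()),
               c("source", "class", "exposure", "diameter", "a", "b",
                 "eccentricity", "area", "perimeter", "compactness",
                 "roundness", "mean_intensity"))
  seeds <- list(seedCubeFixture(16, 16, 3, a = 5, b = 3, source = "p#1"),
                seedCubeFixture(16, 16, 3, a = 4, b = 4, source = "p#2"))
  tab <- featureTable(seeds)
  expect_equal(nrow(tab), 2)
  expect_identical(tab, featureTable(seeds))       # deterministic
  expect_true(all(tab$a >= tab$b))
  expect_true(all(tab$roundness > 0 & tab$roundness <= 1))
})
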
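## Synthetic hyperspectral seed panels with known ground truth. Each
## treatment class has a mean reflectance spectrum built from a shared
## smooth baseline plus class-specific Gaussian bumps; exposure duration
## applies a small within-class amplitude shift. The sensor model writes
## raw counts as dark + reflectance * (white - dark) + Gaussian noise, so
## Shafer calibration recovers the reflectance exactly at zero noise.

#' Build generative spectral models for treatment classes
#'
#' Class mean spectra share a smooth baseline and differ by non-negative
#' Gaussian bumps whose amplitudes scale with `separation`, so pairwise L2
#' distances between class means grow linearly with it (`separation = 0`
#' gives identical means). Exposure duration scales bump amplitudes by
#' `1 + exposureCoef * (hours - 204)`, a small within-class shift.
#'
#' @param nClasses number of classes (>= 2).
#' @param separation non-negative scalar controlling between-class distance
#'   (default 1, well-separated at the default noise level).
#' @param rngSeed seed fixing the bump geometry.
#' @param noiseSd per-pixel-band Gaussian noise sd in reflectance units
#'   (default 0.02, a typical NIR line-scan noise floor).
#' @param classNames optional class names (default Class1..ClassN; the rice
#'   study's five treatments are `riceClassNames()`).
#' @param exposureCoef relative amplitude change per hour of exposure
#'   (default 0.002).
#' @return list of [SpectralClassModel-class].
#' @export
makeClassModels <- function(nClasses, separation = 1, rngSeed = 0L,
                            noiseSd = 0.02, classNames = NULL,
                            exposureCoef = 0.002) {
  if (nClasses < 2L) stop("need at least 2 classes")
  if (separation < 0) stop("separation must be non-negative")
  if (is.null(classNames))
    classNames <- paste0("Class", seq_len(nClasses))
  stopifnot(length(classNames) == nClasses)
  set.seed(rngSeed)
  lapply(seq_len(nClasses), function(i) {
    nb <- 3L
    bumps <- data.frame(
      centerNm = runif(nb, 0.05, 0.95),          # relative position in range
      widthNm = runif(nb, 0.04, 0.12),           # relative width
      amplitude = separation * runif(nb, 0.05, 0.10))
    slope <- separation * runif(1, -0.03, 0.03)
    new("SpectralClassModel", name = classNames[i], bumps = bumps,
        slope = slope, noiseSd = noiseSd, exposureCoef = exposureCoef)
  })
}

#' The five rice treatment class names
#' @return character(5): Control, HDNT1, HNT, HDT, HDNT2.
#' @export
riceClassNames <- function() c("Control", "HDNT1", "HNT", "HDT", "HDNT2")

#' The six high-temperature exposure durations (hours)
#' @return numeric(6): 168, 180, 204, 216, 228, 240.
#' @export
riceExposures <- function() c(168, 180, 204, 216, 228, 240)

#' Mean reflectance spectrum of a class model
#'
#' @param model a [SpectralClassModel-class].
#' @param grid a [WavelengthGrid-class].
#' @param exposure exposure duration in hours (default 204, the schedule
#'   centre, where the exposure shift vanishes).
#' @return numeric vector of mean reflectance per band, clamped to 0..1.
#' @export
classMeanSpectrum <- function(model, grid, exposure = 204) {
  wl <- wavelengths(grid)
  span <- max(wl[length(wl)] - wl[1], 1)
  u <- (wl - wl[1]) / span
  base <- 0.35 + 0.08 * exp(-0.5 * ((u - 0.5) / 0.35)^2)
  expFactor <- 1 + model@exposureCoef * (exposure - 204)
  dev <- rep(0, length(wl))
  for (j in seq_len(nrow(model@bumps))) {
    b <- model@bumps[j, ]
    dev <- dev + b$amplitude * exp(-0.5 * ((u - b$centerNm) / b$widthNm)^2)
  }
  pmin(pmax(base + model@slope * (u - 0.5) + expFactor * dev, 0), 1)
}

#' Specification of one synthetic seed panel
#'
#' @param rows,cols panel frame size in pixels.
#' @param grid a [WavelengthGrid-class] (default the 597.21/4.14/268 nm
#'   sensor grid).
#' @param seeds data.frame with one row per seed: `class` (name matching a
#'   model), `exposure` (hours), `a`, `b` (ellipse half-axes, px),
#'   `centerRow`, `centerCol`, `theta` (orientation, radians).
#' @param whitePeak peak white-reference count level (default 3500, a 12-bit
#'   sensor near 85% of full well).
#' @param darkLevel dark-reference offset counts (default 100).
#' @param rngSeed seed for pixel noise.
#' @return a validated panel specification list.
#' @export
panelSpec <- function(rows, cols, grid = wavelengthGrid(597.21, 4.14, 268),
                      seeds, whitePeak = 3500, darkLevel = 100, rngSeed = 0L) {
  need <- c("class", "exposure", "a", "b", "centerRow", "centerCol", "theta")
  if (!all(need %in% names(seeds)))
    stop("seeds must have columns: ", paste(need, collapse = ", "))
  spec <- list(rows = as.integer(rows), cols = as.integer(cols), grid = grid,
               seeds = seeds, whitePeak = whitePeak, darkLevel = darkLevel,
               rngSeed = as.integer(rngSeed))
  class(spec) <- "PanelSpec"
  spec
}

.ellipseMask <- function(rows, cols, cr, cc, a, b, theta, margin = 0) {
  rr <- matrix(seq_len(rows), rows, cols) - cr
  cc2 <- matrix(seq_len(cols), rows, cols, byrow = TRUE) - cc
  x <- rr * cos(theta) + cc2 * sin(theta)
  y <- -rr * sin(theta) + cc2 * cos(theta)
  (x / (a + margin))^2 + (y / (b + margin))^2 <= 1
}

#' Generate one synthetic seed panel
#'
#' Renders the seeds of a [panelSpec()] into a reflectance scene
#' (background reflectance 0.03), simulates the white reference as a smooth
#' lamp spectrum and the dark reference as a constant offset, and emits raw
#' counts `dark + reflectance * (white - dark) + noise` whose calibration
#' recovers the scene.
#'
#' @param spec a [panelSpec()].
#' @param models list of [SpectralClassModel-class] covering every class
#'   named in `spec$seeds`.
#' @return list with `raw` (a [Hypercube-class] of counts), `refs`
#'   (a [CalibrationRefs-class]), `reflectance` (the noise-free scene), and
#'   `truth` (list: `raster` class-index matrix with 0 background, `regions`
#'   list of [SeedRegion-class] sorted like [segmentPanel()] output,
#'   `seedInfo` data.frame of class/exposure per region).
#' @export
generatePanel <- function(spec, models) {
  stopifnot(inherits(spec, "PanelSpec"))
  modNames <- vapply(models, function(m) m@name, character(1))
  if (!all(spec$seeds$class %in% modNames))
    stop("no spectral model for class(es): ",
         paste(setdiff(spec$seeds$class, modNames), collapse = ", "))
  nr <- spec$rows; nc <- spec$cols; nb <- spec$grid@count
  wl <- wavelengths(spec$grid)
  span <- max(wl[length(wl)] - wl[1], 1)
  u <- (wl - wl[1]) / span

  ## references: smooth lamp spectrum, constant over the frame
  whiteSpec <- spec$whitePeak * (0.55 + 0.45 * exp(-0.5 * ((u - 0.45) / 0.35)^2))
  white <- hypercube(aperm(array(whiteSpec, c(nb, nr, nc)), c(2, 3, 1)), spec$grid,
                     list(reference = "white"))
  dark <- hypercube(array(spec$darkLevel, c(nr, nc, nb)), spec$grid,
                    list(reference = "dark"))

  refl <- array(0.03, c(nr, nc, nb))
  raster <- matrix(0L, nr, nc)
  sdMap <- matrix(models[[1]]@noiseSd, nr, nc)
  occupied <- matrix(FALSE, nr, nc)
  regions <- list()
  for (s in seq_len(nrow(spec$seeds))) {
    sd <- spec$seeds[s, ]
    mask <- .ellipseMask(nr, nc, sd$centerRow, sd$centerCol, sd$a, sd$b, sd$theta)
    if (!any(mask)) stop("seed ", s, " lies outside the frame")
    guard <- .ellipseMask(nr, nc, sd$centerRow, sd$centerCol, sd$a, sd$b,
                          sd$theta, margin = 2)
    if (any(guard & occupied))
      stop("seeds overlap or are closer than 2 px (seed ", s, ")")
    occupied <- occupied | guard
    mi <- which(modNames == sd$class)[1]
    mu <- classMeanSpectrum(models[[mi]], spec$grid, sd$exposure)
    px <- which(mask)
    for (bIdx in seq_len(nb)) {
      plane <- refl[, , bIdx]
      plane[px] <- mu[bIdx]
      refl[, , bIdx] <- plane
    }
    raster[mask] <- mi
    sdMap[mask] <- models[[mi]]@noiseSd
    regions[[s]] <- seedRegion(s, mask)
  }
  ord <- order(vapply(regions, function(r) r@bbox[1], integer(1)),
               vapply(regions, function(r) r@bbox[2], integer(1)))
  regions <- regions[ord]
  seedInfo <- spec$seeds[ord, c("class", "exposure"), drop = FALSE]
  rownames(seedInfo) <- NULL
  for (i in seq_along(regions)) regions[[i]]@labelId <- i

  set.seed(spec$rngSeed)
  gain <- sweep(array(0, c(nr, nc, nb)), 3, whiteSpec - spec$darkLevel, `+`)
  rawCounts <- spec$darkLevel + refl * gain
  if (any(sdMap > 0))
    rawCounts <- rawCounts + array(rnorm(nr * nc * nb), c(nr, nc, nb)) *
      as.numeric(sdMap) * gain
  raw <- hypercube(rawCounts, spec$grid, list(calibrated = FALSE))
  list(raw = raw, refs = calibrationRefs(white, dark),
       reflectance = hypercube(refl, spec$grid, list(calibrated = TRUE)),
       truth = list(raster = raster, regions = regions, seedInfo = seedInfo))
}

## lay seeds out on a jittered cell grid so the >= 2 px spacing always holds
.layoutSeeds <- function(rows, cols, n, aRange, bRange, classes, exposures) {
  cell <- ceiling(2 * max(aRange) + 8)
  perRow <- max(1L, (cols - 4L) %/% cell)
  perCol <- max(1L, (rows - 4L) %/% cell)
  if (perRow * perCol < n)
    stop("panel too small for ", n, " seeds of this size")
  cells <- sample(perRow * perCol, n)
  data.frame(
    class = classes, exposure = exposures,
    a = runif(n, aRange[1], aRange[2]),
    b = runif(n, bRange[1], bRange[2]),
    centerRow = 2 + cell * ((cells - 1) %/% perRow) + cell / 2 + runif(n, -1, 1),
    centerCol = 2 + cell * ((cells - 1) %% perRow) + cell / 2 + runif(n, -1, 1),
    theta = runif(n, 0, pi))
}

#' Generate a labeled synthetic seed dataset
#'
#' Builds panels of seeds (classes interleaved, exposures cycling through
#' the schedule), calibrates them, and extracts one [SeedCube-class] per
#' seed using the ground-truth regions (segmentation bypass), plus the
#' matching [PixelDataset-class]. Deterministic for a fixed `rngSeed`.
#'
#' @param nPerClass seed cubes per class (the study acquires 40).
#' @param classNames class names (default [riceClassNames()]).
#' @param separation class separation passed to [makeClassModels()].
#' @param noiseSd pixel noise sd in reflectance units (default 0.02).
#' @param grid the [WavelengthGrid-class] (default the full 268-band sensor
#'   grid; tests use fewer bands for speed).
#' @param canonicalHW seed chip size (default `c(64, 32)`).
#' @param aRange,bRange ellipse half-axis ranges in px.
#' @param exposures exposure schedule (default [riceExposures()]).
#' @param seedsPerPanel seeds rendered per panel (default 10).
#' @param rngSeed master seed.
#' @return list with `seedSet` (a [LabeledSeedSet-class]), `pixels`
#'   (a [PixelDataset-class]), `models`, and `panels` (list of per-panel
#'   truth structures).
#' @export
generateDataset <- function(nPerClass, classNames = riceClassNames(),
                            separation = 1, noiseSd = 0.02,
                            grid = wavelengthGrid(597.21, 4.14, 268),
                            canonicalHW = c(64L, 32L),
                            aRange = c(9, 14), bRange = c(5, 8),
                            exposures = riceExposures(),
                            seedsPerPanel = 10L, rngSeed = 0L) {
  k <- length(classNames)
  models <- makeClassModels(k, separation, rngSeed, noiseSd, classNames)
  total <- nPerClass * k
  allClasses <- rep(classNames, nPerClass)           # interleaved round-robin
  allExposures <- rep_len(exposures, total)
  cubes <- list(); labels <- character(0); panels <- list()
  set.seed(rngSeed + 1L)
  cell <- ceiling(2 * max(aRange) + 8)
  perRow <- max(2L, ceiling(sqrt(seedsPerPanel)))
  side <- as.integer(perRow * cell + 8L)
  done <- 0L; panelNo <- 0L
  while (done < total) {
    nHere <- min(seedsPerPanel, total - done)
    panelNo <- panelNo + 1L
    seeds <- .layoutSeeds(side, side, nHere, aRange, bRange,
                          allClasses[done + seq_len(nHere)],
                          allExposures[done + seq_len(nHere)])
    spec <- panelSpec(side, side, grid, seeds,
                      rngSeed = (rngSeed %% 1000000L) * 1000L + panelNo)
    pan <- generatePanel(spec, models)
    calib <- calibrate(pan$raw, pan$refs)
    panelId <- sprintf("panel%03d", panelNo)
    sc <- extractSeedCubes(calib, pan$truth$regions, canonicalHW = canonicalHW,
                           panelId = panelId)
    for (i in seq_along(sc)) {
      sc[[i]]@classLabel <- pan$truth$seedInfo$class[i]
      sc[[i]]@exposureLabel <- pan$truth$seedInfo$exposure[i]
    }
    cubes <- c(cubes, sc)
    labels <- c(labels, pan$truth$seedInfo$class)
    panels[[panelId]] <- pan$truth
    done <- done + nHere
  }
  seedSet <- labeledSeedSet(cubes, factor(labels, levels = classNames))
  pixels <- buildPixelDataset(cubes)
  list(seedSet = seedSet, pixels = pixels, models = models, panels = panels)
}
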
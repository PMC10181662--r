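## End-to-end workflow: simulate (or load) -> calibrate -> segment ->
## extract -> features -> pixels -> train (DNN and/or 3D-CNN) -> evaluate ->
## map -> embed, driven by a validated YAML/list configuration. Artifacts
## are written under the configured output directory; the run summary
## (metrics, artifact paths, seed) is returned and written as JSON.

.pipelineSchema <- list(
  global = c("rngSeed", "outdir", "stages"),
  simulate = c("nPerClass", "classes", "separation", "noiseSd", "bands",
               "startNm", "stepNm", "canonicalH", "canonicalW", "aMin", "aMax",
               "bMin", "bMax", "seedsPerPanel"),
  calibrate = c("clip", "epsilonGuard"),
  segment = c("minArea", "closingRadius", "borderPolicy"),
  features = c("perimeterMethod"),
  dnn = c("enabled", "trainFrac", "epochs", "batchSize", "lr", "hiddenWidths"),
  cnn3d = c("enabled", "fractions", "perClassTotal", "epochs", "batchSize",
            "lr", "fcWidth"),
  map = c("enabled"),
  embed = c("enabled", "nComponents", "perplexity", "maxPixels"))

#' Validate a pipeline configuration
#'
#' Fills defaults and rejects unknown sections or keys.
#'
#' @param config a nested list, or the path of a YAML file.
#' @return the validated config with defaults filled.
#' @export
validateRunConfig <- function(config) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  if (!is.list(config)) stop("config must be a list or a YAML file path")
  unknownSec <- setdiff(names(config), names(.pipelineSchema))
  if (length(unknownSec))
    stop("unknown config section(s): ", paste(unknownSec, collapse = ", "))
  for (sec in names(config)) {
    bad <- setdiff(names(config[[sec]]), .pipelineSchema[[sec]])
    if (length(bad))
      stop("unknown key(s) in section '", sec, "': ", paste(bad, collapse = ", "))
  }
  g <- config$global %||% list()
  g$rngSeed <- g$rngSeed %||% 0L
  g$outdir <- g$outdir %||% tempfile("seedhsi_run_")
  config$global <- g
  s <- config$simulate %||% list()
  s$nPerClass <- s$nPerClass %||% 12L
  s$classes <- s$classes %||% riceClassNames()
  s$separation <- s$separation %||% 1
  s$noiseSd <- s$noiseSd %||% 0.02
  s$bands <- s$bands %||% 32L
  s$startNm <- s$startNm %||% 597.21
  s$stepNm <- s$stepNm %||% 4.14
  s$canonicalH <- s$canonicalH %||% 24L
  s$canonicalW <- s$canonicalW %||% 24L
  s$aMin <- s$aMin %||% 7; s$aMax <- s$aMax %||% 10
  s$bMin <- s$bMin %||% 4; s$bMax <- s$bMax %||% 6
  s$seedsPerPanel <- s$seedsPerPanel %||% 10L
  config$simulate <- s
  config
}

#' Run the full pipeline
#'
#' Simulates a labeled panel dataset, re-segments the panels, extracts
#' seeds and features, trains the configured classifiers, evaluates them on
#' held-out data, renders a classification map and an embedding, and writes
#' all artifacts plus `summary.json` under the output directory. Bit-identical
#' summaries are produced for a fixed `rngSeed`.
#'
#' @param config a config list or YAML path (see [validateRunConfig()]).
#' @return the summary list, invisibly written to `summary.json`.
#' @export
runPipeline <- function(config = list()) {
  cfg <- validateRunConfig(config)
  g <- cfg$global
  dir.create(g$outdir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(g$rngSeed)
  summary <- list(rngSeed = seed, stages = list())

  ## simulate
  s <- cfg$simulate
  grid <- wavelengthGrid(s$startNm, s$stepNm, s$bands)
  ds <- generateDataset(
    nPerClass = s$nPerClass, classNames = s$classes, separation = s$separation,
    noiseSd = s$noiseSd, grid = grid,
    canonicalHW = c(s$canonicalH, s$canonicalW),
    aRange = c(s$aMin, s$aMax), bRange = c(s$bMin, s$bMax),
    seedsPerPanel = s$seedsPerPanel, rngSeed = seed)
  summary$stages$simulate <- list(
    nSeeds = length(ds$seedSet@cubes), nPixels = nrow(ds$pixels@X),
    classes = levels(ds$seedSet@labels), bands = s$bands)

  ## segmentation consistency on a fresh panel
  segCfg <- cfg$segment %||% list()
  set.seed(seed + 7L)
  checkSeeds <- .layoutSeeds(200L, 200L, 6L,
                             c(s$aMin, s$aMax), c(s$bMin, s$bMax),
                             rep_len(s$classes, 6L), rep_len(riceExposures(), 6L))
  checkPanel <- generatePanel(
    panelSpec(200L, 200L, grid, checkSeeds, rngSeed = seed + 7L), ds$models)
  calCfg <- cfg$calibrate %||% list()
  calib <- calibrate(checkPanel$raw, checkPanel$refs,
                     clip = calCfg$clip %||% TRUE,
                     epsilonGuard = calCfg$epsilonGuard %||% FALSE)
  regions <- segmentPanel(calib, minArea = segCfg$minArea %||% 50L,
                          closingRadius = segCfg$closingRadius %||% 2L,
                          borderPolicy = segCfg$borderPolicy %||% "discard")
  summary$stages$segment <- list(
    truthSeeds = length(checkPanel$truth$regions), found = length(regions))

  ## features
  feat <- featureTable(ds$seedSet@cubes,
                       perimeterMethod = (cfg$features$perimeterMethod %||% "ellipse"))
  featPath <- file.path(g$outdir, "features.csv")
  write.csv(feat, featPath, row.names = FALSE)
  summary$stages$features <- list(rows = nrow(feat), path = "features.csv")

  ## pixel DNN
  dnnCfgIn <- cfg$dnn %||% list()
  if (dnnCfgIn$enabled %||% TRUE) {
    sp <- splitPixels(ds$pixels, trainFrac = dnnCfgIn$trainFrac %||% 0.7,
                      rngSeed = seed)
    dnnModel <- trainDNN(sp$train,
                         dnnConfig(hiddenWidths = dnnCfgIn$hiddenWidths %||%
                                     c(64L, 64L, 48L, 48L, 48L, 32L, 32L, 32L,
                                       24L, 24L, 16L, 16L),
                                   epochs = dnnCfgIn$epochs %||% 12L,
                                   batchSize = dnnCfgIn$batchSize %||% 256L,
                                   lr = dnnCfgIn$lr %||% 1e-3, rngSeed = seed))
    pr <- predictPixels(dnnModel, sp$val)
    repDnn <- multiclassReport(confusionMatrix(
      factor(sp$val@y, levels = dnnModel@classLevels), pr$labels))
    summary$stages$dnn <- list(OA = repDnn@OA, AA = repDnn@AA, kappa = repDnn@kappa,
                               nTrain = nrow(sp$train@X), nVal = nrow(sp$val@X))
    jsonlite::write_json(reportAsList(repDnn),
                         file.path(g$outdir, "dnn_report.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
    if ((cfg$map %||% list())$enabled %||% TRUE) {
      pid <- sp$val@origin$panel[1]
      sel <- sp$val@origin$panel == pid
      shape <- dim(ds$panels[[pid]]$raster)
      map <- renderMap(shape, sp$val@origin[sel, ], pr$labels[sel],
                       pngPath = file.path(g$outdir, "map.png"))
      summary$stages$map <- list(panel = pid, classes = map@classLevels,
                                 painted = sum(map@labels > 0))
    }
  }

  ## seed-level 3D-CNN
  cnnCfgIn <- cfg$cnn3d %||% list()
  if (cnnCfgIn$enabled %||% TRUE) {
    split <- splitDataset(ds$seedSet,
                          fractions = cnnCfgIn$fractions %||% c(0.8, 0.1, 0.1),
                          rngSeed = seed)
    aug <- augmentSeedSet(split,
                          perClassTotal = cnnCfgIn$perClassTotal %||%
                            max(table(split@labels)), rngSeed = seed)
    cnnModel <- trainCNN3D(aug, cnn3dConfig(
      fcWidth = cnnCfgIn$fcWidth %||% 32L,
      epochs = cnnCfgIn$epochs %||% 15L,
      batchSize = cnnCfgIn$batchSize %||% 8L,
      lr = cnnCfgIn$lr %||% 1e-3, rngSeed = seed))
    teIdx <- which(aug@split == "test")
    pr <- predictCNN3D(cnnModel, aug@cubes[teIdx])
    repCnn <- multiclassReport(confusionMatrix(
      factor(aug@labels[teIdx], levels = cnnModel@classLevels), pr$labels))
    summary$stages$cnn3d <- list(OA = repCnn@OA, AA = repCnn@AA, kappa = repCnn@kappa,
                                 nTrain = sum(aug@split == "train"),
                                 nTest = length(teIdx))
    jsonlite::write_json(reportAsList(repCnn),
                         file.path(g$outdir, "cnn3d_report.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
  }

  ## embedding
  embCfg <- cfg$embed %||% list()
  if (embCfg$enabled %||% TRUE) {
    maxPix <- embCfg$maxPixels %||% 1500L
    set.seed(seed + 13L)
    sel <- sort(sample.int(nrow(ds$pixels@X), min(maxPix, nrow(ds$pixels@X))))
    emb <- suppressWarnings(
      pcaTsneEmbed(ds$pixels@X[sel, ], nComponents = embCfg$nComponents %||% 50L,
                   rngSeed = seed, perplexity = embCfg$perplexity %||% 30))
    coords <- data.frame(tsne1 = emb$coords[, 1], tsne2 = emb$coords[, 2],
                         class = as.character(ds$pixels@y[sel]))
    write.csv(coords, file.path(g$outdir, "embedding.csv"), row.names = FALSE)
    summary$stages$embed <- list(n = nrow(coords),
                                 nComponents = emb$nComponents)
  }

  jsonlite::write_json(summary, file.path(g$outdir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  summary
}
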
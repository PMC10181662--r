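## Classification metrics: confusion matrix, one-vs-rest precision/recall/F1
## with macro and support-weighted averages, overall accuracy (trace/total),
## average accuracy (mean one-vs-rest accuracy), and Cohen's kappa
## (Po - Pe) / (1 - Pe) with Pe from the marginal products. Zero-denominator
## metrics are reported as 0 and flagged undefined rather than NaN, keeping
## tabular output stable.

#' Confusion matrix
#'
#' `counts[i, j]` is the number of items with truth class `i` predicted as
#' class `j`.
#'
#' @param truth,pred vectors of equal length; factors (sharing levels) or
#'   integer codes in `1:k`.
#' @param k number of classes; inferred from factor levels if missing.
#' @return k x k integer matrix with class dimnames.
#' @export
confusionMatrix <- function(truth, pred, k = NULL) {
  if (length(truth) != length(pred))
    stop("truth and pred must have equal length")
  if (is.factor(truth) || is.factor(pred)) {
    lev <- levels(as.factor(truth))
    if (is.factor(pred)) lev <- union(lev, levels(pred))
    truth <- as.integer(factor(as.character(truth), levels = lev))
    pred <- as.integer(factor(as.character(pred), levels = lev))
    if (is.null(k)) k <- length(lev)
  } else {
    lev <- NULL
    if (is.null(k)) k <- max(truth, pred, 0L)
  }
  truth <- as.integer(truth); pred <- as.integer(pred)
  if (length(truth) && (any(truth < 1L | truth > k) || any(pred < 1L | pred > k)))
    stop("labels must lie in 1..k")
  M <- matrix(0L, k, k)
  for (i in seq_along(truth)) M[truth[i], pred[i]] <- M[truth[i], pred[i]] + 1L
  if (!is.null(lev)) dimnames(M) <- list(truth = lev, pred = lev)
  M
}

#' Binary classification metrics from a 2x2 tally
#'
#' Precision `TP/(TP+FP)`, recall `TP/(TP+FN)`, F1
#' `2*precision*recall/(precision+recall)` and accuracy
#' `(TP+TN)/(TP+TN+FP+FN)`. A zero denominator yields 0 for that metric with
#' its name recorded in `undefined`.
#'
#' @param TP,FP,TN,FN non-negative counts.
#' @return list with `precision`, `recall`, `f1`, `accuracy`, `undefined`
#'   (character vector of flagged metrics).
#' @examples
#' binaryMetrics(8, 2, 9, 1)  # precision 0.8, recall 8/9, f1 0.84211
#' @export
binaryMetrics <- function(TP, FP, TN, FN) {
  counts <- c(TP, FP, TN, FN)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("TP, FP, TN, FN must be non-negative integers")
  undef <- character(0)
  div <- function(num, den, name) {
    if (den == 0) { undef <<- c(undef, name); 0 } else num / den
  }
  precision <- div(TP, TP + FP, "precision")
  recall <- div(TP, TP + FN, "recall")
  f1 <- if (precision + recall == 0) { undef <- c(undef, "f1"); 0 }
        else 2 * precision * recall / (precision + recall)
  accuracy <- div(TP + TN, TP + TN + FP + FN, "accuracy")
  list(precision = precision, recall = recall, f1 = f1, accuracy = accuracy,
       undefined = undef)
}

#' Multi-class evaluation report
#'
#' Per-class one-vs-rest precision/recall/F1 with macro (unweighted) and
#' weighted (by support) averages; overall accuracy `OA = trace/total`;
#' average accuracy `AA` = mean of per-class one-vs-rest accuracies
#' `(TP+TN)/(TP+TN+FP+FN)`; Cohen's kappa `(Po - Pe)/(1 - Pe)` with
#' `Po = OA` and `Pe = sum_i row_i * col_i / total^2`. For `k = 2` the
#' per-class rows agree exactly with [binaryMetrics()].
#'
#' @param confusion k x k count matrix, rows = truth (k >= 2, total > 0).
#' @return an [EvaluationReport-class].
#' @examples
#' multiclassReport(matrix(c(45, 15, 5, 35), 2))@kappa  # 0.6
#' @export
multiclassReport <- function(confusion) {
  confusion <- as.matrix(confusion)
  if (nrow(confusion) != ncol(confusion) || nrow(confusion) < 2L)
    stop("confusion must be a square matrix with k >= 2")
  total <- sum(confusion)
  if (total <= 0) stop("confusion matrix is empty")
  k <- nrow(confusion)
  lev <- rownames(confusion) %||% as.character(seq_len(k))
  rows <- lapply(seq_len(k), function(i) {
    TP <- confusion[i, i]
    FN <- sum(confusion[i, ]) - TP
    FP <- sum(confusion[, i]) - TP
    TN <- total - TP - FN - FP
    bm <- binaryMetrics(TP, FP, TN, FN)
    data.frame(class = lev[i], precision = bm$precision, recall = bm$recall,
               f1 = bm$f1, accuracy = bm$accuracy,
               support = TP + FN, undefined = length(bm$undefined) > 0,
               stringsAsFactors = FALSE)
  })
  perClass <- do.call(rbind, rows)
  support <- perClass$support
  wts <- if (sum(support) > 0) support / sum(support) else rep(1 / k, k)
  macro <- c(precision = mean(perClass$precision), recall = mean(perClass$recall),
             f1 = mean(perClass$f1))
  weighted <- c(precision = sum(wts * perClass$precision),
                recall = sum(wts * perClass$recall),
                f1 = sum(wts * perClass$f1))
  OA <- sum(diag(confusion)) / total
  AA <- mean(perClass$accuracy)
  Pe <- sum(rowSums(confusion) * colSums(confusion)) / total^2
  kappa <- if (Pe >= 1) { if (OA >= 1) 1 else 0 } else (OA - Pe) / (1 - Pe)
  new("EvaluationReport", confusion = confusion, perClass = perClass,
      macroAvg = macro, weightedAvg = weighted, AA = AA, OA = OA, kappa = kappa)
}

#' Evaluation report as a plain list (for JSON export)
#' @param report an [EvaluationReport-class].
#' @return a nested list mirroring the report's slots.
#' @export
reportAsList <- function(report) {
  stopifnot(is(report, "EvaluationReport"))
  list(confusion = unname(apply(report@confusion, 1, function(r) as.integer(r),
                                simplify = FALSE)),
       classes = report@perClass$class,
       per_class = report@perClass[, c("class", "precision", "recall", "f1",
                                       "accuracy", "support")],
       macro_avg = as.list(report@macroAvg),
       weighted_avg = as.list(report@weightedAvg),
       AA = report@AA, OA = report@OA, kappa = report@kappa)
}

#' Render a per-pixel classification map
#'
#' Paints pixel predictions back into the panel frame; background pixels
#' keep the sentinel 0. Optionally writes an RGB PNG plus a JSON legend
#' sidecar (`<png>.legend.json`) mapping classes to colours.
#'
#' @param panelShape integer(2) panel dimensions `c(rows, cols)`.
#' @param origins data.frame with `row`, `col` per prediction (as produced by
#'   [buildPixelDataset()]).
#' @param predictions factor or character vector of predicted classes.
#' @param palette named vector of hex colours covering all classes; default
#'   a colour-blind-safe palette.
#' @param pngPath optional path to write the map as PNG.
#' @return a [ClassificationMap-class].
#' @export
renderMap <- function(panelShape, origins, predictions, palette = NULL,
                      pngPath = NULL) {
  panelShape <- as.integer(panelShape)
  predictions <- as.factor(predictions)
  lev <- levels(predictions)
  if (nrow(origins) != length(predictions))
    stop("origins and predictions must have equal length")
  if (any(origins$row < 1L | origins$row > panelShape[1] |
          origins$col < 1L | origins$col > panelShape[2]))
    stop("origin coordinates outside the panel frame")
  if (is.null(palette)) {
    base <- c("#E69F00", "#56B4E9", "#009E73", "#F0E442", "#0072B2",
              "#D55E00", "#CC79A7", "#999999")
    palette <- setNames(rep(base, length.out = length(lev)), lev)
  }
  if (!all(lev %in% names(palette)))
    stop("palette must name a colour for every class")
  labels <- matrix(0L, panelShape[1], panelShape[2])
  labels[cbind(origins$row, origins$col)] <- as.integer(predictions)
  map <- new("ClassificationMap", labels = labels, classLevels = lev,
             palette = palette[lev])
  if (!is.null(pngPath)) {
    rgb <- array(0, c(panelShape[1], panelShape[2], 3))
    for (i in seq_along(lev)) {
      cc <- grDevices::col2rgb(palette[[lev[i]]]) / 255
      sel <- labels == i
      for (ch in 1:3) {
        plane <- rgb[, , ch]; plane[sel] <- cc[ch]; rgb[, , ch] <- plane
      }
    }
    png::writePNG(rgb, pngPath)
    jsonlite::write_json(list(background = 0L,
                              classes = as.list(setNames(seq_along(lev), lev)),
                              palette = as.list(palette[lev])),
                         paste0(pngPath, ".legend.json"), auto_unbox = TRUE)
  }
  map
}

#' PCA then t-SNE embedding of spectra
#'
#' Reduces spectra to their first `nComponents` principal components
#' (centred, unscaled) and embeds those scores in 2-D with t-SNE. If fewer
#' observations than components are available, the component count is
#' reduced with a warning; the perplexity is likewise capped for small n.
#'
#' @param X numeric matrix n x bands (pixel or seed spectra).
#' @param nComponents principal components to keep (default 50).
#' @param rngSeed seed making the embedding deterministic.
#' @param perplexity t-SNE perplexity (default 30).
#' @return list with `coords` (n x 2), `explainedVariance` (per kept
#'   component) and `nComponents` actually used.
#' @export
pcaTsneEmbed <- function(X, nComponents = 50L, rngSeed = 0L, perplexity = 30) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < 4L) stop("need at least 4 observations to embed")
  maxComp <- min(n - 1L, ncol(X))
  if (nComponents > maxComp) {
    warning("reducing components from ", nComponents, " to ", maxComp)
    nComponents <- maxComp
  }
  pc <- prcomp(X, center = TRUE, scale. = FALSE, rank. = nComponents)
  ev <- pc$sdev[seq_len(nComponents)]^2
  maxPerp <- floor((n - 2) / 3)
  if (perplexity > maxPerp) {
    warning("reducing perplexity from ", perplexity, " to ", maxPerp)
    perplexity <- maxPerp
  }
  set.seed(rngSeed)
  ts <- Rtsne::Rtsne(pc$x, dims = 2, perplexity = perplexity, pca = FALSE,
                     check_duplicates = FALSE, verbose = FALSE)
  list(coords = ts$Y, explainedVariance = ev, nComponents = nComponents)
}
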
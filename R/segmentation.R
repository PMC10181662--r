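## Seed segmentation: score image (mean reflectance over a band window) ->
## Otsu threshold -> binary closing -> 8-connected components -> area and
## border filtering. The panel's seeds sit bright on a dark background after
## calibration, so a global threshold on mean reflectance separates them.

#' Segment seeds from a calibrated panel cube
#'
#' Builds a scalar score image as the mean reflectance over a band window,
#' thresholds it (Otsu by default), applies binary closing, labels
#' 8-connected components, and filters by minimum area and border contact.
#'
#' @param panel a calibrated [Hypercube-class].
#' @param bandWindow integer(2) `c(from, to)` band range for the score image,
#'   or NULL (default) to average all bands.
#' @param thresholdMethod `"otsu"` or a numeric threshold on the score image.
#' @param minArea minimum region area in pixels (default 50).
#' @param closingRadius radius of the binary closing brush in pixels
#'   (default 2; 0 disables closing).
#' @param borderPolicy `"discard"` (default) drops regions whose bounding box
#'   touches the panel edge (clipped seeds bias shape features); `"keep"`
#'   retains them.
#' @return list of [SeedRegion-class], sorted by bounding box
#'   `(rowMin, colMin)`; masks are pairwise disjoint. An empty or constant
#'   panel yields an empty list.
#' @seealso [extractSeedCubes()]
#' @export
segmentPanel <- function(panel, bandWindow = NULL, thresholdMethod = "otsu",
                         minArea = 50L, closingRadius = 2L,
                         borderPolicy = c("discard", "keep")) {
  stopifnot(is(panel, "Hypercube"))
  borderPolicy <- match.arg(borderPolicy)
  if (!isCalibrated(panel))
    warning("segmenting an uncalibrated cube; threshold assumes reflectance")
  if (!is.null(bandWindow)) {
    bandWindow <- as.integer(bandWindow)
    if (length(bandWindow) != 2L || bandWindow[1] < 1L ||
        bandWindow[2] > nBands(panel) || bandWindow[1] > bandWindow[2])
      stop("bandWindow must be c(from, to) within 1..", nBands(panel))
  } else bandWindow <- c(1L, nBands(panel))
  if (minArea < 1L) stop("minArea must be >= 1")
  if (closingRadius < 0L) stop("closingRadius must be >= 0")

  score <- rowMeans(panel@data[, , bandWindow[1]:bandWindow[2], drop = FALSE],
                    dims = 2)
  rng <- range(score)
  if (rng[2] - rng[1] <= .Machine$double.eps * max(1, abs(rng[2])))
    return(list())                       # constant panel: nothing to segment
  if (identical(thresholdMethod, "otsu")) {
    norm <- (score - rng[1]) / (rng[2] - rng[1])
    t01 <- EBImage::otsu(EBImage::Image(norm), range = c(0, 1))
    thr <- rng[1] + t01 * (rng[2] - rng[1])
  } else if (is.numeric(thresholdMethod) && length(thresholdMethod) == 1L) {
    thr <- thresholdMethod
  } else stop("thresholdMethod must be \"otsu\" or a single numeric threshold")

  bw <- score > thr
  if (!any(bw)) return(list())
  if (closingRadius > 0L) {
    brush <- EBImage::makeBrush(2L * closingRadius + 1L, shape = "disc")
    bw <- EBImage::imageData(EBImage::closing(EBImage::Image(bw * 1), brush)) > 0.5
  }
  lab <- .labelComponents8(bw)
  ids <- setdiff(sort(unique(as.vector(lab))), 0L)
  regions <- list()
  nr <- nrow(bw); nc <- ncol(bw)
  for (id in ids) {
    mask <- lab == id
    if (sum(mask) < minArea) next
    reg <- seedRegion(length(regions) + 1L, mask)
    if (borderPolicy == "discard" &&
        (reg@bbox[1] == 1L || reg@bbox[2] == 1L ||
         reg@bbox[3] == nr || reg@bbox[4] == nc)) next
    regions[[length(regions) + 1L]] <- reg
  }
  if (!length(regions)) return(list())
  ord <- order(vapply(regions, function(r) r@bbox[1], integer(1)),
               vapply(regions, function(r) r@bbox[2], integer(1)))
  regions <- regions[ord]
  for (i in seq_along(regions)) regions[[i]]@labelId <- i
  regions
}

#' Extract fixed-size seed sub-cubes from a panel
#'
#' Crops each region's bounding box from the panel, zeroes pixels outside the
#' seed mask, and centres the crop in a canonical `H x W` chip with zero
#' padding. If a bounding box exceeds the canonical size and `resize = TRUE`,
#' the crop is band-wise bilinearly resized (aspect preserved) to fit; the
#' band axis is never resampled.
#'
#' @param panel the calibrated source [Hypercube-class].
#' @param regions list of [SeedRegion-class] from [segmentPanel()] on this
#'   panel.
#' @param canonicalHW integer(2) chip size `c(H, W)` (default `c(64, 32)`).
#' @param classLabel treatment class label applied to all extracted seeds.
#' @param exposureLabel exposure duration in hours (default NA).
#' @param panelId provenance id recorded in each seed's `source`.
#' @param resize allow resizing oversized regions (default TRUE); with
#'   `FALSE`, an oversized bounding box is an error.
#' @return list of [SeedCube-class], one per region.
#' @export
extractSeedCubes <- function(panel, regions, canonicalHW = c(64L, 32L),
                             classLabel = NA_character_, exposureLabel = NA_real_,
                             panelId = "panel", resize = TRUE) {
  stopifnot(is(panel, "Hypercube"))
  canonicalHW <- as.integer(canonicalHW)
  H <- canonicalHW[1]; W <- canonicalHW[2]
  nb <- nBands(panel)
  lapply(regions, function(reg) {
    bb <- reg@bbox
    h <- bb[3] - bb[1] + 1L; w <- bb[4] - bb[2] + 1L
    crop <- panel@data[bb[1]:bb[3], bb[2]:bb[4], , drop = FALSE]
    m <- reg@mask[bb[1]:bb[3], bb[2]:bb[4], drop = FALSE]
    crop <- crop * as.numeric(m)          # zero background, recycled over bands
    resized <- FALSE
    if (h > H || w > W) {
      resized <- TRUE
      if (!resize)
        stop("region ", reg@labelId, " bounding box (", h, "x", w,
             ") exceeds canonical size ", H, "x", W, " and resize is disabled")
      s <- min(H / h, W / w)
      h2 <- max(1L, as.integer(round(h * s))); w2 <- max(1L, as.integer(round(w * s)))
      shrunk <- array(0, c(h2, w2, nb))
      for (b in seq_len(nb))
        shrunk[, , b] <- EBImage::imageData(
          EBImage::resize(EBImage::Image(crop[, , b]), w = h2, h = w2))
      m <- EBImage::imageData(
        EBImage::resize(EBImage::Image(m * 1), w = h2, h = w2)) > 0.5
      crop <- shrunk * as.numeric(m)
      h <- h2; w <- w2
    }
    r0 <- (H - h) %/% 2L; c0 <- (W - w) %/% 2L
    chip <- array(0, c(H, W, nb))
    chip[r0 + seq_len(h), c0 + seq_len(w), ] <- crop
    chipMask <- matrix(FALSE, H, W)
    chipMask[r0 + seq_len(h), c0 + seq_len(w)] <- m
    new("SeedCube", data = chip, mask = chipMask, grid = panel@grid,
        classLabel = as.character(classLabel),
        exposureLabel = as.numeric(exposureLabel),
        source = sprintf("%s#%d", panelId, reg@labelId),
        offset = if (resized) c(NA_real_, NA_real_)
                 else c(bb[1] - r0, bb[2] - c0))
  })
}
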
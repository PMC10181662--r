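## Spatial-spectral phenotype descriptors for one seed. The shape model is
## an ellipse fitted from the region's boundary diameter: the major axis is
## the segment between the two most distant boundary points, the minor axis
## is the region's extent perpendicular to it. The descriptor formulas use
## the ellipse approximation throughout, including the crude perimeter
## p = pi * (a + b); Ramanujan's approximation is available behind a flag.

#' Boundary diameter of a point set
#'
#' Maximum pairwise Euclidean distance between boundary points, with the
#' achieving pair. Computed on the convex hull (the diameter of a finite set
#' is attained on its hull). Ties are broken by the lexicographically
#' smallest pair of original point indices.
#'
#' @param points numeric matrix n x 2 of (row, col) boundary coordinates.
#' @return list with `diameter`, `endpoints` (2 x 2 matrix of coordinates)
#'   and `indices` (integer(2) into `points`).
#' @examples
#' sq <- rbind(c(0, 0), c(0, 1), c(1, 0), c(1, 1))
#' boundaryDiameter(sq)$diameter  # sqrt(2)
#' @export
boundaryDiameter <- function(points) {
  points <- as.matrix(points)
  if (!nrow(points)) stop("need at least one boundary point")
  if (nrow(points) == 1L)
    return(list(diameter = 0, endpoints = points[c(1, 1), , drop = FALSE],
                indices = c(1L, 1L)))
  hull <- if (nrow(points) > 3L) {
    h <- tryCatch(grDevices::chull(points[, 2], points[, 1]),
                  error = function(e) seq_len(nrow(points)))
    sort(unique(h))
  } else seq_len(nrow(points))
  best <- -1; bi <- c(1L, 1L)
  for (u in seq_along(hull)) {
    i <- hull[u]
    for (v in seq_len(u - 1L)) {
      j <- hull[v]
      d2 <- sum((points[i, ] - points[j, ])^2)
      lo <- min(i, j); hi <- max(i, j)
      if (d2 > best + 1e-12 ||
          (abs(d2 - best) <= 1e-12 &&
           (lo < bi[1] || (lo == bi[1] && hi < bi[2])))) {
        best <- d2; bi <- c(lo, hi)
      }
    }
  }
  list(diameter = sqrt(best), endpoints = points[bi, , drop = FALSE], indices = bi)
}

#' Boundary points of a seed region
#'
#' Outer boundary pixel centres under 8-connectivity: mask pixels with at
#' least one 4-neighbour outside the mask (or on the frame edge).
#'
#' @param region a [SeedRegion-class].
#' @return numeric matrix n x 2 of (row, col) pixel-centre coordinates.
#' @export
boundaryPoints <- function(region) {
  m <- region@mask
  nr <- nrow(m); nc <- ncol(m)
  pad <- matrix(FALSE, nr + 2L, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- m
  inner <- pad[2:(nr + 1L), 2:(nc + 1L)] &
    pad[1:nr, 2:(nc + 1L)] & pad[3:(nr + 2L), 2:(nc + 1L)] &
    pad[2:(nr + 1L), 1:nc] & pad[2:(nr + 1L), 3:(nc + 2L)]
  which(m & !inner, arr.ind = TRUE)
}

#' Major and minor half-axes of a seed region
#'
#' The major axis is the boundary-diameter segment: `a` is half the maximum
#' pairwise boundary distance, oriented along the achieving pair. `b` is
#' half the extent of the region's pixels projected on the perpendicular
#' direction. If the region is (near-)collinear, `b` is 0 and the result is
#' flagged degenerate.
#'
#' @param region a [SeedRegion-class] with at least 3 pixels.
#' @return list with `a`, `b`, `orientation` (radians of the major axis) and
#'   `degenerate` flag.
#' @export
axesFromRegion <- function(region) {
  if (region@areaPx < 3L) stop("region must have at least 3 pixels")
  bp <- boundaryPoints(region)
  dia <- boundaryDiameter(bp)
  a <- dia$diameter / 2
  u <- dia$endpoints[2, ] - dia$endpoints[1, ]
  theta <- atan2(u[2], u[1])
  perp <- c(-sin(theta), cos(theta))
  px <- which(region@mask, arr.ind = TRUE)
  proj <- px %*% perp
  b <- (max(proj) - min(proj)) / 2
  degenerate <- b < 0.5            # thinner than one pixel: collinear region
  if (degenerate) b <- 0
  if (b > a) { tmp <- a; a <- b; b <- tmp; theta <- theta + pi / 2 }
  list(a = a, b = b, orientation = theta, degenerate = degenerate)
}

#' Ellipse shape descriptors from half-axes
#'
#' Computes the five ellipse descriptors from the major/minor half-axes:
#' eccentricity `sqrt(1 - (b/a)^2)`, area `pi*a*b`, perimeter `pi*(a + b)`
#' (the module's deliberately simple ellipse perimeter; Ramanujan's
#' approximation via `perimeterMethod = "ramanujan"`), compactness `p^2/A`
#' and roundness `4*pi*A/p^2`. With the default perimeter, roundness times
#' compactness is exactly `4*pi` and a circle attains compactness `4*pi`,
#' roundness 1.
#'
#' @param a,b major and minor half-axes, `a >= b >= 0`, `a > 0`.
#' @param perimeterMethod `"ellipse"` (default, `p = pi*(a+b)`) or
#'   `"ramanujan"`.
#' @return named list: `eccentricity`, `area`, `perimeter`, `compactness`,
#'   `roundness`, and a `degenerate` flag (TRUE when `b == 0`, where the
#'   ellipse collapses and eccentricity hits its boundary value 1).
#' @examples
#' ellipseFeatures(1, 1)$compactness  # 4*pi
#' ellipseFeatures(2, 1)$roundness    # 8/9
#' @export
ellipseFeatures <- function(a, b, perimeterMethod = c("ellipse", "ramanujan")) {
  perimeterMethod <- match.arg(perimeterMethod)
  if (!is.finite(a) || !is.finite(b)) stop("a and b must be finite")
  if (a <= 0) stop("a must be positive")
  if (b > a) stop("require a >= b")
  if (b < 0) stop("b must be non-negative")
  ecc <- sqrt(1 - (b / a)^2)
  A <- pi * a * b
  p <- if (perimeterMethod == "ellipse") pi * (a + b) else {
    h <- ((a - b) / (a + b))^2
    pi * (a + b) * (1 + 3 * h / (10 + sqrt(4 - 3 * h)))
  }
  degenerate <- b == 0
  list(eccentricity = ecc, area = A, perimeter = p,
       compactness = if (degenerate) Inf else p^2 / A,
       roundness = if (degenerate) 0 else 4 * pi * A / p^2,
       degenerate = degenerate)
}

#' @describeIn meanSpectrum per-band mean over the seed's masked pixels.
#' @export
setMethod("meanSpectrum", "SeedCube", function(x) {
  if (!any(x@mask)) stop("seed has no masked pixels")
  flat <- matrix(x@data, ncol = nBands(x))    # (H*W) x bands
  colMeans(flat[as.vector(x@mask), , drop = FALSE])
})

#' @describeIn meanIntensity mean over masked pixels of each pixel's
#'   band-averaged reflectance (bands are reduced first, then pixels).
#' @export
setMethod("meanIntensity", "SeedCube", function(x) {
  if (!any(x@mask)) stop("seed has no masked pixels")
  flat <- matrix(x@data, ncol = nBands(x))
  mean(rowMeans(flat[as.vector(x@mask), , drop = FALSE]))
})

#' Per-seed phenotype feature table
#'
#' One row per seed with the full descriptor set and labels, in a stable
#' column order suitable for CSV export.
#'
#' @param seeds list of [SeedCube-class].
#' @param regions list of [SeedRegion-class] matching `seeds` (same order),
#'   used for the shape descriptors; if NULL, shapes are computed from each
#'   seed chip's own mask.
#' @param perimeterMethod passed to [ellipseFeatures()].
#' @return data.frame with columns source, class, exposure, diameter, a, b,
#'   eccentricity, area, perimeter, compactness, roundness, mean_intensity.
#' @export
featureTable <- function(seeds, regions = NULL,
                         perimeterMethod = c("ellipse", "ramanujan")) {
  perimeterMethod <- match.arg(perimeterMethod)
  cols <- c("source", "class", "exposure", "diameter", "a", "b", "eccentricity",
            "area", "perimeter", "compactness", "roundness", "mean_intensity")
  if (!length(seeds)) {
    empty <- as.data.frame(setNames(
      c(list(character(0), character(0), numeric(0)),
        rep(list(numeric(0)), 9)), cols))
    return(empty)
  }
  rows <- lapply(seq_along(seeds), function(i) {
    sc <- seeds[[i]]
    reg <- if (!is.null(regions)) regions[[i]] else seedRegion(i, sc@mask)
    ax <- axesFromRegion(reg)
    ef <- ellipseFeatures(ax$a, max(ax$b, 0), perimeterMethod = perimeterMethod)
    data.frame(source = sc@source, class = sc@classLabel,
               exposure = sc@exposureLabel, diameter = 2 * ax$a,
               a = ax$a, b = ax$b, eccentricity = ef$eccentricity,
               area = ef$area, perimeter = ef$perimeter,
               compactness = ef$compactness, roundness = ef$roundness,
               mean_intensity = meanIntensity(sc),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
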
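## Reflectance calibration (Shafer model): Ic = (I - Id) / (Iw - Id), applied
## elementwise with the white (100% reflectance) and dark (0%) references.

#' @describeIn calibrate Shafer-model calibration of a raw cube.
#'
#' Computes reflectance `(I - Id) / (Iw - Id)` elementwise. References may be
#' full-frame (same rows x cols as `raw`) or a single-line column profile
#' (`1 x cols x bands`, the line-scan acquisition convention), which is
#' broadcast across rows. By default values are clipped to `[0, 1.2]`
#' (specular glints can slightly exceed the white tile).
#'
#' If any reference element has `Iw == Id` the calibration is degenerate
#' there; with `epsilonGuard = FALSE` (default) this is an error reporting
#' the affected band and pixel counts. With `epsilonGuard = TRUE`,
#' denominators smaller than `eps` times the white dynamic range are masked
#' and the output set to 0 (dead-pixel tolerance), with a message giving the
#' masked count.
#'
#' @param clip logical; clamp output to `[0, 1.2]` (default TRUE).
#' @param epsilonGuard logical; mask near-zero denominators instead of
#'   erroring (default FALSE).
#' @param eps guard threshold as a fraction of the white dynamic range
#'   (default `1e-6`).
#' @examples
#' g <- wavelengthGrid(600, 10, 4)
#' white <- hypercube(array(9, c(3, 3, 4)), g)
#' dark  <- hypercube(array(1, c(3, 3, 4)), g)
#' raw   <- hypercube(array(5, c(3, 3, 4)), g)
#' cubeData(calibrate(raw, calibrationRefs(white, dark)))[1, 1, 1]  # 0.5
#' @export
setMethod("calibrate", signature(raw = "Hypercube", refs = "CalibrationRefs"),
  function(raw, refs, clip = TRUE, epsilonGuard = FALSE, eps = 1e-6) {
    validObject(raw); validObject(refs)
    if (isCalibrated(raw))
      stop("cube is already calibrated; refusing to calibrate twice")
    d <- dim(raw@data)
    dr <- dim(refs@white@data)
    if (dr[3] != d[3])
      stop("reference band count (", dr[3], ") does not match cube (", d[3], ")")
    if (abs(refs@white@grid@startNm - raw@grid@startNm) > 1e-6 ||
        abs(refs@white@grid@stepNm - raw@grid@stepNm) > 1e-9)
      stop("reference wavelength grid does not match cube grid")
    broadcast <- function(ref) {
      if (identical(dim(ref)[1:2], d[1:2])) return(ref)
      if (dim(ref)[1] == 1L && dim(ref)[2] == d[2]) {
        # column profile: replicate across rows
        out <- array(0, d)
        for (b in seq_len(d[3]))
          out[, , b] <- matrix(ref[1, , b], nrow = d[1], ncol = d[2], byrow = TRUE)
        return(out)
      }
      stop("reference dims ", paste(dim(ref), collapse = "x"),
           " not broadcastable to cube dims ", paste(d, collapse = "x"))
    }
    Iw <- broadcast(refs@white@data)
    Id <- broadcast(refs@dark@data)
    den <- Iw - Id
    dyn <- max(Iw) - min(Id)
    if (epsilonGuard) {
      bad <- abs(den) < eps * dyn
      if (any(bad)) {
        message(sum(bad), " degenerate reference element(s) masked to 0")
        den[bad] <- 1
      }
      refl <- (raw@data - Id) / den
      refl[bad] <- 0
    } else {
      bad <- den == 0
      if (any(bad)) {
        bandBad <- apply(bad, 3, sum)
        stop("degenerate reference (white == dark) at ", sum(bad),
             " element(s) in band(s) ",
             paste(which(bandBad > 0), collapse = ", "),
             "; enable epsilonGuard to mask dead pixels")
      }
      refl <- (raw@data - Id) / den
    }
    if (clip) refl <- pmin(pmax(refl, 0), 1.2)
    meta <- raw@metadata
    meta$calibrated <- TRUE
    hypercube(refl, raw@grid, meta)
  })

#' Average replicate reference frames
#'
#' Elementwise mean of one or more reference cubes (white or dark frames are
#' commonly captured several times and averaged to suppress shot noise).
#'
#' @param frames a list of [Hypercube-class] objects with identical
#'   dimensions and grids.
#' @return a [Hypercube-class], the elementwise mean.
#' @export
averageReference <- function(frames) {
  if (!length(frames)) stop("need at least one reference frame")
  stopifnot(all(vapply(frames, is, logical(1), "Hypercube")))
  d <- dim(frames[[1]]@data)
  for (f in frames[-1])
    if (!identical(dim(f@data), d)) stop("reference frames must share dimensions")
  acc <- array(0, d)
  for (f in frames) acc <- acc + f@data
  hypercube(acc / length(frames), frames[[1]]@grid, frames[[1]]@metadata)
}
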
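## Hypercube I/O: ENVI (.hdr + flat binary) and HDF5 (/data, /wavelengths_nm).
## Axis convention everywhere: (row, col, band), 1-based. ENVI "lines" are rows
## and "samples" are columns. Storage dtype is float32 in both formats; raw
## uint16 sensor cubes are promoted to float on read.

.enviHeaderPath <- function(path) paste0(path, ".hdr")

.enviInterleaves <- c("bil", "bip", "bsq")

#' Read a hyperspectral cube
#'
#' Reads an ENVI (text header plus flat binary) or HDF5 cube into a
#' [Hypercube-class]. All ENVI interleaves (BIL, BIP, BSQ) are normalized to
#' the (row, col, band) axis order.
#'
#' For ENVI, `path` is the binary data file; the header is expected at
#' `<path>.hdr` and must declare `samples`, `lines`, `bands`, `data type`,
#' `interleave` and a `wavelength` list. For HDF5 the file must contain
#' datasets `/data` (rows x cols x bands) and `/wavelengths_nm`; metadata is
#' read from attributes of `/data`.
#'
#' @param path file path (for ENVI, the binary file; header at `<path>.hdr`).
#' @param format `"envi"` or `"hdf5"`.
#' @return a [Hypercube-class].
#' @seealso [writeCube()], [bandIndex()]
#' @examples
#' cube <- hypercube(array(runif(60), c(4, 5, 3)), wavelengthGrid(600, 10, 3))
#' f <- tempfile(fileext = ".img")
#' writeCube(cube, f, "envi")
#' cube2 <- readCube(f, "envi")
#' all.equal(cubeData(cube2), cubeData(cube), tolerance = 1e-7)
#' @export
readCube <- function(path, format = c("envi", "hdf5")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "envi") .readEnvi(path) else .readH5(path)
}

#' Write a hyperspectral cube
#'
#' Writes a [Hypercube-class] to disk so that [readCube()] round-trips it
#' losslessly at float32 precision. ENVI wavelengths are written with two
#' decimals (the sensor-specification precision of the grids this package
#' models); a grid whose wavelengths carry more precision should use HDF5,
#' which stores the grid fields exactly.
#'
#' @param cube a [Hypercube-class].
#' @param path output path (ENVI: binary file, header written to `<path>.hdr`).
#' @param format `"envi"` or `"hdf5"`.
#' @param interleave ENVI interleave to write: `"bil"`, `"bip"` or `"bsq"`.
#' @return `invisible(path)`.
#' @export
writeCube <- function(cube, path, format = c("envi", "hdf5"),
                      interleave = c("bsq", "bil", "bip")) {
  stopifnot(is(cube, "Hypercube"))
  validObject(cube)
  format <- match.arg(format)
  interleave <- match.arg(interleave)
  if (format == "envi") .writeEnvi(cube, path, interleave) else .writeH5(cube, path)
  invisible(path)
}

.readEnvi <- function(path) {
  hdrPath <- .enviHeaderPath(path)
  if (!file.exists(hdrPath)) stop("ENVI header not found: ", hdrPath)
  hdr <- .parseEnviHeader(hdrPath)
  need <- c("samples", "lines", "bands", "data type", "interleave", "wavelength")
  miss <- setdiff(need, names(hdr))
  if (length(miss))
    stop("ENVI header missing required field(s): ", paste(miss, collapse = ", "))
  nc <- as.integer(hdr$samples); nr <- as.integer(hdr$lines); nb <- as.integer(hdr$bands)
  dtype <- as.integer(hdr$`data type`)
  il <- tolower(hdr$interleave)
  if (!il %in% .enviInterleaves) stop("unsupported ENVI interleave: ", il)
  wl <- as.numeric(strsplit(gsub("[{}\n]", "", hdr$wavelength), ",")[[1]])
  if (length(wl) != nb)
    stop("ENVI header declares ", nb, " bands but lists ", length(wl), " wavelengths")
  sz <- switch(as.character(dtype), "4" = 4L, "12" = 2L, "2" = 2L,
               stop("unsupported ENVI data type: ", dtype))
  n <- nr * nc * nb
  expect <- n * sz + as.integer(hdr$`header offset` %||% 0)
  if (file.size(path) != expect)
    stop("ENVI data size mismatch: expected ", expect, " bytes, found ", file.size(path))
  con <- file(path, "rb"); on.exit(close(con))
  off <- as.integer(hdr$`header offset` %||% 0)
  if (off > 0) readBin(con, "raw", off)
  vals <- if (dtype == 4L) {
    readBin(con, "numeric", n = n, size = 4L, endian = "little")
  } else {
    # uint16 (12) or int16 (2): promote to double
    v <- readBin(con, "integer", n = n, size = 2L,
                 signed = (dtype == 2L), endian = "little")
    as.numeric(v)
  }
  a <- switch(il,
    bsq = aperm(array(vals, c(nc, nr, nb)), c(2, 1, 3)),
    bil = aperm(array(vals, c(nc, nb, nr)), c(3, 1, 2)),
    bip = aperm(array(vals, c(nb, nc, nr)), c(3, 2, 1)))
  grid <- .gridFromWavelengths(wl)
  meta <- .metaFromDescription(hdr$description)
  hypercube(a, grid, meta)
}

.writeEnvi <- function(cube, path, interleave) {
  d <- dim(cube@data)
  wl <- wavelengths(cube)
  hdr <- c(
    "ENVI",
    sprintf("samples = %d", d[2]),
    sprintf("lines = %d", d[1]),
    sprintf("bands = %d", d[3]),
    "header offset = 0",
    "file type = ENVI Standard",
    "data type = 4",
    sprintf("interleave = %s", interleave),
    "byte order = 0",
    sprintf("description = {%s}", .metaToDescription(cube@metadata)),
    sprintf("wavelength units = Nanometers"),
    sprintf("wavelength = {%s}", paste(sprintf("%.2f", wl), collapse = ", ")))
  ok <- tryCatch({
    writeLines(hdr, .enviHeaderPath(path))
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop("cannot write ENVI header at ", .enviHeaderPath(path))
  vals <- switch(interleave,
    bsq = as.numeric(aperm(cube@data, c(2, 1, 3))),
    bil = as.numeric(aperm(cube@data, c(2, 3, 1))),
    bip = as.numeric(aperm(cube@data, c(3, 2, 1))))
  con <- tryCatch(file(path, "wb"), error = function(e)
    stop("cannot open for writing: ", path))
  on.exit(close(con))
  writeBin(vals, con, size = 4L, endian = "little")
}

.parseEnviHeader <- function(hdrPath) {
  lines <- readLines(hdrPath, warn = FALSE)
  if (!length(lines) || trimws(lines[1]) != "ENVI")
    stop("not an ENVI header (missing magic line): ", hdrPath)
  lines <- lines[-1]
  out <- list(); key <- NULL; buf <- NULL
  for (ln in lines) {
    if (is.null(key)) {
      m <- regmatches(ln, regexec("^\\s*([^=]+?)\\s*=\\s*(.*)$", ln))[[1]]
      if (length(m) < 3) next
      key <- tolower(trimws(m[2])); buf <- m[3]
    } else buf <- paste(buf, ln)
    if (grepl("\\{", buf) && !grepl("\\}", buf)) next  # continue multi-line list
    out[[key]] <- trimws(buf); key <- NULL; buf <- NULL
  }
  out
}

.gridFromWavelengths <- function(wl, tol = 1e-6) {
  if (length(wl) == 1L) return(wavelengthGrid(wl, 1, 1L))
  step <- (wl[length(wl)] - wl[1]) / (length(wl) - 1)
  if (step <= 0 || max(abs(diff(wl) - step)) > max(tol, 1e-3 * step))
    stop("wavelengths are not a uniform increasing grid")
  wavelengthGrid(wl[1], step, length(wl))
}

## metadata <-> ENVI description string, "key=value;key=value"
.metaToDescription <- function(meta) {
  keep <- meta[vapply(meta, function(v) is.atomic(v) && length(v) == 1L, logical(1))]
  paste(vapply(names(keep), function(k) sprintf("%s=%s", k, format(keep[[k]])),
               character(1)), collapse = "; ")
}

.metaFromDescription <- function(desc) {
  if (is.null(desc)) return(list())
  desc <- gsub("[{}]", "", desc)
  parts <- strsplit(desc, ";")[[1]]
  meta <- list()
  for (p in parts) {
    kv <- strsplit(p, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2) next
    k <- trimws(kv[1]); v <- trimws(kv[2])
    meta[[k]] <- if (v %in% c("TRUE", "FALSE")) as.logical(v)
      else if (grepl("^-?[0-9.]+$", v)) as.numeric(v) else v
  }
  meta
}

.readH5 <- function(path) {
  objs <- rhdf5::h5ls(path)$name
  if (!all(c("data", "wavelengths_nm") %in% objs))
    stop("HDF5 cube must contain datasets 'data' and 'wavelengths_nm'")
  a <- rhdf5::h5read(path, "data")
  wl <- as.numeric(rhdf5::h5read(path, "wavelengths_nm"))
  if (length(dim(a)) != 3L) stop("HDF5 'data' must be 3-D (rows x cols x bands)")
  if (dim(a)[3] != length(wl))
    stop("HDF5 band dimension (", dim(a)[3], ") does not match wavelengths (",
         length(wl), ")")
  attrs <- rhdf5::h5readAttributes(path, "data")
  meta <- lapply(attrs, function(v) if (length(v) == 1L) v[[1]] else v)
  if (!is.null(meta$calibrated)) meta$calibrated <- as.logical(meta$calibrated)
  rhdf5::h5closeAll()
  hypercube(array(as.numeric(a), dim(a)), .gridFromWavelengths(wl), meta)
}

.writeH5 <- function(cube, path) {
  if (file.exists(path)) unlink(path)
  ok <- tryCatch(rhdf5::h5createFile(path), error = function(e) FALSE)
  if (!isTRUE(ok)) stop("cannot create HDF5 file at ", path)
  d <- dim(cube@data)
  rhdf5::h5createDataset(path, "data", dims = d, H5type = "H5T_IEEE_F32LE")
  rhdf5::h5write(cube@data, path, "data")
  rhdf5::h5write(wavelengths(cube), path, "wavelengths_nm")
  fid <- rhdf5::H5Fopen(path)
  did <- rhdf5::H5Dopen(fid, "data")
  keep <- cube@metadata[vapply(cube@metadata,
                               function(v) is.atomic(v) && length(v) == 1L, logical(1))]
  for (k in names(keep)) {
    v <- keep[[k]]
    if (is.logical(v)) v <- as.integer(v)
    rhdf5::h5writeAttribute(v, did, k)
  }
  rhdf5::H5Dclose(did); rhdf5::H5Fclose(fid)
  rhdf5::h5closeAll()
}

#' Band index nearest to a wavelength
#'
#' Maps a wavelength in nanometres to the nearest band index of a
#' [WavelengthGrid-class] (1-based). Exact midpoints between two bands round
#' toward the lower index.
#'
#' @param grid a [WavelengthGrid-class].
#' @param nm wavelength in nanometres; must lie within the grid range
#'   extended by half a step on either side.
#' @return integer band index in `1:nBands(grid)`.
#' @examples
#' g <- wavelengthGrid(597.21, 4.14, 268)
#' bandIndex(g, 597.21)   # 1
#' bandIndex(g, 1703.93)  # 268
#' @export
bandIndex <- function(grid, nm) {
  stopifnot(is(grid, "WavelengthGrid"), length(nm) == 1L, is.finite(nm))
  lo <- grid@startNm - grid@stepNm / 2
  hi <- grid@startNm + (grid@count - 1) * grid@stepNm + grid@stepNm / 2
  if (nm < lo || nm > hi)
    stop(sprintf("wavelength %.2f nm outside grid range [%.2f, %.2f]", nm, lo, hi))
  x <- (nm - grid@startNm) / grid@stepNm          # fractional 0-based position
  i <- ceiling(x - 0.5 - 1e-9)                    # nearest; exact midpoint -> lower
  as.integer(min(max(i, 0), grid@count - 1)) + 1L
}

#' RGB composite of three bands
#'
#' Builds a displayable 3-channel image from three (not necessarily
#' distinct) bands, each min-max scaled to `[0, 1]` independently. A
#' constant band scales to all zeros.
#'
#' @param cube a [Hypercube-class].
#' @param r,g,b 1-based band indices for the red, green and blue channels.
#' @return numeric array rows x cols x 3 in `[0, 1]`.
#' @export
rgbComposite <- function(cube, r, g, b) {
  stopifnot(is(cube, "Hypercube"))
  nb <- nBands(cube)
  idx <- c(r, g, b)
  if (any(idx < 1L | idx > nb | idx != as.integer(idx)))
    stop("band indices must be integers in 1..", nb)
  scale01 <- function(m) {
    rng <- range(m)
    if (rng[2] - rng[1] <= 0) return(array(0, dim(m)))
    (m - rng[1]) / (rng[2] - rng[1])
  }
  d <- dim(cube@data)
  out <- array(0, c(d[1], d[2], 3))
  for (k in 1:3) out[, , k] <- scale01(cube@data[, , idx[k]])
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
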
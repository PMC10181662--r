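## Seed chip persistence (HDF5): /data, /wavelengths_nm, /mask plus label
## attributes. Used by the command-line workflow to pass extracted seeds
## between stages.

#' Write a seed cube to HDF5
#'
#' Stores the chip (`/data`), its wavelength grid (`/wavelengths_nm`), the
#' seed mask (`/mask`) and the class/exposure/source labels as attributes.
#'
#' @param seed a [SeedCube-class].
#' @param path output `.h5` path.
#' @return `invisible(path)`.
#' @export
writeSeedCube <- function(seed, path) {
  stopifnot(is(seed, "SeedCube"))
  cube <- hypercube(seed@data, seed@grid,
                    list(calibrated = TRUE, class = seed@classLabel,
                         exposure_h = seed@exposureLabel, source = seed@source))
  writeCube(cube, path, "hdf5")
  rhdf5::h5write(seed@mask * 1L, path, "mask")
  if (all(is.finite(seed@offset)))
    rhdf5::h5write(as.numeric(seed@offset), path, "offset")
  rhdf5::h5closeAll()
  invisible(path)
}

#' Read a seed cube from HDF5
#'
#' @param path a `.h5` file written by `writeSeedCube()`.
#' @return a [SeedCube-class].
#' @export
readSeedCube <- function(path) {
  cube <- readCube(path, "hdf5")
  objs <- rhdf5::h5ls(path)$name
  mask <- if ("mask" %in% objs) rhdf5::h5read(path, "mask") > 0
    else apply(abs(cubeData(cube)), c(1, 2), sum) > 0
  offset <- if ("offset" %in% objs) as.numeric(rhdf5::h5read(path, "offset"))
    else c(NA_real_, NA_real_)
  rhdf5::h5closeAll()
  meta <- cubeMeta(cube)
  new("SeedCube", data = cubeData(cube), mask = mask, grid = cube@grid,
      classLabel = as.character(meta$class %||% NA_character_),
      exposureLabel = as.numeric(meta$exposure_h %||% NA_real_),
      source = as.character(meta$source %||% basename(path)),
      offset = offset)
}
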
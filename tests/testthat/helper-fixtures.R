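# Small builders shared across tests. Everything is generated in code;
# cubes use float32-representable values where bit-exact round trips are
# asserted.

tinyGrid <- function(n = 4L, start = 600, step = 10) wavelengthGrid(start, step, n)

tinyCube <- function(dims = c(4L, 5L, 3L), value = NULL, seed = 1L,
                     grid = NULL, meta = list()) {
  if (is.null(grid)) grid <- tinyGrid(dims[3])
  data <- if (!is.null(value)) array(value, dims) else {
    set.seed(seed)
    # quantized to float32-exact values so storage round trips are bit-exact
    array(round(runif(prod(dims)) * 1024) / 1024, dims)
  }
  hypercube(data, grid, meta)
}

constRefs <- function(dims, white = 9, dark = 1, grid = NULL) {
  if (is.null(grid)) grid <- tinyGrid(dims[3])
  calibrationRefs(hypercube(array(white, dims), grid),
                  hypercube(array(dark, dims), grid))
}

# mask of an axis-aligned ellipse centred in an r x c frame
ellipseMaskFixture <- function(r, c, a, b, theta = 0) {
  cr <- (r + 1) / 2; cc <- (c + 1) / 2
  rr <- matrix(seq_len(r), r, c) - cr
  cc2 <- matrix(seq_len(c), r, c, byrow = TRUE) - cc
  x <- rr * cos(theta) + cc2 * sin(theta)
  y <- -rr * sin(theta) + cc2 * cos(theta)
  (x / a)^2 + (y / b)^2 <= 1
}

seedCubeFixture <- function(h = 8L, w = 8L, nb = 3L, value = 0.5, a = 3, b = 2,
                            class = "A", exposure = 168, source = "p#1") {
  m <- ellipseMaskFixture(h, w, a, b)
  data <- array(0, c(h, w, nb))
  for (k in seq_len(nb)) data[, , k][m] <- value
  new("SeedCube", data = data, mask = m, grid = tinyGrid(nb),
      classLabel = class, exposureLabel = exposure, source = source,
      offset = c(1, 1))
}

# independent nested-loop oracle for valid 3-D convolution
convOracle <- function(input, kernel, bias) {
  di <- dim(input); dk <- dim(kernel)
  Do <- di[2] - dk[3] + 1; Ho <- di[3] - dk[4] + 1; Wo <- di[4] - dk[5] + 1
  out <- array(0, c(dk[1], Do, Ho, Wo))
  for (cp in 1:dk[1]) for (i in 1:Do) for (j in 1:Ho) for (k in 1:Wo) {
    acc <- bias[cp]
    for (c in 1:di[1]) for (d in 1:dk[3]) for (h in 1:dk[4]) for (w in 1:dk[5])
      acc <- acc + input[c, i + d - 1, j + h - 1, k + w - 1] *
        kernel[cp, c, d, h, w]
    out[cp, i, j, k] <- acc
  }
  out
}

# independent window-scan oracle for max pooling with clipped border windows
poolOracle <- function(input, pool) {
  di <- dim(input)
  Do <- ceiling(di[2] / pool[1]); Ho <- ceiling(di[3] / pool[2])
  Wo <- ceiling(di[4] / pool[3])
  out <- array(-Inf, c(di[1], Do, Ho, Wo))
  for (c in 1:di[1]) for (i in 1:Do) for (j in 1:Ho) for (k in 1:Wo) {
    ds <- ((i - 1) * pool[1] + 1):min(i * pool[1], di[2])
    hs <- ((j - 1) * pool[2] + 1):min(j * pool[2], di[3])
    ws <- ((k - 1) * pool[3] + 1):min(k * pool[3], di[4])
    out[c, i, j, k] <- max(input[c, ds, hs, ws])
  }
  out
}
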
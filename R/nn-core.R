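## Shared neural-network primitives: dense layers, softmax cross-entropy,
## He initialization and Adam. Both classifiers are trained with plain
## minibatch Adam on categorical cross-entropy; all randomness (shuffling,
## initialization) is driven by R's RNG so a single rngSeed makes training
## deterministic on a single thread.

.softmaxRows <- function(Z) {
  Z <- Z - apply(Z, 1, max)
  E <- exp(Z)
  E / rowSums(E)
}

.oneHot <- function(y, k) {
  M <- matrix(0, length(y), k)
  M[cbind(seq_along(y), as.integer(y))] <- 1
  M
}

.crossEntropy <- function(P, yInt) {
  -mean(log(pmax(P[cbind(seq_along(yInt), yInt)], 1e-12)))
}

.heInit <- function(nIn, nOut) {
  matrix(rnorm(nIn * nOut, sd = sqrt(2 / nIn)), nIn, nOut)
}

#' Dense layer forward pass
#'
#' Computes `activation(X %*% W + b)`: the affine map plus bias followed by
#' the layer non-linearity (`relu` for hidden layers, `softmax` for the
#' output layer, `linear` for none).
#'
#' @param X numeric matrix n x nIn.
#' @param W numeric matrix nIn x nOut.
#' @param b numeric vector length nOut.
#' @param activation `"relu"`, `"softmax"` or `"linear"`.
#' @return numeric matrix n x nOut.
#' @examples
#' denseForward(matrix(c(1, 2), 1), matrix(c(1, 1), 2), -5)  # ReLU(-2) = 0
#' @export
denseForward <- function(X, W, b, activation = c("relu", "softmax", "linear")) {
  activation <- match.arg(activation)
  X <- as.matrix(X)
  if (ncol(X) != nrow(W))
    stop("shape mismatch: X has ", ncol(X), " columns but W has ", nrow(W), " rows")
  if (length(b) != ncol(W))
    stop("bias length (", length(b), ") must equal output width (", ncol(W), ")")
  Z <- sweep(X %*% W, 2, b, `+`)
  switch(activation,
         relu = pmax(Z, 0),
         softmax = .softmaxRows(Z),
         linear = Z)
}

## Adam optimizer over a flat list of parameter arrays.
.adamInit <- function(params) {
  list(m = lapply(params, function(p) array(0, dim(p) %||% length(p))),
       v = lapply(params, function(p) array(0, dim(p) %||% length(p))),
       t = 0L)
}

.adamStep <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  for (i in seq_along(params)) {
    state$m[[i]] <- beta1 * state$m[[i]] + (1 - beta1) * grads[[i]]
    state$v[[i]] <- beta2 * state$v[[i]] + (1 - beta2) * grads[[i]]^2
    mhat <- state$m[[i]] / (1 - beta1^state$t)
    vhat <- state$v[[i]] / (1 - beta2^state$t)
    params[[i]] <- params[[i]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

## Dense multilayer forward with caches for backprop.
## params: list(W = list, b = list); last layer softmax, others ReLU.
.mlpForward <- function(X, params) {
  L <- length(params$W)
  A <- vector("list", L + 1L)   # activations; A[[1]] is the input
  A[[1]] <- X
  for (l in seq_len(L)) {
    Z <- sweep(A[[l]] %*% params$W[[l]], 2, params$b[[l]], `+`)
    A[[l + 1L]] <- if (l < L) pmax(Z, 0) else .softmaxRows(Z)
  }
  A
}

## Backward for softmax + cross-entropy through ReLU hidden layers.
.mlpBackward <- function(A, params, Y) {
  L <- length(params$W)
  n <- nrow(Y)
  gW <- vector("list", L); gb <- vector("list", L)
  delta <- (A[[L + 1L]] - Y) / n          # softmax-CE gradient at the output
  for (l in rev(seq_len(L))) {
    gW[[l]] <- crossprod(A[[l]], delta)
    gb[[l]] <- colSums(delta)
    if (l > 1L)
      delta <- (delta %*% t(params$W[[l]])) * (A[[l]] > 0)
  }
  list(W = gW, b = gb)
}
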
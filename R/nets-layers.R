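# Minimal 1-D neural network engine: forward/backward primitives, Glorot
# initialisation, and Adam. No deep-learning framework is assumed; all
# heavy lifting is BLAS matrix products over im2col patch matrices.
#
# Activations flow as 3-D arrays (n, L, C) through conv/pool layers and as
# (n, d) matrices through dense layers. A model is a list of layer
# descriptors; a forward pass returns caches sufficient for the exact
# backward pass (used both for training and for guided backpropagation).

glorot_uniform <- function(fan_in, fan_out, dims) {
  lim <- sqrt(6 / (fan_in + fan_out))
  array(stats::runif(prod(dims), -lim, lim), dims)
}

# --- replicate padding ------------------------------------------------------

pad_replicate_fwd <- function(X, pad) {
  L <- dim(X)[2]
  X[, c(rep(1L, pad), seq_len(L), rep(L, pad)), , drop = FALSE]
}

pad_replicate_bwd <- function(dY, pad, L) {
  # gradients of the replicated samples accumulate onto the edge samples
  dX <- dY[, pad + seq_len(L), , drop = FALSE]
  if (pad > 0L) {
    d <- dim(dX)
    lo <- apply(dY[, seq_len(pad), , drop = FALSE], c(1, 3), sum)
    hi <- apply(dY[, pad + L + seq_len(pad), , drop = FALSE], c(1, 3), sum)
    s1 <- dX[, 1L, , drop = FALSE]; dim(s1) <- c(d[1], d[3])
    sL <- dX[, L, , drop = FALSE]; dim(sL) <- c(d[1], d[3])
    dX[, 1L, ] <- s1 + lo
    dX[, L, ] <- sL + hi
  }
  dX
}

# --- 1-D convolution (valid) ------------------------------------------------

im2col <- function(X, K) {
  d <- dim(X); n <- d[1]; L <- d[2]; Cin <- d[3]
  L_out <- L - K + 1L
  P <- array(0, c(n, L_out, K, Cin))
  for (k in seq_len(K)) P[, , k, ] <- X[, k:(k + L_out - 1L), , drop = FALSE]
  dim(P) <- c(n * L_out, K * Cin)
  P
}

conv1d_fwd <- function(X, W, b) {
  # X: (n, L, Cin); W: (K, Cin, Cout); b: (Cout)
  dw <- dim(W); K <- dw[1]; Cin <- dw[2]; Cout <- dw[3]
  n <- dim(X)[1]; L_out <- dim(X)[2] - K + 1L
  P <- im2col(X, K)
  Y <- P %*% matrix(W, K * Cin, Cout)
  Y <- sweep(Y, 2L, b, "+")
  dim(Y) <- c(n, L_out, Cout)
  list(Y = Y, P = P)
}

conv1d_bwd <- function(dY, cache_P, X_dim, W) {
  dw <- dim(W); K <- dw[1]; Cin <- dw[2]; Cout <- dw[3]
  n <- X_dim[1]; L <- X_dim[2]
  L_out <- L - K + 1L
  dYm <- dY; dim(dYm) <- c(n * L_out, Cout)
  dW <- crossprod(cache_P, dYm)
  dim(dW) <- c(K, Cin, Cout)
  db <- colSums(dYm)
  dP <- dYm %*% t(matrix(W, K * Cin, Cout))
  dim(dP) <- c(n, L_out, K, Cin)
  dX <- array(0, X_dim)
  for (k in seq_len(K)) {
    dPk <- dP[, , k, , drop = FALSE]
    dim(dPk) <- c(n, L_out, Cin)
    dX[, k:(k + L_out - 1L), ] <- dX[, k:(k + L_out - 1L), , drop = FALSE] + dPk
  }
  list(dX = dX, dW = dW, db = db)
}

# --- max pooling (size 2, stride 2), ties to the first index ---------------

maxpool2_fwd <- function(X) {
  L <- dim(X)[2]
  if (L %% 2L != 0L) stopf("maxpool2: length %d not divisible by 2", L)
  i1 <- seq(1L, L, by = 2L)
  x1 <- X[, i1, , drop = FALSE]
  x2 <- X[, i1 + 1L, , drop = FALSE]
  first <- x1 >= x2 # ties routed to the first element
  list(Y = ifelse(first, x1, x2), first = first)
}

maxpool2_bwd <- function(dY, first, X_dim) {
  dX <- array(0, X_dim)
  L <- X_dim[2]
  i1 <- seq(1L, L, by = 2L)
  dX[, i1, ] <- dY * first
  dX[, i1 + 1L, ] <- dY * !first
  dX
}

# --- ReLU -------------------------------------------------------------------

relu_fwd <- function(X) {
  pos <- X > 0
  list(Y = X * pos, pos = pos)
}

# standard backward: gate by forward sign; guided additionally zeroes
# negative incoming gradients (the guided-backpropagation rule)
relu_bwd <- function(dY, pos, guided = FALSE) {
  g <- dY * pos
  if (guided) g <- g * (dY > 0)
  g
}

# --- dense ------------------------------------------------------------------

dense_fwd <- function(X, W, b) sweep(X %*% W, 2L, b, "+")

dense_bwd <- function(dY, X, W) {
  list(dX = dY %*% t(W), dW = crossprod(X, dY), db = colSums(dY))
}

# --- softmax + weighted cross-entropy --------------------------------------

softmax_rows <- function(Z) {
  Z <- Z - apply(Z, 1L, max)
  E <- exp(Z)
  E / rowSums(E)
}

#' Class-weighted categorical cross-entropy
#'
#' `L = mean_i w(y_i) * (-log p_i[y_i])`: the categorical cross-entropy of
#' each example scaled by its true class's weight, averaged over the batch.
#' Probabilities at the true class are floored at 1e-12 before the log.
#'
#' @param y_onehot n x C one-hot matrix (or integer class vector 1..C).
#' @param p n x C matrix of predicted probabilities (rows sum to 1).
#' @param weights length-C class weight vector (default all 1).
#' @return scalar batch loss.
#' @export
weighted_cross_entropy <- function(y_onehot, p, weights = NULL) {
  if (!is.matrix(y_onehot)) y_onehot <- onehot(y_onehot, ncol(p))
  stopifnot(all(dim(y_onehot) == dim(p)))
  weights <- weights %||% rep(1, ncol(p))
  p_true <- rowSums(p * y_onehot)
  if (any(p_true < 1e-12)) {
    oct_log("weighted_cross_entropy: clamped %d probabilities at 1e-12", sum(p_true < 1e-12))
    p_true <- pmax(p_true, 1e-12)
  }
  w <- as.vector(y_onehot %*% weights)
  mean(-w * log(p_true))
}

onehot <- function(y, n_classes) {
  Y <- matrix(0, length(y), n_classes)
  Y[cbind(seq_along(y), as.integer(y))] <- 1
  Y
}

# gradient of the batch loss w.r.t. the pre-softmax logits
ce_softmax_grad <- function(P, Y_onehot, weights) {
  w <- as.vector(Y_onehot %*% weights)
  (P - Y_onehot) * w / nrow(P)
}

# --- Adam -------------------------------------------------------------------

adam_init <- function(params) {
  list(m = lapply(params, function(p) array(0, dim(p) %||% length(p))),
       v = lapply(params, function(p) array(0, dim(p) %||% length(p))),
       t = 0L)
}

adam_step <- function(state, params, grads, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (i in seq_along(params)) {
    g <- grads[[i]]
    state$m[[i]] <- beta1 * state$m[[i]] + (1 - beta1) * g
    state$v[[i]] <- beta2 * state$v[[i]] + (1 - beta2) * g * g
    mhat <- state$m[[i]] / bc1
    vhat <- state$v[[i]] / bc2
    params[[i]] <- params[[i]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(state = state, params = params)
}
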
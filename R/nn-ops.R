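# Primitive differentiable operations for the segmentation network.
#
# Feature maps are stored as dense matrices X of shape (N x C) with
# N = B * H * W rows ordered batch-major then column-major within each image
# (row = (b-1)*H*W + (w-1)*H + h). Convolutions are realized as im2col
# gathers followed by one BLAS matrix multiplication, which is where nearly
# all the arithmetic happens; index matrices are cached per spatial shape.

.nn_cache <- new.env(parent = emptyenv())

nn_cache_get <- function(key, builder) {
  if (!exists(key, envir = .nn_cache, inherits = FALSE)) {
    assign(key, builder(), envir = .nn_cache)
  }
  get(key, envir = .nn_cache, inherits = FALSE)
}

# per-offset row shifts of the 3x3 neighbourhood on the flattened layout:
# delta_k = dw*H + dh, plus the rows whose neighbour leaves the image
conv_shift_info <- function(H, W, B) {
  key <- paste("shift", H, W, B, sep = "_")
  nn_cache_get(key, function() {
    HW <- H * W
    hh <- rep(seq_len(H), W)
    ww <- rep(seq_len(W), each = H)
    deltas <- integer(9)
    invalid <- vector("list", 9)
    k <- 1L
    for (dw in -1:1) {
      for (dh in -1:1) {
        deltas[k] <- dw * H + dh
        bad1 <- which(hh + dh < 1 | hh + dh > H | ww + dw < 1 | ww + dw > W)
        bad <- if (B > 1) as.vector(outer(bad1, (0:(B - 1)) * HW, "+")) else bad1
        invalid[[k]] <- as.integer(bad)
        k <- k + 1L
      }
    }
    list(delta = deltas, invalid = invalid)
  })
}

# (N/4 x 4) input rows feeding each 2x2 max-pool output
pool_indices <- function(H, W, B) {
  key <- paste("pool", H, W, B, sep = "_")
  nn_cache_get(key, function() {
    stopifnot(H %% 2 == 0, W %% 2 == 0)
    H2 <- H %/% 2
    W2 <- W %/% 2
    hh <- rep(seq_len(H2), W2)
    ww <- rep(seq_len(W2), each = H2)
    base <- cbind(
      (2 * ww - 2) * H + (2 * hh - 1),
      (2 * ww - 2) * H + (2 * hh),
      (2 * ww - 1) * H + (2 * hh - 1),
      (2 * ww - 1) * H + (2 * hh)
    )
    out <- matrix(0L, H2 * W2 * B, 4)
    for (b in seq_len(B)) {
      out[((b - 1L) * H2 * W2 + 1L):(b * H2 * W2), ] <- base + (b - 1L) * H * W
    }
    out
  })
}

# parent (coarse) row feeding each fine output row of a 2x nearest upsample;
# coarse grid is (H x W), fine grid (2H x 2W)
upsample_indices <- function(H, W, B) {
  key <- paste("up", H, W, B, sep = "_")
  nn_cache_get(key, function() {
    H2 <- 2L * H
    W2 <- 2L * W
    hh <- rep(seq_len(H2), W2)
    ww <- rep(seq_len(W2), each = H2)
    base <- ((ww + 1L) %/% 2L - 1L) * H + (hh + 1L) %/% 2L
    out <- integer(H2 * W2 * B)
    for (b in seq_len(B)) {
      out[((b - 1L) * H2 * W2 + 1L):(b * H2 * W2)] <- base + (b - 1L) * H * W
    }
    out
  })
}

# Weight matrices are (9*Cin x Cout) with rows in offset-major blocks:
# rows (k-1)*Cin+1 .. k*Cin hold the Cin x Cout map of offset k.
conv2d_forward <- function(X, Wt, bias, sinfo) {
  N <- nrow(X)
  C <- ncol(X)
  Y <- matrix(rep(bias, each = N), N, ncol(Wt))
  for (k in 1:9) {
    Wk <- Wt[((k - 1L) * C + 1L):(k * C), , drop = FALSE]
    Zk <- X %*% Wk
    add_shifted(Y, Zk, sinfo$delta[k], sinfo$invalid[[k]])
  }
  list(Y = Y, X = X)
}

conv2d_backward <- function(dY, cache_X, Wt, sinfo) {
  X <- cache_X
  N <- nrow(X)
  C <- ncol(X)
  db <- colSums(dY)
  dW <- matrix(0, 9L * C, ncol(Wt))
  dX <- matrix(0, N, C)
  for (k in 1:9) {
    rows <- ((k - 1L) * C + 1L):(k * C)
    dW[rows, ] <- crossprod_shifted(X, dY, sinfo$delta[k], sinfo$invalid[[k]])
    acc_shifted_product(dX, dY, Wt[rows, , drop = FALSE],
                        sinfo$delta[k], sinfo$invalid[[k]])
  }
  list(dX = dX, dW = dW, db = db)
}

bn_forward <- function(X, gamma, beta, running, training, momentum = 0.1, eps = 1e-5) {
  N <- nrow(X)
  if (training) {
    mu <- colMeans(X)
    v <- pmax(colMeans(X * X) - mu^2, 0)
    istd <- 1 / sqrt(v + eps)
    running$mean <- (1 - momentum) * running$mean + momentum * mu
    running$var <- (1 - momentum) * running$var + momentum * v
  } else {
    mu <- running$mean
    istd <- 1 / sqrt(running$var + eps)
  }
  xhat <- matrix(0, N, ncol(X))
  Y <- bn_apply(X, mu, istd, gamma, beta, xhat)
  list(Y = Y, xhat = xhat, istd = istd, running = running)
}

bn_backward <- function(dY, cache, gamma) {
  dbeta <- colSums(dY)
  dgamma <- colSums(dY * cache$xhat)
  dX <- bn_input_grad(dY, cache$xhat, gamma, cache$istd,
                      dbeta * gamma, dgamma * gamma)
  list(dX = dX, dgamma = dgamma, dbeta = dbeta)
}

relu_forward <- function(X) {
  mask <- X > 0
  list(Y = X * mask, mask = mask)
}

maxpool_forward <- function(X, pidx) {
  M <- X[pidx[, 1], , drop = FALSE]
  A <- matrix(1L, nrow(M), ncol(M))
  for (k in 2:4) {
    Ck <- X[pidx[, k], , drop = FALSE]
    upd <- Ck > M
    M[upd] <- Ck[upd]
    A[upd] <- k
  }
  list(Y = M, argmax = A)
}

maxpool_backward <- function(dY, argmax, pidx, N_in) {
  dX <- matrix(0, N_in, ncol(dY))
  for (k in 1:4) {
    contrib <- dY * (argmax == k)
    dX[pidx[, k], ] <- dX[pidx[, k], , drop = FALSE] + contrib
  }
  dX
}

upsample_forward <- function(X, uidx) {
  X[uidx, , drop = FALSE]
}

upsample_backward <- function(dY, uidx, N_in) {
  out <- rowsum(dY, group = uidx)
  # every parent has exactly four children, so all groups 1..N_in appear
  dX <- matrix(0, N_in, ncol(dY))
  dX[as.integer(rownames(out)), ] <- out
  dX
}

sigmoid <- function(x) 1 / (1 + exp(-x))

softmax_rows <- function(Z) {
  m <- matrixStats_rowMaxs(Z)
  E <- exp(Z - m)
  E / rowSums(E)
}

# rowMaxs without a matrixStats dependency
matrixStats_rowMaxs <- function(Z) {
  out <- Z[, 1]
  for (j in seq_len(ncol(Z))[-1]) out <- pmax(out, Z[, j])
  out
}

adam_step <- function(param, grad, state, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1
  state$m <- beta1 * state$m + (1 - beta1) * grad
  state$v <- beta2 * state$v + (1 - beta2) * grad * grad
  mhat <- state$m / (1 - beta1^state$t)
  vhat <- state$v / (1 - beta2^state$t)
  list(param = param - lr * mhat / (sqrt(vhat) + eps), state = state)
}
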
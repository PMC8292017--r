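# Minimal neural-network numerics used by the CNN and LSTM models.
#
# CNN feature maps travel transposed as plain matrices of dim C x (H*W*N)
# whose columns are ordered (h, w, n) with h fastest. In this layout every
# per-channel operation (batch norm, bias) is a recycled vector operation,
# and a 3x3 "same" convolution decomposes into 9 GEMMs over spatially
# shifted copies of the map, where each shift is one contiguous
# column-block copy plus zeroing of the border columns. All forward
# functions return the output plus the cache their backward pass needs.
# Nothing here is specific to the architecture; the wiring lives in
# model-cnn.R and model-hybrid.R.

# K9 is (9*Cin) x Cout with row blocks ordered by offset k = 1..9,
# dh = (k-1) %% 3 - 1, dw = (k-1) %/% 3 - 1; block k holds the (Cin x Cout)
# kernel slice for that offset. The shift-GEMM loop lives in C++
# (src/nn_kernels.cpp).
conv3_fwd <- function(M, H, W, N, K9, b) {
  list(out = cpp_conv3_fwd(M, H, W, N, K9, b),
       cache = list(M = M, H = H, W = W, N = N, K9 = K9))
}

conv3_bwd <- function(cache, dOut, need_dx = TRUE) {
  r <- cpp_conv3_bwd(cache$M, cache$K9, dOut, cache$H, cache$W, cache$N,
                     need_dx)
  list(dM = if (need_dx) r$dM else NULL, dK = r$dK, db = drop(r$db))
}

# 1x1 convolution: K is Cin x Cout.
conv1_fwd <- function(M, K, b) {
  out <- crossprod(K, M) + b
  list(out = out, cache = list(M = M, K = K))
}

conv1_bwd <- function(cache, dOut) {
  list(dM = cache$K %*% dOut, dK = cache$M %*% t(dOut), db = rowSums(dOut))
}

# Fused per-channel batch norm + ReLU over all spatial positions and batch
# items (the composite-layer entry everywhere in the CNN).
bn_relu_fwd <- function(M, gamma, beta, run_mean, run_var, training,
                        momentum = 0.1, eps = 1e-5) {
  if (training) {
    st <- cpp_row_stats(M)
    m <- drop(st$mean); v <- drop(st$var)
    run_mean <- (1 - momentum) * run_mean + momentum * m
    run_var <- (1 - momentum) * run_var + momentum * v
  } else {
    m <- run_mean; v <- run_var
  }
  invstd <- 1 / sqrt(v + eps)
  out <- cpp_bn_relu_fwd(M, gamma, beta, m, invstd)
  list(out = out, run_mean = run_mean, run_var = run_var,
       cache = list(out = out, M = M, m = m, invstd = invstd, gamma = gamma))
}

bn_relu_bwd <- function(cache, dOut) {
  r <- cpp_bn_relu_bwd(dOut, cache$out, cache$M, cache$m, cache$gamma,
                       cache$invstd)
  list(dM = r$dM, dgamma = drop(r$dgamma), dbeta = drop(r$dbeta))
}

relu_fwd <- function(M) {
  out <- M * (M > 0)
  list(out = out, cache = M > 0)
}
relu_bwd <- function(cache, dOut) dOut * cache

# 2x2 average pooling, stride 2; odd trailing rows/columns are dropped.
pool2_fwd <- function(M, H, W, N) {
  C <- nrow(M)
  A <- M; dim(A) <- c(C, H, W, N)
  H2 <- H %/% 2; W2 <- W %/% 2
  hi <- seq(1, 2 * H2, by = 2); wi <- seq(1, 2 * W2, by = 2)
  out <- (A[, hi, wi, , drop = FALSE] + A[, hi + 1, wi, , drop = FALSE] +
          A[, hi, wi + 1, , drop = FALSE] + A[, hi + 1, wi + 1, , drop = FALSE]) / 4
  dim(out) <- c(C, H2 * W2 * N)
  list(out = out, cache = list(H = H, W = W, N = N, C = C, H2 = H2, W2 = W2))
}

pool2_bwd <- function(cache, dOut) {
  H <- cache$H; W <- cache$W; N <- cache$N; C <- cache$C
  H2 <- cache$H2; W2 <- cache$W2
  dY <- dOut / 4; dim(dY) <- c(C, H2, W2, N)
  dX <- array(0, c(C, H, W, N))
  hi <- seq(1, 2 * H2, by = 2); wi <- seq(1, 2 * W2, by = 2)
  dX[, hi, wi, ] <- dY
  dX[, hi + 1, wi, ] <- dY
  dX[, hi, wi + 1, ] <- dY
  dX[, hi + 1, wi + 1, ] <- dY
  dim(dX) <- c(C, H * W * N)
  dX
}

# Global average pooling; returns the conventional N x C orientation for the
# fully connected layers.
gap_fwd <- function(M, H, W, N) {
  C <- nrow(M)
  A <- aperm(array(M, c(C, H * W, N)), c(2, 1, 3))
  S <- colSums(A)                       # C x N
  list(out = t(S) / (H * W), cache = list(H = H, W = W, N = N, C = C))
}
gap_bwd <- function(cache, dOut) {
  # dOut: N x C -> C x (H*W*N)
  t(dOut)[, rep(seq_len(cache$N), each = cache$H * cache$W), drop = FALSE] /
    (cache$H * cache$W)
}

dense_fwd <- function(X, W, b) {
  out <- X %*% W
  out <- out + rep(b, each = nrow(out))
  list(out = out, cache = X)
}
dense_bwd <- function(cache, W, dOut) {
  list(dX = dOut %*% t(W), dW = crossprod(cache, dOut), db = colSums(dOut))
}

softmax_rows <- function(Z) {
  Z <- Z - apply(Z, 1, max)
  E <- exp(Z)
  E / rowSums(E)
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# ---- Adam ------------------------------------------------------------------

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr = 1e-3, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

# He-style initialization helpers (seeded by the caller).
.init_mat <- function(nr, nc, fan_in) {
  matrix(stats::rnorm(nr * nc, sd = sqrt(2 / fan_in)), nr, nc)
}
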
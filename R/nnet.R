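# Internal training engine for the convolutional classifier family.
#
# A small, self-contained implementation of the layers the model family
# needs — 1D convolution (length-preserving "same" padding) via im2col and
# BLAS matrix products, non-overlapping max-pooling with floor truncation,
# inverted dropout, batch normalization, dense layers, sigmoid output,
# binary cross-entropy, and the Adam optimizer. Everything is deterministic
# under a fixed seed. Shapes follow the (batch, length, channels)
# convention throughout.

glorot_init <- function(nrow, ncol) {
  lim <- sqrt(6 / (nrow + ncol))
  matrix(stats::runif(nrow * ncol, -lim, lim), nrow, ncol)
}

# X: (B, Lx, Cin) array; W: (k*Cin, F); b: length F.
# Returns pre-activation as a (B*Lx, F) matrix (rows ordered batch-fastest)
# plus the im2col matrix for the backward pass.
conv1d_forward <- function(X, W, b, k) {
  d <- dim(X); B <- d[1]; Lx <- d[2]; Cin <- d[3]
  pad <- (k - 1L) %/% 2L
  Xp <- array(0, c(B, Lx + 2L * pad, Cin))
  Xp[, pad + seq_len(Lx), ] <- X
  M <- matrix(0, B * Lx, k * Cin)
  for (j in seq_len(k)) {
    sl <- Xp[, j:(j + Lx - 1L), , drop = FALSE]
    dim(sl) <- c(B * Lx, Cin)
    M[, ((j - 1L) * Cin + 1L):(j * Cin)] <- sl
  }
  Z <- M %*% W
  Z <- Z + matrix(b, nrow(Z), length(b), byrow = TRUE)
  list(Z = Z, M = M, B = B, Lx = Lx, Cin = Cin, k = k)
}

# dZ: gradient at pre-activation, (B*Lx, F)
conv1d_backward <- function(dZ, cache, W) {
  B <- cache$B; Lx <- cache$Lx; Cin <- cache$Cin; k <- cache$k
  pad <- (k - 1L) %/% 2L
  dW <- crossprod(cache$M, dZ)
  db <- colSums(dZ)
  dM <- dZ %*% t(W)
  dXp <- array(0, c(B, Lx + 2L * pad, Cin))
  for (j in seq_len(k)) {
    sl <- dM[, ((j - 1L) * Cin + 1L):(j * Cin), drop = FALSE]
    dim(sl) <- c(B, Lx, Cin)
    dXp[, j:(j + Lx - 1L), ] <- dXp[, j:(j + Lx - 1L), , drop = FALSE] + sl
  }
  list(dX = dXp[, pad + seq_len(Lx), , drop = FALSE], dW = dW, db = db)
}

# Non-overlapping max pool of window p over the length axis, floor
# truncation (trailing positions that do not fill a window are dropped).
maxpool_forward <- function(A, p) {
  d <- dim(A); B <- d[1]; Lx <- d[2]; F <- d[3]
  Lp <- Lx %/% p
  At <- A[, seq_len(p * Lp), , drop = FALSE]
  dim(At) <- c(B, p, Lp, F)
  cur <- array(At[, 1, , ], c(B, Lp, F))
  arg <- array(1L, c(B, Lp, F))
  if (p > 1) {
    for (i in 2:p) {
      xi <- array(At[, i, , ], c(B, Lp, F))
      upd <- xi > cur
      arg[upd] <- i
      cur[upd] <- xi[upd]
    }
  }
  list(out = cur, arg = arg, Lx = Lx, p = p)
}

maxpool_backward <- function(dOut, cache) {
  d <- dim(dOut); B <- d[1]; Lp <- d[2]; F <- d[3]
  p <- cache$p
  dA <- array(0, c(B, p, Lp, F))
  bidx <- rep(seq_len(B), times = Lp * F)
  widx <- rep(rep(seq_len(Lp), each = B), times = F)
  fidx <- rep(seq_len(F), each = B * Lp)
  lin <- bidx + (as.vector(cache$arg) - 1) * B +
    (widx - 1) * B * p + (fidx - 1) * B * p * Lp
  dA[lin] <- as.vector(dOut)
  dim(dA) <- c(B, p * Lp, F)
  if (cache$Lx > p * Lp) {
    full <- array(0, c(B, cache$Lx, F))
    full[, seq_len(p * Lp), ] <- dA
    dA <- full
  }
  dA
}

dropout_mask <- function(n, rate) {
  if (rate <= 0) return(NULL)
  (stats::runif(n) >= rate) / (1 - rate)
}

bn_forward <- function(Z, gamma, beta, state, training, eps = 1e-3,
                       momentum = 0.9) {
  if (training && nrow(Z) > 1) {
    mu <- colMeans(Z)
    va <- colMeans(sweep(Z, 2, mu)^2)
    state$mean <- momentum * state$mean + (1 - momentum) * mu
    state$var <- momentum * state$var + (1 - momentum) * va
  } else {
    mu <- state$mean
    va <- state$var
  }
  xc <- sweep(Z, 2, mu)
  istd <- 1 / sqrt(va + eps)
  xhat <- sweep(xc, 2, istd, `*`)
  out <- sweep(sweep(xhat, 2, gamma, `*`), 2, beta, `+`)
  list(out = out, xhat = xhat, xc = xc, istd = istd, state = state)
}

bn_backward <- function(dOut, cache, gamma) {
  B <- nrow(dOut)
  dgamma <- colSums(dOut * cache$xhat)
  dbeta <- colSums(dOut)
  dxhat <- sweep(dOut, 2, gamma, `*`)
  if (B == 1) {
    # a size-1 batch was normalized with running statistics (constants),
    # so the gradient passes straight through the affine map
    return(list(dZ = sweep(dxhat, 2, cache$istd, `*`),
                dgamma = dgamma, dbeta = dbeta))
  }
  # standard batch-norm backward, fully column-vectorized
  t1 <- sweep(dxhat, 2, colMeans(dxhat))
  t2 <- sweep(cache$xhat, 2, colMeans(dxhat * cache$xhat), `*`)
  dZ <- sweep(t1 - t2, 2, cache$istd, `*`)
  list(dZ = dZ, dgamma = dgamma, dbeta = dbeta)
}

sigmoid <- function(x) 1 / (1 + exp(-x))

bce_loss <- function(p, y, eps = 1e-7) {
  p <- pmin(pmax(p, eps), 1 - eps)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / bc1
    vhat <- state$v[[nm]] / bc2
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

# Initialize all weights for a model spec. kmer_dim only used by HM/DHM.
init_params <- function(spec) {
  L <- spec$L
  f1 <- spec$conv1_filters; k1 <- spec$conv1_kernel
  f2 <- spec$conv2_filters; k2 <- spec$conv2_kernel
  flat <- spec$flatten_dim
  head_dim <- spec$concat_dim
  params <- list(
    W1 = glorot_init(k1 * 4L, f1), b1 = rep(0, f1),
    W2 = glorot_init(k2 * f1, f2), b2 = rep(0, f2)
  )
  if (spec$variant == "DHM") {
    params$Wk <- glorot_init(spec$kmer_dim, spec$dhm_units)
    params$bk <- rep(0, spec$dhm_units)
  }
  if (spec$batch_norm) {
    params$gamma <- rep(1, head_dim)
    params$beta <- rep(0, head_dim)
  }
  params$Wo <- glorot_init(head_dim, 1L)
  params$bo <- 0
  params
}

# Full forward pass. X: (B, L, 4); K: (B, kmer_dim) or NULL.
# training toggles dropout and batch statistics. Returns prediction and all
# caches needed for the backward pass; `taps` collects named intermediate
# embeddings when requested.
net_forward <- function(params, spec, X, K, bn_state, training = FALSE,
                        want_taps = NULL) {
  B <- dim(X)[1]
  rate <- if (training) spec$dropout else 0
  c1 <- conv1d_forward(X, params$W1, params$b1, spec$conv1_kernel)
  relu1 <- c1$Z > 0
  A1 <- c1$Z * relu1
  dim(A1) <- c(B, spec$L, spec$conv1_filters)
  p1 <- maxpool_forward(A1, spec$pool_size)
  m1 <- dropout_mask(length(p1$out), rate)
  D1 <- if (is.null(m1)) p1$out else p1$out * array(m1, dim(p1$out))

  c2 <- conv1d_forward(D1, params$W2, params$b2, spec$conv2_kernel)
  relu2 <- c2$Z > 0
  A2 <- c2$Z * relu2
  dim(A2) <- c(B, spec$pooled1, spec$conv2_filters)
  p2 <- maxpool_forward(A2, spec$pool_size)
  m2 <- dropout_mask(length(p2$out), rate)
  D2 <- if (is.null(m2)) p2$out else p2$out * array(m2, dim(p2$out))

  flat <- D2
  dim(flat) <- c(B, spec$flatten_dim)

  kd_pre <- NULL; kd_relu <- NULL
  z0 <- switch(spec$variant,
    SM = flat,
    HM = cbind(flat, K),
    DHM = {
      kd_pre <- K %*% params$Wk +
        matrix(params$bk, B, spec$dhm_units, byrow = TRUE)
      kd_relu <- kd_pre > 0
      cbind(flat, kd_pre * kd_relu)
    })

  m3 <- dropout_mask(length(z0), if (training) spec$head_dropout else 0)
  zd <- if (is.null(m3)) z0 else z0 * matrix(m3, B)

  bn_cache <- NULL
  if (spec$batch_norm) {
    bn_cache <- bn_forward(zd, params$gamma, params$beta, bn_state, training)
    zb <- bn_cache$out
    bn_state <- bn_cache$state
  } else {
    zb <- zd
  }
  logits <- zb %*% params$Wo + params$bo
  p <- sigmoid(logits)

  taps <- NULL
  if (!is.null(want_taps)) {
    taps <- list()
    if ("cnn" %in% want_taps) taps$cnn <- flat
    if ("kmer_raw" %in% want_taps) taps$kmer_raw <- K
    if ("kmer_deep" %in% want_taps) taps$kmer_deep <- kd_pre * kd_relu
    if ("fused" %in% want_taps) taps$fused <- z0
  }
  list(p = as.numeric(p), bn_state = bn_state, taps = taps,
       cache = list(c1 = c1, relu1 = relu1, p1 = p1, m1 = m1, D1 = D1,
                    c2 = c2, relu2 = relu2, p2 = p2, m2 = m2,
                    flat = flat, K = K, kd_relu = kd_relu, m3 = m3,
                    zd = zd, bn = bn_cache, zb = zb, B = B))
}

net_backward <- function(params, spec, fwd, y) {
  cache <- fwd$cache
  B <- cache$B
  grads <- list()

  dlogits <- matrix((fwd$p - y) / B, ncol = 1)
  grads$Wo <- crossprod(cache$zb, dlogits)
  grads$bo <- sum(dlogits)
  dzb <- dlogits %*% t(params$Wo)

  if (spec$batch_norm) {
    bb <- bn_backward(dzb, cache$bn, params$gamma)
    grads$gamma <- bb$dgamma
    grads$beta <- bb$dbeta
    dzd <- bb$dZ
  } else {
    dzd <- dzb
  }
  dz0 <- if (is.null(cache$m3)) dzd else dzd * matrix(cache$m3, B)

  flat_dim <- spec$flatten_dim
  dflat <- dz0[, seq_len(flat_dim), drop = FALSE]
  if (spec$variant == "DHM") {
    dkd <- dz0[, (flat_dim + 1L):ncol(dz0), drop = FALSE] * cache$kd_relu
    grads$Wk <- crossprod(cache$K, dkd)
    grads$bk <- colSums(dkd)
  }

  dD2 <- dflat
  dim(dD2) <- c(B, spec$pooled2, spec$conv2_filters)
  if (!is.null(cache$m2)) dD2 <- dD2 * array(cache$m2, dim(dD2))
  dA2 <- maxpool_backward(dD2, cache$p2)
  dZ2 <- dA2
  dim(dZ2) <- c(B * spec$pooled1, spec$conv2_filters)
  dZ2 <- dZ2 * cache$relu2
  cb2 <- conv1d_backward(dZ2, cache$c2, params$W2)
  grads$W2 <- cb2$dW
  grads$b2 <- cb2$db

  dD1 <- cb2$dX
  if (!is.null(cache$m1)) dD1 <- dD1 * array(cache$m1, dim(dD1))
  dA1 <- maxpool_backward(dD1, cache$p1)
  dZ1 <- dA1
  dim(dZ1) <- c(B * spec$L, spec$conv1_filters)
  dZ1 <- dZ1 * cache$relu1
  cb1 <- conv1d_backward(dZ1, cache$c1, params$W1)
  grads$W1 <- cb1$dW
  grads$b1 <- cb1$db

  grads
}
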
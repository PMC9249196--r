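# Minimal dense/conv network engine.
#
# Activations for a batch of N images are stored as a (H*W*C) x N matrix with
# linear index h + H*w + H*W*c (0-based; rows vary fastest, then columns, then
# channels), so a base-R image matrix flattens to a column directly.
# Convolutions are im2col gathers followed by a single BLAS matrix
# multiplication; gathers, scatters, depthwise convolution and max pooling run
# through small compiled kernels (src/engine.cpp) because they are
# memory-bound. Layers are environments mutated in place; all randomness goes
# through the global RNG stream so a single set.seed() makes initialization
# and training reproducible.

new_layer <- function(type, ...) {
  e <- new.env(parent = emptyenv())
  e$type <- type
  fields <- list(...)
  for (nm in names(fields)) assign(nm, fields[[nm]], envir = e)
  e
}

he_init <- function(nout, nin, fan_in) {
  matrix(rnorm(nout * nin, sd = sqrt(2 / fan_in)), nout, nin)
}

# --- padding -----------------------------------------------------------------

# Integer map of length Hp*Wp*C: padded row -> source row (1-based), or 0 for
# a zero-filled position. mode "sym" mirrors with the border sample repeated,
# so a constant image stays constant; "zero" fills with zeros.
build_pad_map <- function(H, W, C, p, mode) {
  if (p == 0) return(NULL)
  Hp <- H + 2 * p
  Wp <- W + 2 * p
  hp <- rep(0:(Hp - 1), times = Wp)
  wp <- rep(0:(Wp - 1), each = Hp)
  reflect <- function(i, n) {
    i <- ifelse(i < 0, -i - 1, i)
    ifelse(i >= n, 2 * n - 1 - i, i)
  }
  h <- hp - p
  w <- wp - p
  if (mode == "sym") {
    src <- reflect(h, H) + H * reflect(w, W) + 1L
  } else {
    src <- ifelse(h >= 0 & h < H & w >= 0 & w < W, h + H * w + 1L, 0L)
  }
  plane <- as.integer(src)
  out <- integer(Hp * Wp * C)
  for (c in 0:(C - 1)) {
    shifted <- ifelse(plane == 0L, 0L, plane + c * H * W)
    out[c * Hp * Wp + seq_len(Hp * Wp)] <- shifted
  }
  out
}

pad_batch <- function(X, padmap) {
  if (is.null(padmap)) X else cpp_gather(X, padmap)
}

unpad_grad <- function(dXp, padmap, nrow_in) {
  if (is.null(padmap)) dXp else cpp_scatter_add(dXp, padmap, nrow_in)
}

# Gather indices (k*k*C x H*W) into the padded column for stride-1 same-size
# convolution; patch order: kh fastest, then kw, then channel.
build_gather_index <- function(H, W, C, k, p) {
  Hp <- H + 2 * p
  Wp <- W + 2 * p
  kh <- rep(0:(k - 1), times = k)
  kw <- rep(0:(k - 1), each = k)
  off <- kh + Hp * kw
  offs <- as.vector(outer(off, Hp * Wp * (0:(C - 1)), "+"))
  oh <- rep(0:(H - 1), times = W)
  ow <- rep(0:(W - 1), each = H)
  base <- oh + Hp * ow
  outer(offs, base, "+") + 1L
}

# --- convolution -------------------------------------------------------------

layer_conv <- function(H, W, inC, outC, k, pad_mode = "zero",
                       need_input_grad = TRUE) {
  p <- (k - 1L) %/% 2L
  idx <- build_gather_index(H, W, inC, k, p)
  L <- new_layer(
    "conv",
    H = H, W = W, inC = inC, outC = outC, k = k, p = p,
    padmap = build_pad_map(H, W, inC, p, pad_mode),
    idx = as.integer(idx),
    nrow_pad = (H + 2 * p) * (W + 2 * p) * inC,
    need_input_grad = need_input_grad,
    W_ = he_init(outC, k * k * inC, k * k * inC),
    b_ = numeric(outC),
    params = c("W_", "b_")
  )
  L$out_dim <- c(H, W, outC)
  L
}

conv_forward <- function(L, X) {
  N <- ncol(X)
  kkc <- L$k * L$k * L$inC
  hw <- L$H * L$W
  # reuse the im2col workspace across batches of the same size: it is the
  # largest allocation in the whole engine
  if (is.null(L$M) || ncol(L$M) != hw * N) L$M <- matrix(0, kkc, hw * N)
  cpp_gather_into(pad_batch(X, L$padmap), L$idx, L$M)
  Y <- L$W_ %*% L$M + L$b_
  cpp_to_act(Y, L$outC, hw)
}

conv_backward <- function(L, dY) {
  N <- ncol(dY)
  dY <- cpp_from_act(dY, L$outC, L$H * L$W)
  L$dW_ <- tcrossprod(dY, L$M)
  L$db_ <- rowSums(dY)
  if (!L$need_input_grad) return(NULL)
  dM <- crossprod(L$W_, dY)
  dim(dM) <- c(length(L$idx), N)
  dXp <- cpp_scatter_add(dM, L$idx, L$nrow_pad)
  unpad_grad(dXp, L$padmap, L$H * L$W * L$inC)
}

# --- depthwise convolution ---------------------------------------------------

layer_depthwise <- function(H, W, C, k, pad_mode = "sym") {
  p <- (k - 1L) %/% 2L
  L <- new_layer(
    "depthwise",
    H = H, W = W, C = C, k = k, p = p,
    padmap = build_pad_map(H, W, C, p, pad_mode),
    W_ = he_init(C, k * k, k * k),
    b_ = numeric(C),
    params = c("W_", "b_")
  )
  L$out_dim <- c(H, W, C)
  L
}

depthwise_forward <- function(L, X) {
  Xp <- pad_batch(X, L$padmap)
  L$Xp <- Xp
  cpp_dw_forward(Xp, L$W_, L$b_, L$H, L$W, L$C, L$k)
}

depthwise_backward <- function(L, dY) {
  g <- cpp_dw_backward(L$Xp, dY, L$W_, L$H, L$W, L$C, L$k)
  L$dW_ <- g$dW
  L$db_ <- as.numeric(g$db)
  unpad_grad(g$dXp, L$padmap, L$H * L$W * L$C)
}

# --- max pooling (2x2, stride 2, ceil mode) ----------------------------------

layer_maxpool <- function(H, W, C) {
  OH <- ceiling(H / 2)
  OW <- ceiling(W / 2)
  oh <- rep(0:(OH - 1), times = OW)
  ow <- rep(0:(OW - 1), each = OH)
  cand <- lapply(list(c(0, 0), c(1, 0), c(0, 1), c(1, 1)), function(kk) {
    h <- 2 * oh + kk[1]
    w <- 2 * ow + kk[2]
    base <- ifelse(h < H & w < W, h + H * w + 1L, 0L)
    full <- as.vector(outer(base, H * W * (0:(C - 1)), "+"))
    as.integer(ifelse(full <= 0 | rep(base, C) == 0L, 0L, full))
  })
  new_layer("maxpool", H = H, W = W, C = C, OH = OH, OW = OW,
            idx = do.call(cbind, cand), P = H * W * C,
            params = character(0), out_dim = c(OH, OW, C))
}

maxpool_forward <- function(L, X) {
  res <- cpp_maxpool_forward(X, L$idx)
  L$arg <- res$arg
  res$Y
}

maxpool_backward <- function(L, dY) {
  cpp_maxpool_backward(dY, L$arg, L$idx, L$P)
}

# --- batch normalization -----------------------------------------------------

layer_bn <- function(C, HW, momentum = 0.9, eps = 1e-5) {
  new_layer("bn", C = C, HW = HW, momentum = momentum, eps = eps,
            group = rep(seq_len(C), each = HW),
            gamma = rep(1, C), beta = numeric(C),
            run_mean = numeric(C), run_var = rep(1, C),
            params = c("gamma", "beta"),
            out_dim = c(HW, C))
}

bn_forward <- function(L, X, training) {
  if (training) {
    m <- L$HW * ncol(X)
    mom <- cpp_group_moments(X, L$HW)
    mu <- mom$sum / m
    v <- pmax(mom$sumsq / m - mu^2, 0)
    L$run_mean <- L$momentum * L$run_mean + (1 - L$momentum) * mu
    L$run_var <- L$momentum * L$run_var + (1 - L$momentum) * v
    L$X <- X
    L$mu <- mu
    L$invstd <- 1 / sqrt(v + L$eps)
    invstd <- L$invstd
  } else {
    mu <- L$run_mean
    invstd <- 1 / sqrt(L$run_var + L$eps)
  }
  # y = gamma * (x - mu) * invstd + beta, as one fused affine pass
  cpp_affine_group(X, L$gamma * invstd, L$beta - L$gamma * mu * invstd, L$HW)
}

bn_backward <- function(L, dY) {
  m <- L$HW * ncol(dY)
  xhat <- cpp_affine_group(L$X, L$invstd, -L$mu * L$invstd, L$HW)
  dots <- cpp_group_dots(dY, xhat, L$HW)
  L$dgamma <- dots$dgamma
  L$dbeta <- dots$dbeta
  g <- L$gamma * L$invstd
  cpp_bn_dx(dY, xhat, g, -g * dots$dgamma / m, -g * dots$dbeta / m, L$HW)
}

# --- dense, activations, dropout ---------------------------------------------

layer_dense <- function(nin, nout) {
  new_layer("dense", nin = nin, nout = nout,
            W_ = he_init(nout, nin, nin), b_ = numeric(nout),
            params = c("W_", "b_"), out_dim = nout)
}

dense_forward <- function(L, X) {
  L$X <- X
  L$W_ %*% X + L$b_
}

dense_backward <- function(L, dY) {
  L$dW_ <- tcrossprod(dY, L$X)
  L$db_ <- rowSums(dY)
  crossprod(L$W_, dY)
}

layer_relu <- function(slope = 0) {
  new_layer("relu", slope = slope, params = character(0))
}

relu_forward <- function(L, X) {
  Y <- cpp_leaky(X, L$slope)
  L$Y <- Y  # the sign pattern is recoverable from the output
  Y
}

relu_backward <- function(L, dY) cpp_leaky_grad(L$Y, dY, L$slope)

layer_dropout <- function(rate) {
  new_layer("dropout", rate = rate, params = character(0))
}

dropout_forward <- function(L, X, training) {
  if (!training || L$rate <= 0) return(X)
  L$mask <- matrix(
    (runif(length(X)) >= L$rate) / (1 - L$rate), nrow(X), ncol(X)
  )
  X * L$mask
}

dropout_backward <- function(L, dY) {
  if (L$rate <= 0) return(dY)
  dY * L$mask
}

# --- loss and optimizer ------------------------------------------------------

softmax_cols <- function(Z) {
  Z <- sweep(Z, 2, apply(Z, 2, max))
  E <- exp(Z)
  sweep(E, 2, colSums(E), "/")
}

# categorical cross-entropy over a logits matrix (classes x N)
cross_entropy <- function(Z, y) {
  P <- softmax_cols(Z)
  n <- ncol(Z)
  at <- cbind(y, seq_len(n))
  loss <- -mean(log(pmax(P[at], 1e-12)))
  dZ <- P
  dZ[at] <- dZ[at] - 1
  list(loss = loss, grad = dZ / n, prob = P)
}

adam_step <- function(layers, lr, t, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  for (L in layers) {
    for (p in L$params) {
      g <- get(paste0("d", p), envir = L)
      mname <- paste0("adam_m_", p)
      vname <- paste0("adam_v_", p)
      if (!exists(mname, envir = L)) {
        assign(mname, g * 0, envir = L)
        assign(vname, g * 0, envir = L)
      }
      m <- beta1 * get(mname, envir = L) + (1 - beta1) * g
      v <- beta2 * get(vname, envir = L) + (1 - beta2) * g * g
      assign(mname, m, envir = L)
      assign(vname, v, envir = L)
      mhat <- m / (1 - beta1^t)
      vhat <- v / (1 - beta2^t)
      assign(p, get(p, envir = L) - lr * mhat / (sqrt(vhat) + eps), envir = L)
    }
  }
}
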
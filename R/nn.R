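# Minimal neural-network core.
#
# No deep-learning framework is assumed: convolutions, batch normalization,
# pooling, LSTM and Adam are implemented directly on top of BLAS matrix
# products. Batched activations use the layout (H, W, N, C) so that a
# kernel-offset slice reshapes to an (H*W*N) x C matrix without a permute
# ("shift-and-matmul" convolution). Every backward pass is validated by
# finite-difference gradient checks in the test suite.

# ---- full 2-D convolution (im2col kernels in src/kernels.cpp) -----------

conv2d_forward <- function(x, W, b, stride = 1L, pad = 0L) {
  stopifnot(dim(x)[4] == dim(W)[3])
  y <- .conv2d_fw(x, W, b, as.integer(stride), as.integer(pad))
  list(y = y, cache = list(x = x, W = W, stride = stride, pad = pad))
}

conv2d_backward <- function(cache, dy) {
  .conv2d_bw(cache$x, cache$W, dy, as.integer(cache$stride),
             as.integer(cache$pad))
}

# ---- depthwise 2-D convolution ------------------------------------------

dwconv2d_forward <- function(x, w, b, stride = 1L, pad = 0L) {
  stopifnot(dim(x)[4] == dim(w)[3])
  y <- .dwconv2d_fw(x, w, b, as.integer(stride), as.integer(pad))
  list(y = y, cache = list(x = x, w = w, stride = stride, pad = pad))
}

dwconv2d_backward <- function(cache, dy) {
  .dwconv2d_bw(cache$x, cache$w, dy, as.integer(cache$stride),
               as.integer(cache$pad))
}

# ---- pointwise (1x1) convolution ----------------------------------------

pwconv_forward <- function(x, W, b) {
  d <- dim(x)
  xm <- x; dim(xm) <- c(prod(d[1:3]), d[4])
  y <- xm %*% W + rep(b, each = nrow(xm))
  dim(y) <- c(d[1:3], ncol(W))
  list(y = y, cache = list(xm = xm, W = W, dimx = d))
}

pwconv_backward <- function(cache, dy) {
  d <- cache$dimx
  dym <- dy; dim(dym) <- c(prod(d[1:3]), ncol(cache$W))
  dx <- dym %*% t(cache$W)
  dim(dx) <- d
  list(dx = dx, dW = crossprod(cache$xm, dym), db = colSums(dym))
}

# ---- batch normalization (per channel over all positions and samples) ---

bn_forward <- function(x, gamma, beta, stats, training, momentum = 0.1,
                       eps = 1e-5) {
  r <- .bn_fw(x, gamma, beta, stats$mean, stats$var, eps, training)
  if (training) {
    stats$mean <- (1 - momentum) * stats$mean + momentum * as.numeric(r$mu)
    stats$var  <- (1 - momentum) * stats$var + momentum * as.numeric(r$va)
  }
  list(y = r$y, stats = stats,
       cache = list(xhat = r$xhat, istd = 1 / sqrt(as.numeric(r$va) + eps),
                    gamma = gamma, training = training))
}

bn_backward <- function(cache, dy) {
  r <- .bn_bw(dy, cache$xhat, cache$gamma, cache$istd, cache$training)
  list(dx = r$dx, dgamma = as.numeric(r$dgamma), dbeta = as.numeric(r$dbeta))
}

# ---- activations, pooling, dense, dropout -------------------------------

relu_forward <- function(x) list(y = pmax(x, 0), cache = x > 0)
relu_backward <- function(cache, dy) dy * cache

sigmoid <- function(x) 1 / (1 + exp(-x))

# 2x2 average pooling, stride 2 (even spatial dims required)
avgpool2_forward <- function(x) {
  list(y = .avgpool2_fw(x), cache = dim(x))
}

avgpool2_backward <- function(cache, dy) {
  .avgpool2_bw(dy, cache[1], cache[2])
}

fc_forward <- function(x, W, b) {
  list(y = x %*% W + rep(b, each = nrow(x)), cache = list(x = x, W = W))
}

fc_backward <- function(cache, dy) {
  list(dx = dy %*% t(cache$W), dW = crossprod(cache$x, dy), db = colSums(dy))
}

dropout_forward <- function(x, p, training) {
  if (!training || p <= 0) return(list(y = x, cache = NULL))
  mask <- (array(stats::runif(length(x)), dim(x) %||% length(x)) > p) / (1 - p)
  list(y = x * mask, cache = mask)
}

dropout_backward <- function(cache, dy) if (is.null(cache)) dy else dy * cache

# ---- 1-D convolution over time (x is T x C) -----------------------------

conv1d_forward <- function(x, W, b) {
  k <- dim(W)[1]; cin <- dim(W)[2]; cout <- dim(W)[3]
  p <- (k - 1L) %/% 2L
  Tn <- nrow(x)
  xp <- rbind(matrix(0, p, cin), x, matrix(0, p, cin))
  acc <- matrix(0, Tn, cout)
  for (o in seq_len(k))
    acc <- acc + xp[o:(o + Tn - 1), , drop = FALSE] %*% matrix(W[o, , ], cin, cout)
  acc <- acc + rep(b, each = Tn)
  list(y = acc, cache = list(xp = xp, W = W, Tn = Tn, p = p))
}

conv1d_backward <- function(cache, dy) {
  W <- cache$W; Tn <- cache$Tn; p <- cache$p
  k <- dim(W)[1]; cin <- dim(W)[2]; cout <- dim(W)[3]
  dW <- array(0, dim(W))
  dxp <- matrix(0, nrow(cache$xp), cin)
  for (o in seq_len(k)) {
    idx <- o:(o + Tn - 1)
    dW[o, , ] <- crossprod(cache$xp[idx, , drop = FALSE], dy)
    dxp[idx, ] <- dxp[idx, , drop = FALSE] + dy %*% t(matrix(W[o, , ], cin, cout))
  }
  list(dx = dxp[(p + 1):(p + Tn), , drop = FALSE], dW = dW, db = colSums(dy))
}

# Temporal resampling as fixed linear operators (used by the 1-D encoder-
# decoder): y = A %*% x, backward dx = t(A) %*% dy.

adaptive_pool_matrix <- function(t_in, t_out) {
  A <- matrix(0, t_out, t_in)
  for (i in seq_len(t_out)) {
    a <- floor((i - 1) * t_in / t_out) + 1
    b <- ceiling(i * t_in / t_out)
    A[i, a:b] <- 1 / (b - a + 1)
  }
  A
}

interp_matrix <- function(t_in, t_out) {
  A <- matrix(0, t_out, t_in)
  s <- clamp((seq_len(t_out) - 0.5) * t_in / t_out - 0.5, 0, t_in - 1)
  i0 <- floor(s); f <- s - i0
  for (i in seq_len(t_out)) {
    a <- i0[i] + 1
    b <- min(a + 1, t_in)
    A[i, a] <- A[i, a] + (1 - f[i])
    A[i, b] <- A[i, b] + f[i]
  }
  A
}

# ---- LSTM ----------------------------------------------------------------
# x: T x D. Gates ordered i, f, g, o in the 4H columns.

lstm_init <- function(d_in, h, scale = NULL) {
  scale <- scale %||% (1 / sqrt(h))
  list(W = matrix(stats::rnorm(d_in * 4 * h, 0, scale), d_in, 4 * h),
       U = matrix(stats::rnorm(h * 4 * h, 0, scale), h, 4 * h),
       b = rep(0, 4 * h))
}

lstm_forward <- function(x, p) {
  Tn <- nrow(x)
  H <- nrow(p$U)
  zx <- x %*% p$W + rep(p$b, each = Tn)
  hs <- matrix(0, Tn, H); cs <- matrix(0, Tn, H)
  gates <- matrix(0, Tn, 4 * H)
  hp <- rep(0, H); cp <- rep(0, H)
  for (t in seq_len(Tn)) {
    z <- zx[t, ] + drop(hp %*% p$U)
    i <- sigmoid(z[1:H]); f <- sigmoid(z[(H + 1):(2 * H)])
    g <- tanh(z[(2 * H + 1):(3 * H)]); o <- sigmoid(z[(3 * H + 1):(4 * H)])
    cp <- f * cp + i * g
    hp <- o * tanh(cp)
    hs[t, ] <- hp; cs[t, ] <- cp
    gates[t, ] <- c(i, f, g, o)
  }
  list(h = hs, cache = list(x = x, p = p, hs = hs, cs = cs, gates = gates, H = H))
}

lstm_backward <- function(cache, dh_out) {
  x <- cache$x; p <- cache$p; H <- cache$H
  Tn <- nrow(x)
  dU <- matrix(0, H, 4 * H)
  dh_next <- rep(0, H); dc_next <- rep(0, H)
  dz_all <- matrix(0, Tn, 4 * H)
  for (t in rev(seq_len(Tn))) {
    i <- cache$gates[t, 1:H]; f <- cache$gates[t, (H + 1):(2 * H)]
    g <- cache$gates[t, (2 * H + 1):(3 * H)]; o <- cache$gates[t, (3 * H + 1):(4 * H)]
    ct <- cache$cs[t, ]
    cprev <- if (t > 1) cache$cs[t - 1, ] else rep(0, H)
    tc <- tanh(ct)
    dh <- dh_out[t, ] + dh_next
    dc <- dc_next + dh * o * (1 - tc * tc)
    dzi <- dc * g * i * (1 - i)
    dzf <- dc * cprev * f * (1 - f)
    dzg <- dc * i * (1 - g * g)
    dzo <- dh * tc * o * (1 - o)
    dz <- c(dzi, dzf, dzg, dzo)
    dz_all[t, ] <- dz
    dh_next <- drop(p$U %*% dz)  # dz %*% t(U) for row vector
    dc_next <- dc * f
    hprev <- if (t > 1) cache$hs[t - 1, ] else rep(0, H)
    dU <- dU + outer(hprev, dz)
  }
  dW <- crossprod(x, dz_all)
  db <- colSums(dz_all)
  dx <- dz_all %*% t(p$W)
  list(dx = dx, dW = dW, dU = dU, db = db)
}

bilstm_forward <- function(x, pf, pb) {
  fw <- lstm_forward(x, pf)
  bw <- lstm_forward(x[rev(seq_len(nrow(x))), , drop = FALSE], pb)
  list(h = cbind(fw$h, bw$h[rev(seq_len(nrow(x))), , drop = FALSE]),
       cache = list(fw = fw$cache, bw = bw$cache, H = ncol(fw$h)))
}

bilstm_backward <- function(cache, dh) {
  H <- cache$H
  Tn <- nrow(dh)
  gf <- lstm_backward(cache$fw, dh[, 1:H, drop = FALSE])
  gb <- lstm_backward(cache$bw, dh[rev(seq_len(Tn)), (H + 1):(2 * H), drop = FALSE])
  list(dx = gf$dx + gb$dx[rev(seq_len(Tn)), , drop = FALSE],
       fw = gf[c("dW", "dU", "db")], bw = gb[c("dW", "dU", "db")])
}

# ---- Adam ----------------------------------------------------------------

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(params, grads, st, lr = 1e-3, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  st$t <- st$t + 1L
  bc1 <- 1 - beta1^st$t
  bc2 <- 1 - beta2^st$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    st$m[[nm]] <- beta1 * st$m[[nm]] + (1 - beta1) * g
    st$v[[nm]] <- beta2 * st$v[[nm]] + (1 - beta2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (st$m[[nm]] / bc1) / (sqrt(st$v[[nm]] / bc2) + eps)
  }
  list(params = params, st = st)
}

# He-normal initializer (draws from the current RNG stream)
init_norm <- function(dims, fan_in) {
  array(stats::rnorm(prod(dims), 0, sqrt(2 / fan_in)), dims)
}
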
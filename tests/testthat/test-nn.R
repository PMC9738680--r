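# Finite-difference gradient checks for the neural-network core. Every
# backward pass is compared against a numeric derivative of its own forward
# pass, so these tests are independent of how the kernels are implemented.

ns <- asNamespace("hmdrppg")

test_that("conv2d forward/backward match finite differences (stride 1 and 2)", {
  set.seed(11)
  for (stride in c(1L, 2L)) {
    x <- array(rnorm(5 * 6 * 2 * 3), c(5, 6, 2, 3))
    W <- array(rnorm(3 * 3 * 3 * 4) * 0.3, c(3, 3, 3, 4))
    b <- rnorm(4)
    fw <- ns$conv2d_forward(x, W, b, stride, 1L)
    dy <- array(rnorm(length(fw$y)), dim(fw$y))
    bk <- ns$conv2d_backward(fw$cache, dy)
    expect_lt(max(abs(num_grad(function(p)
      sum(ns$conv2d_forward(x, p, b, stride, 1L)$y * dy), W) - bk$dW)), 1e-6)
    expect_lt(max(abs(num_grad(function(p)
      sum(ns$conv2d_forward(p, W, b, stride, 1L)$y * dy), x) - bk$dx)), 1e-6)
    expect_lt(max(abs(num_grad(function(p)
      sum(ns$conv2d_forward(x, W, p, stride, 1L)$y * dy), b) - bk$db)), 1e-6)
  }
})

test_that("depthwise and pointwise conv gradients are exact", {
  set.seed(12)
  x <- array(rnorm(5 * 5 * 2 * 3), c(5, 5, 2, 3))
  w <- array(rnorm(3 * 3 * 3) * 0.3, c(3, 3, 3))
  b <- rnorm(3)
  fw <- ns$dwconv2d_forward(x, w, b, 2L, 1L)
  dy <- array(rnorm(length(fw$y)), dim(fw$y))
  bk <- ns$dwconv2d_backward(fw$cache, dy)
  expect_lt(max(abs(num_grad(function(p)
    sum(ns$dwconv2d_forward(x, p, b, 2L, 1L)$y * dy), w) - bk$dw)), 1e-6)
  expect_lt(max(abs(num_grad(function(p)
    sum(ns$dwconv2d_forward(p, w, b, 2L, 1L)$y * dy), x) - bk$dx)), 1e-6)

  W <- matrix(rnorm(3 * 5) * 0.3, 3, 5)
  bp <- rnorm(5)
  fp <- ns$pwconv_forward(x, W, bp)
  dyp <- array(rnorm(length(fp$y)), dim(fp$y))
  bkp <- ns$pwconv_backward(fp$cache, dyp)
  expect_lt(max(abs(num_grad(function(p)
    sum(ns$pwconv_forward(x, p, bp)$y * dyp), W) - bkp$dW)), 1e-6)
  expect_lt(max(abs(num_grad(function(p)
    sum(ns$pwconv_forward(p, W, bp)$y * dyp), x) - bkp$dx)), 1e-6)
})

test_that("batchnorm gradients are exact in training and inference modes", {
  set.seed(13)
  x <- array(rnorm(4 * 4 * 2 * 3), c(4, 4, 2, 3))
  g <- rnorm(3) + 1; be <- rnorm(3)
  st <- list(mean = rnorm(3), var = abs(rnorm(3)) + 0.5)
  for (training in c(TRUE, FALSE)) {
    fb <- ns$bn_forward(x, g, be, st, training)
    dy <- array(rnorm(length(x)), dim(x))
    bb <- ns$bn_backward(fb$cache, dy)
    expect_lt(max(abs(num_grad(function(p)
      sum(ns$bn_forward(p, g, be, st, training)$y * dy), x) - bb$dx)), 1e-6)
    expect_lt(max(abs(num_grad(function(p)
      sum(ns$bn_forward(x, p, be, st, training)$y * dy), g) - bb$dgamma)), 1e-6)
  }
})

test_that("average pooling and fc gradients are exact", {
  set.seed(14)
  x <- array(rnorm(4 * 4 * 2 * 3), c(4, 4, 2, 3))
  fp <- ns$avgpool2_forward(x)
  dy <- array(rnorm(length(fp$y)), dim(fp$y))
  expect_lt(max(abs(num_grad(function(p)
    sum(ns$avgpool2_forward(p)$y * dy), x) -
    ns$avgpool2_backward(fp$cache, dy))), 1e-6)

  xm <- matrix(rnorm(6 * 4), 6, 4)
  W <- matrix(rnorm(4 * 3), 4, 3); b <- rnorm(3)
  ff <- ns$fc_forward(xm, W, b)
  dyf <- matrix(rnorm(18), 6, 3)
  bf <- ns$fc_backward(ff$cache, dyf)
  expect_lt(max(abs(num_grad(function(p)
    sum(ns$fc_forward(xm, p, b)$y * dyf), W) - bf$dW)), 1e-6)
})

test_that("conv1d and temporal resampling operators have exact adjoints", {
  set.seed(15)
  x <- matrix(rnorm(10 * 4), 10, 4)
  W <- array(rnorm(3 * 4 * 5) * 0.3, c(3, 4, 5)); b <- rnorm(5)
  fc <- ns$conv1d_forward(x, W, b)
  dy <- matrix(rnorm(length(fc$y)), nrow(fc$y))
  bc <- ns$conv1d_backward(fc$cache, dy)
  expect_lt(max(abs(num_grad(function(p)
    sum(ns$conv1d_forward(x, p, b)$y * dy), W) - bc$dW)), 1e-6)
  expect_lt(max(abs(num_grad(function(p)
    sum(ns$conv1d_forward(p, W, b)$y * dy), x) - bc$dx)), 1e-6)

  # pooling / interpolation matrices: rows sum to 1 (constant preserving)
  for (A in list(ns$adaptive_pool_matrix(10, 4), ns$interp_matrix(4, 10)))
    expect_equal(rowSums(A), rep(1, nrow(A)))
})

test_that("LSTM and bidirectional LSTM gradients are exact", {
  set.seed(16)
  x <- matrix(rnorm(7 * 4), 7, 4)
  p <- ns$lstm_init(4, 3)
  fl <- ns$lstm_forward(x, p)
  dy <- matrix(rnorm(21), 7, 3)
  bl <- ns$lstm_backward(fl$cache, dy)
  for (nm in c("W", "U", "b")) {
    gn <- num_grad(function(v) {
      p2 <- p; p2[[nm]] <- v; sum(ns$lstm_forward(x, p2)$h * dy)
    }, p[[nm]])
    expect_lt(max(abs(gn - bl[[paste0("d", nm)]])), 1e-6)
  }
  expect_lt(max(abs(num_grad(function(v)
    sum(ns$lstm_forward(v, p)$h * dy), x) - bl$dx)), 1e-6)

  pb <- ns$lstm_init(4, 3)
  fb <- ns$bilstm_forward(x, p, pb)
  dyb <- matrix(rnorm(7 * 6), 7, 6)
  bb <- ns$bilstm_backward(fb$cache, dyb)
  expect_lt(max(abs(num_grad(function(v)
    sum(ns$bilstm_forward(v, p, pb)$h * dyb), x) - bb$dx)), 1e-6)
})

test_that("Adam minimizes a quadratic and is deterministic", {
  p <- list(w = c(5, -3))
  st <- ns$adam_init(p)
  for (i in 1:500) {
    g <- list(w = 2 * (p$w - c(1, 2)))
    up <- ns$adam_step(p, g, st, lr = 0.05)
    p <- up$params; st <- up$st
  }
  expect_equal(p$w, c(1, 2), tolerance = 1e-3)
})
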
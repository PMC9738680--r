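ns <- asNamespace("hmdrppg")

test_that("BPM normalization maps the printed endpoints and round-trips", {
  expect_equal(normalize_bpm(45), 0)
  expect_equal(normalize_bpm(240), 1)
  expect_equal(normalize_bpm(142.5), 0.5)
  v <- seq(45, 240, by = 7.3)
  expect_equal(denormalize_bpm(normalize_bpm(v)), v, tolerance = 1e-12)
  expect_warning(out <- normalize_bpm(30), "clamped")
  expect_equal(out, 0)
})

test_that("spatial_lowest_band reduces any square frame to 5x5 per channel", {
  expect_equal(dim(spatial_lowest_band(array(0.3, c(100, 100, 3)))), c(5, 5, 3))
  expect_equal(dim(spatial_lowest_band(matrix(0, 64, 64))), c(5, 5, 1))
  # constant input -> constant output (lowpass of a constant)
  out <- spatial_lowest_band(array(0.42, c(40, 40, 3)))
  expect_equal(as.numeric(out), rep(0.42, 75))
  # horizontal ramp: rows equal, columns monotone increasing
  ramp <- matrix(rep(seq(0, 1, length.out = 64), each = 64), 64, 64)
  lb <- spatial_lowest_band(ramp)[, , 1]
  for (r in 2:5) expect_equal(lb[r, ], lb[1, ], tolerance = 1e-9)
  expect_true(all(diff(lb[1, ]) > 0))
})

test_that("feature images are zero for constant video and band-limited", {
  const <- lapply(1:30, function(i) array(0.5, c(20, 20, 3)))
  fi <- build_feature_image(const, 30)
  expect_equal(dim(fi), c(25, 25, 3))
  expect_lt(max(abs(fi)), 1e-12)

  # every pixel oscillating at 2 Hz: dominant rFFT bin of each row is 2 Hz
  frames <- lapply(1:30, function(k)
    array(0.5 + 0.1 * sin(2 * pi * 2 * (k - 1) / 30), c(20, 20, 3)))
  fi2 <- build_feature_image(frames, 30)
  for (p in c(1, 13, 25)) {
    sp <- Mod(stats::fft(fi2[p, , 2]))[2:12]
    expect_equal(which.max(sp), 2)  # bin k = 2 <-> 2 Hz at 1 Hz resolution
  }
  expect_error(build_feature_image(const[1:10], 30), "one second")
})

test_that("the regression network reproduces every Table-layer geometry", {
  m <- build_evm_network(evm_config(seed = 1))
  # first convolution: 5 x 5 x 3 x 96 weights
  expect_equal(dim(m$params$L1_W), c(5, 5, 3, 96))
  expect_equal(length(m$params$L1_W), 5 * 5 * 3 * 96)
  x <- array(rnorm(25 * 25 * 2 * 3) * 0.1, c(25, 25, 2, 3))
  fw <- ns$evm_forward(m, x, training = FALSE)
  expect_equal(dim(fw$out), c(2, 1))
  # intermediate spatial sizes, read off the layer input caches
  sizes <- vapply(seq_len(11), function(i) {
    ca <- fw$caches[[paste0("L", i, "_conv")]]
    d <- if (!is.null(ca[["x"]])) dim(ca[["x"]]) else ca$dimx
    d[1]
  }, 0L)
  expect_equal(sizes, c(25, 23, 21, 21, 11, 11, 6, 6, 3, 3, 2))
  chans <- vapply(seq_len(11), function(i) {
    ca <- fw$caches[[paste0("L", i, "_conv")]]
    d <- if (!is.null(ca[["x"]])) dim(ca[["x"]]) else ca$dimx
    d[4]
  }, 0L)
  expect_equal(chans, c(3, 96, 96, 96, 96, 96, 96, 128, 128, 128, 128))
  expect_equal(dim(m$params$fc1_W), c(128, 192))
  expect_equal(dim(m$params$fc2_W), c(192, 1))
  expect_equal(m$config$dropout, 0.6)
})

test_that("network initialization is deterministic under a seed", {
  a <- build_evm_network(evm_config(seed = 5))
  b <- build_evm_network(evm_config(seed = 5))
  expect_identical(a$params, b$params)
  c <- build_evm_network(evm_config(seed = 6))
  expect_false(identical(a$params, c$params))
})

test_that("training reduces loss and degenerate labels converge to constant", {
  set.seed(41)
  mk <- function(f) {
    frames <- lapply(1:30, function(k)
      array(0.5 + 0.05 * sin(2 * pi * f * (k - 1) / 30) +
            rnorm(1, 0, 0.002), c(12, 12, 3)))
    build_feature_image(frames, 30)
  }
  feats <- lapply(rep(c(1, 2), each = 10), mk)
  labs <- rep(c(60, 120), each = 10)
  fit <- train_evm(feats, labs, evm_config(epochs = 8, batch = 10, lr = 2e-3,
                                           seed = 0))
  expect_lt(tail(fit$loss, 1), fit$loss[1])
  fit2 <- train_evm(feats, labs, evm_config(epochs = 8, batch = 10, lr = 2e-3,
                                            seed = 0))
  expect_identical(fit$loss, fit2$loss)

  fitc <- train_evm(feats, rep(90, 20),
                    evm_config(epochs = 35, batch = 5, lr = 5e-3, seed = 1))
  pred <- ns$evm_forward(fitc$model, ns$stack_feature_images(feats),
                         training = FALSE)$out
  expect_lt(max(abs(denormalize_bpm(pred) - 90)), 8)
})

test_that("prediction windows follow the stride arithmetic", {
  set.seed(42)
  frames <- lapply(1:90, function(k)
    array(0.5 + 0.05 * sin(2 * pi * 1.5 * (k - 1) / 30), c(12, 12, 3)))
  m <- build_evm_network(evm_config(seed = 2))
  out <- predict_evm(m, frames, fps = 30)
  expect_equal(nrow(out), 3)           # 3 s clip, 1 s stride -> 3 windows
  expect_true(all(out$bpm >= 45 & out$bpm <= 240))
  expect_error(predict_evm(m, frames[1:10], fps = 30), "one")

  mp <- build_evm_network(evm_config(target = "ppg", seed = 2))
  tr <- predict_evm(mp, frames, fps = 30)
  expect_s3_class(tr, "ppg_trace")
  expect_length(tr$samples, 25 * 3)    # 25 samples per window
})

test_that("constant input yields a constant prediction series", {
  frames <- lapply(1:60, function(k) array(0.5, c(12, 12, 3)))
  m <- build_evm_network(evm_config(seed = 3))
  out <- predict_evm(m, frames, fps = 30)
  expect_equal(out$bpm[1], out$bpm[2])
})
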
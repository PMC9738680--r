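# Feature-image construction and the depthwise-separable regression network.
#
# One second of ROI frames becomes a 25 x 25 x 3 feature image: each frame is
# reduced to the lowest band of its Gaussian pyramid (5 x 5 per channel,
# flattened row-major to a 25-vector forming one column), the time axis is
# resampled to 25 columns, and every pixel row is band-passed with a hard FFT
# mask keeping 0.75--4 Hz. The regression network maps a feature image to the
# normalized heart rate (45 BPM -> 0, 240 BPM -> 1) or, in the PPG-target
# variant, to 25 waveform samples; the loss is the Euclidean distance between
# predictions and targets and the optimizer is Adam.

#' Normalize a heart rate to `[0, 1]`
#'
#' 45 BPM maps to 0 and 240 BPM to 1. Values outside the range are clamped
#' with a warning.
#'
#' @param bpm heart rate(s) in BPM
#' @return normalized value(s)
#' @export
normalize_bpm <- function(bpm) {
  if (any(bpm < 45 | bpm > 240)) {
    warning("BPM outside [45, 240] clamped before normalization")
    bpm <- clamp(bpm, 45, 240)
  }
  (bpm - 45) / (240 - 45)
}

#' Invert [normalize_bpm()]
#' @param v normalized value(s) in `[0, 1]`
#' @return heart rate(s) in BPM
#' @export
denormalize_bpm <- function(v) 45 + v * (240 - 45)

#' Lowest Gaussian-pyramid band of an ROI frame
#'
#' Repeatedly blurs and halves until the smaller dimension is at most 8
#' pixels, then resizes to exactly 5 x 5 per channel.
#'
#' @param roi_frame square image (`H x W x C` or `H x W`)
#' @return `5 x 5 x C` array (C = 1 for grayscale input)
#' @export
spatial_lowest_band <- function(roi_frame) {
  x <- roi_frame
  if (length(dim(x)) == 2) dim(x) <- c(dim(x), 1L)
  while (min(dim(x)[1:2]) > 8) x <- pyr_down(x)
  resize_image(x, 5, 5)
}

#' Build one feature image from a one-second window of ROI frames
#'
#' @param roi_frames list of ROI frames spanning one second (>= 2 frames)
#' @param fps frame rate of the window in Hz
#' @param f_lo,f_hi temporal pass band in Hz
#' @return object of class `feature_image`: a `25 x 25 x C` array with
#'   attributes `fps` and `band`
#' @export
build_feature_image <- function(roi_frames, fps, f_lo = 0.75, f_hi = 4) {
  n <- length(roi_frames)
  if (n < 2 || n < round(fps) - 1L)
    stop_cfg("a feature image needs one second of frames (got %d at %g FPS)",
             n, fps)
  nc <- if (length(dim(roi_frames[[1]])) == 3) dim(roi_frames[[1]])[3] else 1L
  # columns: flattened (row-major) lowest bands, one per frame
  cols <- vapply(roi_frames, function(fr) {
    lb <- spatial_lowest_band(fr)
    apply(lb, 3, function(m) as.vector(t(m)))  # row-major flatten per channel
  }, matrix(0, 25 * nc, 1)[, 1])
  dim(cols) <- c(25, nc, n)
  A <- interp_matrix(n, 25)                    # resample time axis to 25
  fs_eff <- 25                                  # 25 columns span one second
  out <- array(0, c(25, 25, nc))
  for (c in seq_len(nc)) {
    rows <- t(A %*% t(cols[, c, ]))            # 25 pixels x 25 time samples
    for (p in 1:25)
      out[p, , c] <- fft_bandpass(rows[p, ], fs_eff, f_lo, f_hi)
  }
  structure(out, fps = fps, band = c(f_lo, f_hi), class = "feature_image")
}

#' Configuration for the regression network
#'
#' @param target `"bpm"` (single normalized output) or `"ppg"` (25 waveform
#'   samples per window)
#' @param dropout dropout ratio before the final layer
#' @param epochs,batch,lr training schedule
#' @param seed integer seed for initialization, shuffling and dropout
#' @return object of class `evm_config`
#' @export
evm_config <- function(target = c("bpm", "ppg"), dropout = 0.6, epochs = 30,
                       batch = 32, lr = 1e-3, seed = 0L) {
  target <- match.arg(target)
  if (dropout < 0 || dropout > 1) stop_cfg("dropout must lie in [0, 1]")
  structure(list(target = target, dropout = dropout, epochs = epochs,
                 batch = batch, lr = lr, seed = as.integer(seed)),
            class = "evm_config")
}

# layer table: full conv, then alternating depthwise / pointwise stages
evm_layer_table <- function() list(
  list(type = "conv", k = 5, cin = 3, cout = 96, stride = 1, pad = 1),
  list(type = "dw", k = 3, c = 96, stride = 1, pad = 0),
  list(type = "pw", cin = 96, cout = 96),
  list(type = "dw", k = 3, c = 96, stride = 2, pad = 1),
  list(type = "pw", cin = 96, cout = 96),
  list(type = "dw", k = 3, c = 96, stride = 2, pad = 1),
  list(type = "pw", cin = 96, cout = 128),
  list(type = "dw", k = 3, c = 128, stride = 2, pad = 1),
  list(type = "pw", cin = 128, cout = 128),
  list(type = "dw", k = 3, c = 128, stride = 2, pad = 1),
  list(type = "pw", cin = 128, cout = 128))

#' Build the regression network
#'
#' Stack: one full 5x5 convolution to 96 channels, then alternating
#' depthwise 3x3 and pointwise 1x1 convolutions (96, 96, 96, 128, 128), each
#' convolution followed by batch normalization and ReLU; 2x2 average pooling
#' to a 128-vector; fully connected 128 -> 192, dropout, fully connected
#' 192 -> 1 (or -> 25 for the PPG-target variant).
#'
#' @param config an [evm_config()]
#' @return object of class `evm_model` (an environment holding parameters,
#'   batch-norm statistics and the config)
#' @export
build_evm_network <- function(config = evm_config()) {
  stopifnot(inherits(config, "evm_config"))
  set.seed(derive_seed(config$seed, "evm-init"))
  out_dim <- if (config$target == "ppg") 25L else 1L
  params <- list()
  bn <- list()
  tab <- evm_layer_table()
  for (i in seq_along(tab)) {
    l <- tab[[i]]
    nm <- paste0("L", i)
    if (l$type == "conv") {
      params[[paste0(nm, "_W")]] <- init_norm(c(l$k, l$k, l$cin, l$cout),
                                              l$k * l$k * l$cin)
      params[[paste0(nm, "_b")]] <- rep(0, l$cout)
      cc <- l$cout
    } else if (l$type == "dw") {
      params[[paste0(nm, "_w")]] <- init_norm(c(l$k, l$k, l$c), l$k * l$k)
      params[[paste0(nm, "_b")]] <- rep(0, l$c)
      cc <- l$c
    } else {
      params[[paste0(nm, "_W")]] <- init_norm(c(l$cin, l$cout), l$cin)
      dim(params[[paste0(nm, "_W")]]) <- c(l$cin, l$cout)
      params[[paste0(nm, "_b")]] <- rep(0, l$cout)
      cc <- l$cout
    }
    params[[paste0(nm, "_g")]] <- rep(1, cc)
    params[[paste0(nm, "_beta")]] <- rep(0, cc)
    bn[[nm]] <- list(mean = rep(0, cc), var = rep(1, cc))
  }
  params$fc1_W <- init_norm(c(128, 192), 128); dim(params$fc1_W) <- c(128, 192)
  params$fc1_b <- rep(0, 192)
  params$fc2_W <- init_norm(c(192, out_dim), 192)
  dim(params$fc2_W) <- c(192, out_dim)
  params$fc2_b <- rep(0, out_dim)
  m <- new.env(parent = emptyenv())
  m$params <- params
  m$bn <- bn
  m$config <- config
  m$out_dim <- out_dim
  class(m) <- "evm_model"
  m
}

# forward pass; x is (25, 25, N, C). Returns N x out_dim predictions.
evm_forward <- function(model, x, training = FALSE) {
  p <- model$params
  caches <- list()
  tab <- evm_layer_table()
  h <- x
  for (i in seq_along(tab)) {
    l <- tab[[i]]
    nm <- paste0("L", i)
    if (l$type == "conv") {
      r <- conv2d_forward(h, p[[paste0(nm, "_W")]], p[[paste0(nm, "_b")]],
                          l$stride, l$pad)
    } else if (l$type == "dw") {
      r <- dwconv2d_forward(h, p[[paste0(nm, "_w")]], p[[paste0(nm, "_b")]],
                            l$stride, l$pad)
    } else {
      r <- pwconv_forward(h, p[[paste0(nm, "_W")]], p[[paste0(nm, "_b")]])
    }
    caches[[paste0(nm, "_conv")]] <- r$cache
    rb <- bn_forward(r$y, p[[paste0(nm, "_g")]], p[[paste0(nm, "_beta")]],
                     model$bn[[nm]], training)
    if (training) model$bn[[nm]] <- rb$stats
    caches[[paste0(nm, "_bn")]] <- rb$cache
    rr <- relu_forward(rb$y)
    caches[[paste0(nm, "_relu")]] <- rr$cache
    h <- rr$y
  }
  rp <- avgpool2_forward(h)                 # 2x2x N x128 -> 1x1
  caches$pool <- rp$cache
  n <- dim(rp$y)[3]
  flat <- rp$y; dim(flat) <- c(n, 128)      # (1*1*N) x C
  r1 <- fc_forward(flat, p$fc1_W, p$fc1_b)
  caches$fc1 <- r1$cache
  rr1 <- relu_forward(r1$y)
  caches$fc1_relu <- rr1$cache
  rd <- dropout_forward(rr1$y, model$config$dropout, training)
  caches$drop <- rd$cache
  r2 <- fc_forward(rd$y, p$fc2_W, p$fc2_b)
  caches$fc2 <- r2$cache
  list(out = r2$y, caches = caches)
}

evm_backward <- function(model, caches, dout) {
  p <- model$params
  g <- list()
  b2 <- fc_backward(caches$fc2, dout)
  g$fc2_W <- b2$dW; g$fc2_b <- b2$db
  dd <- dropout_backward(caches$drop, b2$dx)
  dr1 <- relu_backward(caches$fc1_relu, dd)
  b1 <- fc_backward(caches$fc1, dr1)
  g$fc1_W <- b1$dW; g$fc1_b <- b1$db
  dx <- b1$dx
  dim(dx) <- c(1, 1, nrow(dx), 128)
  dh <- avgpool2_backward(caches$pool, dx)
  tab <- evm_layer_table()
  for (i in rev(seq_along(tab))) {
    l <- tab[[i]]
    nm <- paste0("L", i)
    dh <- relu_backward(caches[[paste0(nm, "_relu")]], dh)
    bb <- bn_backward(caches[[paste0(nm, "_bn")]], dh)
    g[[paste0(nm, "_g")]] <- bb$dgamma
    g[[paste0(nm, "_beta")]] <- bb$dbeta
    dh <- bb$dx
    if (l$type == "conv") {
      bc <- conv2d_backward(caches[[paste0(nm, "_conv")]], dh)
      g[[paste0(nm, "_W")]] <- bc$dW; g[[paste0(nm, "_b")]] <- bc$db
    } else if (l$type == "dw") {
      bc <- dwconv2d_backward(caches[[paste0(nm, "_conv")]], dh)
      g[[paste0(nm, "_w")]] <- bc$dw; g[[paste0(nm, "_b")]] <- bc$db
    } else {
      bc <- pwconv_backward(caches[[paste0(nm, "_conv")]], dh)
      g[[paste0(nm, "_W")]] <- bc$dW; g[[paste0(nm, "_b")]] <- bc$db
    }
    dh <- bc$dx
  }
  g
}

# stack a list of feature images into the (25, 25, N, C) batch layout
stack_feature_images <- function(fims) {
  nc <- dim(fims[[1]])[3]
  x <- array(0, c(25, 25, length(fims), nc))
  for (i in seq_along(fims)) x[, , i, ] <- unclass(fims[[i]])
  x
}

# Euclidean (L2) regression loss and its gradient
euclid_loss <- function(pred, target) {
  d <- pred - target
  list(loss = 0.5 * mean(d * d), grad = d / length(d))
}

#' Export a feature image as PNG for visual inspection
#'
#' Channels are min-max normalized jointly so the band-passed variations are
#' visible.
#'
#' @param fi a [build_feature_image()] result
#' @param path output PNG file
#' @export
write_feature_image_png <- function(fi, path) {
  x <- unclass(fi)
  r <- range(x)
  x <- if (r[2] > r[1]) (x - r[1]) / (r[2] - r[1]) else x * 0 + 0.5
  if (dim(x)[3] == 1) x <- array(rep(x, 3), c(dim(x)[1:2], 3))
  write_png(x, path)
}

#' Train the regression network
#'
#' @param features list of [build_feature_image()] results
#' @param labels numeric vector of heart rates in BPM (`target = "bpm"`), or
#'   a list/matrix of 25-sample PPG windows (`target = "ppg"`)
#' @param config an [evm_config()]
#' @return object of class `evm_fit`: list with the trained `model` and the
#'   per-epoch `loss` history
#' @export
train_evm <- function(features, labels, config = evm_config()) {
  if (!length(features)) stop_cfg("empty training set")
  model <- build_evm_network(config)
  x <- stack_feature_images(features)
  if (config$target == "bpm") {
    y <- matrix(normalize_bpm(as.numeric(labels)), ncol = 1)
  } else {
    y <- if (is.matrix(labels)) labels else do.call(rbind, labels)
    if (ncol(y) != 25) stop_cfg("ppg targets must have 25 samples per window")
  }
  if (nrow(y) != length(features)) stop_cfg("features and labels differ in length")
  n <- length(features)
  st <- adam_init(model$params)
  set.seed(derive_seed(config$seed, "evm-train"))
  history <- numeric(config$epochs)
  for (ep in seq_len(config$epochs)) {
    ord <- sample.int(n)
    ep_loss <- 0; nb <- 0
    for (s in seq(1, n, by = config$batch)) {
      idx <- ord[s:min(s + config$batch - 1, n)]
      xb <- x[, , idx, , drop = FALSE]
      fw <- evm_forward(model, xb, training = TRUE)
      ls <- euclid_loss(fw$out, y[idx, , drop = FALSE])
      grads <- evm_backward(model, fw$caches, ls$grad)
      up <- adam_step(model$params, grads, st, lr = config$lr)
      model$params <- up$params; st <- up$st
      ep_loss <- ep_loss + ls$loss; nb <- nb + 1
    }
    history[ep] <- ep_loss / nb
  }
  structure(list(model = model, loss = history, config = config),
            class = "evm_fit")
}

#' Predict heart rate (or PPG) from an ROI frame stream
#'
#' The stream is assumed to be at 30 FPS (rescale first with
#' [resample_fps()]). Sliding one-second windows (default stride one second)
#' are converted to feature images and passed through the network.
#'
#' @param fit an [train_evm()] result (or a bare `evm_model`)
#' @param roi_frames list of ROI frames
#' @param fps frame rate (windows hold `round(fps)` frames)
#' @param stride_s window stride in seconds
#' @return for `target = "bpm"`: data frame `time`, `bpm`; for
#'   `target = "ppg"`: a [ppg_trace()] of 25 samples per window at 25 Hz
#' @export
predict_evm <- function(fit, roi_frames, fps = 30, stride_s = 1) {
  model <- if (inherits(fit, "evm_fit")) fit$model else fit
  win <- round(fps)
  n <- length(roi_frames)
  if (n < win) stop_cfg("stream shorter than one one-second window")
  starts <- seq(1L, n - win + 1L, by = max(1L, round(stride_s * fps)))
  fims <- lapply(starts, function(s)
    build_feature_image(roi_frames[s:(s + win - 1L)], fps))
  x <- stack_feature_images(fims)
  out <- evm_forward(model, x, training = FALSE)$out
  if (model$config$target == "bpm") {
    data.frame(time = (starts - 1 + win / 2) / fps,
               bpm = denormalize_bpm(clamp(out[, 1], 0, 1)))
  } else {
    ppg_trace(as.vector(t(out)), 25)
  }
}
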
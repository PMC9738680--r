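# Meta-learning PPG estimator on composed HMD frames.
#
# The three ROI crops are composed into one 64 x 64 face-like frame (eyes
# side by side on top, lower face below). Sequences of 60 composed frames
# pass through a five-block convolutional encoder (3x3 convolutions with
# batch norm, 2x2 average pooling and ReLU, widths 32-48-64-80-120, with
# 1x1-projected shortcut connections between blocks) to one 120-vector per
# frame, then through a bidirectional LSTM, a linear layer and an ordinal
# output layer of 40 cumulative thresholds per time step. A synthetic-
# gradient generator (a 1-D convolutional encoder-decoder over time,
# temporal sizes 60 -> 40 -> 20 -> 40 -> 60 at 120 channels) learns to mimic
# the true gradient of the ordinal loss with respect to the encoder
# features, enabling transductive adaptation on unlabeled sequences.

META_T <- 60L       # sequence length (frames)
META_K <- 40L       # ordinal thresholds
META_FEAT <- 120L   # encoder feature width

#' Compose the three ROI crops into one face-like frame
#'
#' The right-eye crop is placed on the image-left (mirroring a viewed face)
#' next to the left-eye crop; the lower-face crop is resized to the width of
#' the eye band and stacked below; the result is resized to 64 x 64.
#'
#' @param left_eye,right_eye square eye crops (equal size, e.g. 100 x 100)
#' @param lower_face square lower-face crop (e.g. 400 x 400)
#' @param grayscale convert to a single channel
#' @return `64 x 64 x 3` array, or `64 x 64 x 1` when `grayscale`
#' @export
compose_frame <- function(left_eye, right_eye, lower_face, grayscale = FALSE) {
  dl <- dim(left_eye); dr <- dim(right_eye)
  if (!identical(dl[1:2], dr[1:2]))
    stop_cfg("eye crops must have identical sizes")
  if (dl[1] != dl[2] || dim(lower_face)[1] != dim(lower_face)[2])
    stop_cfg("ROI crops must be square")
  to3 <- function(x) if (length(dim(x)) == 2) array(x, c(dim(x), 1L)) else x
  le <- to3(left_eye); re <- to3(right_eye); lf <- to3(lower_face)
  if (dim(le)[3] != dim(lf)[3]) stop_cfg("channel counts differ between ROIs")
  e <- dl[1]
  band <- array(0, c(e, 2 * e, dim(le)[3]))
  band[, seq_len(e), ] <- re            # right eye on the image-left
  band[, e + seq_len(e), ] <- le
  low <- resize_image(lf, 2 * e, 2 * e)
  full <- array(0, c(3 * e, 2 * e, dim(le)[3]))
  full[seq_len(e), , ] <- band
  full[e + seq_len(2 * e), , ] <- low
  out <- resize_image(full, 64, 64)
  if (grayscale && dim(out)[3] == 3) out <- array(rgb_to_gray(out), c(64, 64, 1))
  out
}

#' Dataset split plan
#'
#' Defaults follow the 88% / 12% train/test split, with 22% of the training
#' portion set aside for pre-training and divided 55% / 45% into query and
#' support sets.
#'
#' @param train_frac,pretrain_frac_of_train,query_frac fractions
#' @param seed shuffle seed
#' @return object of class `split_plan`
#' @export
split_plan <- function(train_frac = 0.88, pretrain_frac_of_train = 0.22,
                       query_frac = 0.55, seed = 0L) {
  if (train_frac <= 0 || train_frac >= 1) stop_cfg("train_frac must be in (0, 1)")
  structure(list(train_frac = train_frac, test_frac = 1 - train_frac,
                 pretrain_frac_of_train = pretrain_frac_of_train,
                 query_frac = query_frac, support_frac = 1 - query_frac,
                 seed = as.integer(seed)),
            class = "split_plan")
}

#' Partition samples into pretrain-query / pretrain-support / train / test
#'
#' Seeded shuffle, then sizes by rounding the plan fractions. The four
#' partitions are disjoint and exhaustive.
#'
#' @param samples a list (or vector) of samples
#' @param plan a [split_plan()]
#' @return named list of the four partitions, with an `indices` attribute
#' @export
split_dataset <- function(samples, plan = split_plan()) {
  n <- length(samples)
  if (n < 10) stop_cfg("need at least 10 samples to split (got %d)", n)
  set.seed(plan$seed)
  ord <- sample.int(n)
  n_test <- round(n * plan$test_frac)
  n_train_all <- n - n_test
  n_pre <- round(n_train_all * plan$pretrain_frac_of_train)
  n_query <- round(n_pre * plan$query_frac)
  if (n_test < 1 || n_train_all - n_pre < 1 || n_pre < 2)
    stop_cfg("too few samples for all four partitions")
  idx <- list(
    pretrain_query = ord[seq_len(n_query)],
    pretrain_support = ord[n_query + seq_len(n_pre - n_query)],
    train = ord[n_pre + seq_len(n_train_all - n_pre)],
    test = ord[n_train_all + seq_len(n_test)])
  out <- lapply(idx, function(i) samples[i])
  attr(out, "indices") <- idx
  out
}

#' Cut a composed-frame stream into fixed-length training sequences
#'
#' A video of `n` frames contributes `floor(n / 60)` sequences of 60 frames
#' (dynamic lengths: nothing is discarded apart from the tail remainder).
#'
#' @param frames list of composed frames
#' @param ppg optional ground-truth PPG samples aligned with the frames
#' @return list of sequence samples: lists with `frames` (length 60) and
#'   `ppg` (length 60 or `NULL`)
#' @export
make_sequences <- function(frames, ppg = NULL) {
  n_seq <- length(frames) %/% META_T
  lapply(seq_len(n_seq), function(k) {
    idx <- (k - 1L) * META_T + seq_len(META_T)
    list(frames = frames[idx], ppg = if (!is.null(ppg)) ppg[idx])
  })
}

#' Encode a normalized PPG value as cumulative ordinal targets
#'
#' Target `k` (k = 1..40) is 1 iff the value exceeds `(k - 1) / 40`.
#'
#' @param v values in `[0, 1]` (vector)
#' @return `length(v) x 40` binary matrix
#' @export
ordinal_encode <- function(v) {
  thr <- (seq_len(META_K) - 1) / META_K
  outer(v, thr, function(a, b) as.numeric(a > b))
}

#' Decode ordinal probabilities to values
#'
#' Value = (number of thresholds with probability > 0.5) / 40; the round-trip
#' error of encode/decode is at most 1/40.
#'
#' @param probs `T x 40` matrix of per-threshold probabilities
#' @return numeric vector of length `T` in `[0, 1]`
#' @export
ordinal_decode <- function(probs) {
  rowSums(probs > 0.5) / META_K
}

# ---- network -------------------------------------------------------------

meta_blocks <- function(channels) {
  widths <- c(channels, 32L, 48L, 64L, 80L, 120L)
  lapply(seq_len(5), function(i) list(cin = widths[i], cout = widths[i + 1]))
}

#' Build the meta-learning network
#'
#' @param channels input channels (3 RGB or 1 grayscale)
#' @param seed initialization seed
#' @return object of class `meta_model` (environment with `params`, `bn`,
#'   `channels`)
#' @export
build_meta_network <- function(channels = 3L, seed = 0L) {
  stopifnot(channels %in% c(1L, 3L))
  set.seed(derive_seed(seed, "meta-init"))
  params <- list()
  bn <- list()
  for (i in seq_along(meta_blocks(channels))) {
    bk <- meta_blocks(channels)[[i]]
    nm <- paste0("enc", i)
    params[[paste0(nm, "_W")]] <- init_norm(c(3, 3, bk$cin, bk$cout),
                                            9 * bk$cin)
    params[[paste0(nm, "_b")]] <- rep(0, bk$cout)
    params[[paste0(nm, "_g")]] <- rep(1, bk$cout)
    params[[paste0(nm, "_beta")]] <- rep(0, bk$cout)
    params[[paste0(nm, "_sW")]] <- init_norm(c(bk$cin, bk$cout), bk$cin)
    dim(params[[paste0(nm, "_sW")]]) <- c(bk$cin, bk$cout)
    params[[paste0(nm, "_sb")]] <- rep(0, bk$cout)
    bn[[nm]] <- list(mean = rep(0, bk$cout), var = rep(1, bk$cout))
  }
  H <- 60L
  params <- c(params, stats::setNames(
    lstm_init(META_FEAT, H), c("lstmf_W", "lstmf_U", "lstmf_b")))
  params <- c(params, stats::setNames(
    lstm_init(META_FEAT, H), c("lstmb_W", "lstmb_U", "lstmb_b")))
  params$lin_W <- init_norm(c(2 * H, 80), 2 * H); dim(params$lin_W) <- c(2 * H, 80)
  params$lin_b <- rep(0, 80)
  params$ord_W <- init_norm(c(80, META_K), 80); dim(params$ord_W) <- c(80, META_K)
  params$ord_b <- rep(0, META_K)
  # synthetic-gradient generator: conv1d blocks over time, 120 channels
  gen_t <- c(META_T, 40L, 20L, 40L, 60L)
  for (i in 1:4) {
    nm <- paste0("gen", i)
    params[[paste0(nm, "_W")]] <- init_norm(c(3, META_FEAT, META_FEAT),
                                            3 * META_FEAT)
    params[[paste0(nm, "_b")]] <- rep(0, META_FEAT)
    if (i < 4) {
      params[[paste0(nm, "_g")]] <- rep(1, META_FEAT)
      params[[paste0(nm, "_beta")]] <- rep(0, META_FEAT)
      bn[[nm]] <- list(mean = rep(0, META_FEAT), var = rep(1, META_FEAT))
    }
  }
  m <- new.env(parent = emptyenv())
  m$params <- params
  m$bn <- bn
  m$channels <- as.integer(channels)
  m$gen_t <- gen_t
  m$gscale <- 1e3   # generator predicts gscale * gradient (conditioning)
  class(m) <- "meta_model"
  m
}

# stack a sequence's frames into (64, 64, T, C)
stack_sequence <- function(frames) {
  C <- dim(frames[[1]])[3]
  x <- array(0, c(64, 64, length(frames), C))
  for (i in seq_along(frames)) x[, , i, ] <- frames[[i]]
  x
}

# encoder forward: (64, 64, T, C) -> T x 120 features
meta_encode <- function(model, x, training = FALSE) {
  p <- model$params
  caches <- list()
  h <- x
  for (i in 1:5) {
    nm <- paste0("enc", i)
    rc <- conv2d_forward(h, p[[paste0(nm, "_W")]], p[[paste0(nm, "_b")]],
                         1L, 1L)
    rb <- bn_forward(rc$y, p[[paste0(nm, "_g")]], p[[paste0(nm, "_beta")]],
                     model$bn[[nm]], training)
    if (training) model$bn[[nm]] <- rb$stats
    rp <- avgpool2_forward(rb$y)
    rs <- pwconv_forward(h, p[[paste0(nm, "_sW")]], p[[paste0(nm, "_sb")]])
    rsp <- avgpool2_forward(rs$y)
    rr <- relu_forward(rp$y + rsp$y)
    caches[[nm]] <- list(conv = rc$cache, bn = rb$cache, pool = rp$cache,
                         short = rs$cache, spool = rsp$cache, relu = rr$cache)
    h <- rr$y
  }
  rg <- avgpool2_forward(h)                   # 2x2 -> 1x1
  caches$gpool <- rg$cache
  Tn <- dim(rg$y)[3]
  f <- rg$y; dim(f) <- c(Tn, META_FEAT)
  list(features = f, caches = caches)
}

meta_encode_backward <- function(model, caches, dfeat) {
  g <- list()
  dh <- dfeat
  dim(dh) <- c(1, 1, nrow(dfeat), META_FEAT)
  dh <- avgpool2_backward(caches$gpool, dh)
  for (i in 5:1) {
    nm <- paste0("enc", i)
    ca <- caches[[nm]]
    dsum <- relu_backward(ca$relu, dh)
    dmain <- avgpool2_backward(ca$pool, dsum)
    bb <- bn_backward(ca$bn, dmain)
    g[[paste0(nm, "_g")]] <- bb$dgamma
    g[[paste0(nm, "_beta")]] <- bb$dbeta
    bc <- conv2d_backward(ca$conv, bb$dx)
    g[[paste0(nm, "_W")]] <- bc$dW
    g[[paste0(nm, "_b")]] <- bc$db
    dshort <- avgpool2_backward(ca$spool, dsum)
    bs <- pwconv_backward(ca$short, dshort)
    g[[paste0(nm, "_sW")]] <- bs$dW
    g[[paste0(nm, "_sb")]] <- bs$db
    dh <- bc$dx + bs$dx
  }
  list(grads = g, dx = dh)
}

# estimator forward: T x 120 features -> T x 40 ordinal probabilities
meta_estimate <- function(model, feats) {
  p <- model$params
  rl <- bilstm_forward(feats, list(W = p$lstmf_W, U = p$lstmf_U, b = p$lstmf_b),
                       list(W = p$lstmb_W, U = p$lstmb_U, b = p$lstmb_b))
  r1 <- fc_forward(rl$h, p$lin_W, p$lin_b)
  rr <- relu_forward(r1$y)
  r2 <- fc_forward(rr$y, p$ord_W, p$ord_b)
  probs <- sigmoid(r2$y)
  list(probs = probs,
       caches = list(lstm = rl$cache, fc1 = r1$cache, relu = rr$cache,
                     fc2 = r2$cache))
}

# backward from d(loss)/d(logits); returns grads and d(loss)/d(features)
meta_estimate_backward <- function(model, caches, dlogits) {
  g <- list()
  b2 <- fc_backward(caches$fc2, dlogits)
  g$ord_W <- b2$dW; g$ord_b <- b2$db
  dr <- relu_backward(caches$relu, b2$dx)
  b1 <- fc_backward(caches$fc1, dr)
  g$lin_W <- b1$dW; g$lin_b <- b1$db
  bl <- bilstm_backward(caches$lstm, b1$dx)
  g$lstmf_W <- bl$fw$dW; g$lstmf_U <- bl$fw$dU; g$lstmf_b <- bl$fw$db
  g$lstmb_W <- bl$bw$dW; g$lstmb_U <- bl$bw$dU; g$lstmb_b <- bl$bw$db
  list(grads = g, dfeat = bl$dx)
}

# ordinal loss: mean binary cross-entropy over T x 40 thresholds
ordinal_loss <- function(probs, targets) {
  eps <- 1e-7
  p <- clamp(probs, eps, 1 - eps)
  loss <- -mean(targets * log(p) + (1 - targets) * log(1 - p))
  dlogits <- (probs - targets) / length(targets)   # w.r.t. pre-sigmoid logits
  list(loss = loss, dlogits = dlogits)
}

# generator forward: features T x 120 -> synthetic gradient T x 120
meta_generate <- function(model, feats, training = FALSE) {
  p <- model$params
  caches <- list()
  h <- feats
  tins <- c(META_T, model$gen_t[2:4])
  touts <- model$gen_t[2:5]
  for (i in 1:4) {
    nm <- paste0("gen", i)
    rc <- conv1d_forward(h, p[[paste0(nm, "_W")]], p[[paste0(nm, "_b")]])
    A <- if (touts[i] < nrow(rc$y)) adaptive_pool_matrix(nrow(rc$y), touts[i])
         else interp_matrix(nrow(rc$y), touts[i])
    hr <- A %*% rc$y
    if (i < 4) {
      rb <- bn_forward(hr, p[[paste0(nm, "_g")]], p[[paste0(nm, "_beta")]],
                       model$bn[[nm]], training)
      if (training) model$bn[[nm]] <- rb$stats
      rr <- relu_forward(rb$y)
      caches[[nm]] <- list(conv = rc$cache, A = A, bn = rb$cache, relu = rr$cache)
      h <- rr$y
    } else {
      caches[[nm]] <- list(conv = rc$cache, A = A)
      h <- hr
    }
  }
  list(g = h, caches = caches)
}

meta_generate_backward <- function(model, caches, dout) {
  g <- list()
  dh <- dout
  for (i in 4:1) {
    nm <- paste0("gen", i)
    ca <- caches[[nm]]
    if (i < 4) {
      dh <- relu_backward(ca$relu, dh)
      bb <- bn_backward(ca$bn, dh)
      g[[paste0(nm, "_g")]] <- bb$dgamma
      g[[paste0(nm, "_beta")]] <- bb$dbeta
      dh <- bb$dx
    }
    dh <- t(ca$A) %*% dh
    bc <- conv1d_backward(ca$conv, dh)
    g[[paste0(nm, "_W")]] <- bc$dW
    g[[paste0(nm, "_b")]] <- bc$db
    dh <- bc$dx
  }
  g
}

# min-max normalize a PPG segment to [0, 1] (constant segments -> 0.5)
minmax01 <- function(v) {
  r <- range(v)
  if (r[2] - r[1] < 1e-12) return(rep(0.5, length(v)))
  (v - r[1]) / (r[2] - r[1])
}

#' Train the meta-learning estimator
#'
#' Phase 1 (pre-training) runs episodic few-shot loops: each episode adapts
#' the encoder on a support sequence using synthetic gradients, then updates
#' all task parameters (and the generator, by gradient matching) on a query
#' sequence. Phase 2 trains on the main training partition with the ordinal
#' loss plus the gradient-matching loss.
#'
#' @param splits result of [split_dataset()] on sequence samples (lists with
#'   `frames` and `ppg`)
#' @param epochs training epochs for each phase
#' @param lr Adam learning rate
#' @param adapt_lr step size of the synthetic-gradient encoder updates
#' @param seed seed for initialization and shuffling
#' @param channels 3 (RGB) or 1 (grayscale)
#' @param pretrain_epochs episodic pre-training epochs (default `epochs`)
#' @return object of class `meta_fit`: `model`, `loss` (phase-2 history),
#'   `pretrain_loss`, `genloss` (gradient-matching history)
#' @export
train_meta <- function(splits, epochs = 10, lr = 1e-3, adapt_lr = 1e-3,
                       seed = 0L, channels = 3L, pretrain_epochs = NULL) {
  for (part in c("pretrain_query", "pretrain_support", "train"))
    if (!length(splits[[part]])) stop_cfg("empty partition '%s'", part)
  pretrain_epochs <- pretrain_epochs %||% max(1L, epochs %/% 2L)
  model <- build_meta_network(channels, seed)
  st <- adam_init(model$params)
  set.seed(derive_seed(seed, "meta-train"))
  seq_xy <- function(s) {
    list(x = stack_sequence(s$frames),
         y = if (!is.null(s$ppg)) ordinal_encode(minmax01(s$ppg)))
  }
  sup_step <- function(s) {
    # transductive adaptation: encoder step along the synthetic gradient
    enc <- meta_encode(model, seq_xy(s)$x, training = TRUE)
    gen <- meta_generate(model, enc$features, training = FALSE)
    bk <- meta_encode_backward(model, enc$caches, gen$g / model$gscale)
    for (nm in grep("^enc", names(model$params), value = TRUE))
      if (!is.null(bk$grads[[nm]]))
        model$params[[nm]] <- model$params[[nm]] - adapt_lr * bk$grads[[nm]]
    invisible(NULL)
  }
  task_step <- function(s) {
    xy <- seq_xy(s)
    enc <- meta_encode(model, xy$x, training = TRUE)
    est <- meta_estimate(model, enc$features)
    ls <- ordinal_loss(est$probs, xy$y)
    eb <- meta_estimate_backward(model, est$caches, ls$dlogits)
    kb <- meta_encode_backward(model, enc$caches, eb$dfeat)
    # generator learns to mimic the true feature gradient (scaled up so the
    # matching loss is well-conditioned; Adam is scale-free per parameter)
    gen <- meta_generate(model, enc$features, training = TRUE)
    gdiff <- gen$g - model$gscale * eb$dfeat
    genloss <- mean(gdiff * gdiff)
    gg <- meta_generate_backward(model, gen$caches,
                                 2 * gdiff / length(gdiff))
    grads <- c(eb$grads, kb$grads, gg)
    up <- adam_step(model$params, grads, st, lr = lr)
    model$params <<- up$params
    st <<- up$st
    list(loss = ls$loss, genloss = genloss)
  }
  pre_hist <- numeric(pretrain_epochs)
  for (ep in seq_len(pretrain_epochs)) {
    sup <- splits$pretrain_support[sample.int(length(splits$pretrain_support))]
    qry <- splits$pretrain_query[sample.int(length(splits$pretrain_query))]
    for (s in sup) sup_step(s)
    ls <- vapply(qry, function(s) task_step(s)$loss, 0)
    pre_hist[ep] <- mean(ls)
  }
  hist <- numeric(epochs)
  gen_hist <- numeric(epochs)
  for (ep in seq_len(epochs)) {
    ord <- sample.int(length(splits$train))
    res <- lapply(splits$train[ord], task_step)
    hist[ep] <- mean(vapply(res, `[[`, 0, "loss"))
    gen_hist[ep] <- mean(vapply(res, `[[`, 0, "genloss"))
  }
  structure(list(model = model, loss = hist, pretrain_loss = pre_hist,
                 genloss = gen_hist, seed = seed),
            class = "meta_fit")
}

#' Transductive adaptation and PPG prediction
#'
#' Optionally performs `k` encoder updates driven by the synthetic-gradient
#' generator on the (unlabeled) test sequences, then decodes the ordinal
#' outputs into a PPG trace at the frame rate.
#'
#' @param fit a [train_meta()] result (or bare `meta_model`)
#' @param sequences list of sequence samples (`frames`, optional `ppg`)
#' @param k number of adaptation steps (0 = pure inference)
#' @param adapt_lr adaptation step size
#' @param fps frame rate of the composed-frame stream
#' @return list with `ppg` (a [ppg_trace()], 60 samples per sequence) and
#'   `bpm` (the [ppg_to_bpm()] series when the trace is long enough)
#' @export
adapt_and_predict <- function(fit, sequences, k = 3, adapt_lr = 1e-3,
                              fps = 30) {
  model <- if (inherits(fit, "meta_fit")) fit$model else fit
  if (k > 0) {
    for (step in seq_len(k)) {
      for (s in sequences) {
        x <- stack_sequence(s$frames)
        enc <- meta_encode(model, x, training = FALSE)
        gen <- meta_generate(model, enc$features, training = FALSE)
        bk <- meta_encode_backward(model, enc$caches, gen$g / model$gscale)
        for (nm in grep("^enc", names(model$params), value = TRUE))
          if (!is.null(bk$grads[[nm]]))
            model$params[[nm]] <- model$params[[nm]] - adapt_lr * bk$grads[[nm]]
      }
    }
  }
  vals <- unlist(lapply(sequences, function(s) {
    enc <- meta_encode(model, stack_sequence(s$frames), training = FALSE)
    est <- meta_estimate(model, enc$features)
    ordinal_decode(est$probs)
  }))
  trace <- ppg_trace(vals, fps)
  bpm <- tryCatch(ppg_to_bpm(trace), error = function(e) NULL)
  list(ppg = trace, bpm = bpm)
}
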
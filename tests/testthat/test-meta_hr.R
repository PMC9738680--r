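ns <- asNamespace("hmdrppg")

test_that("compose_frame places ROI colors according to the face layout", {
  mkc <- function(rgb, n) {
    a <- array(0, c(n, n, 3))
    for (c in 1:3) a[, , c] <- rgb[c]
    a
  }
  le <- mkc(c(1, 0, 0), 100)   # left eye: red
  re <- mkc(c(0, 1, 0), 100)   # right eye: green
  lf <- mkc(c(0, 0, 1), 400)   # lower face: blue
  out <- compose_frame(le, re, lf)
  expect_equal(dim(out), c(64, 64, 3))
  # top band: image-left half is the right eye (green), right half red
  top_l <- out[1:20, 1:30, ]
  top_r <- out[1:20, 35:64, ]
  expect_gt(mean(top_l[, , 2]), 0.9); expect_lt(mean(top_l[, , 1]), 0.1)
  expect_gt(mean(top_r[, , 1]), 0.9); expect_lt(mean(top_r[, , 2]), 0.1)
  # bottom two thirds: lower face (blue)
  bottom <- out[24:64, , ]
  expect_gt(mean(bottom[, , 3]), 0.9)

  black <- compose_frame(mkc(c(0, 0, 0), 100), mkc(c(0, 0, 0), 100),
                         mkc(c(0, 0, 0), 400))
  expect_equal(max(abs(black)), 0)

  g <- compose_frame(le, re, lf, grayscale = TRUE)
  expect_equal(dim(g), c(64, 64, 1))
  expect_error(compose_frame(le, mkc(c(0, 1, 0), 50), lf), "identical")
})

test_that("split_dataset reproduces the 88/12 and 22%, 55/45 arithmetic", {
  s <- split_dataset(as.list(1:100), split_plan(seed = 1))
  expect_length(s$test, 12)
  expect_length(s$train, 88 - 19)
  expect_length(s$pretrain_query, 10)
  expect_length(s$pretrain_support, 9)
})

test_that("split partitions are disjoint, exhaustive and seed-stable", {
  for (n in c(10, 37, 250)) {
    for (seed in c(0, 9)) {
      s <- split_dataset(as.list(seq_len(n)), split_plan(seed = seed))
      all_idx <- sort(unname(unlist(s)))
      expect_equal(all_idx, seq_len(n))
    }
  }
  a <- split_dataset(as.list(1:50), split_plan(seed = 3))
  b <- split_dataset(as.list(1:50), split_plan(seed = 3))
  expect_identical(a, b)
  expect_error(split_dataset(as.list(1:5), split_plan()), "at least 10")
})

test_that("make_sequences cuts floor(n/60) sequences of length 60", {
  frames <- lapply(1:130, function(i) array(0, c(2, 2, 3)))
  ppg <- seq_len(130)
  ss <- make_sequences(frames, ppg)
  expect_length(ss, 2)
  expect_length(ss[[1]]$frames, 60)
  expect_equal(ss[[2]]$ppg, 61:120)
})

test_that("ordinal encode/decode follow the threshold-count arithmetic", {
  expect_equal(ordinal_encode(0)[1, ], rep(0, 40))
  expect_equal(ordinal_encode(1)[1, ], rep(1, 40))
  half <- ordinal_encode(0.5)[1, ]
  expect_equal(sum(half), 20)
  expect_equal(half, c(rep(1, 20), rep(0, 20)))
  expect_equal(ordinal_decode(ordinal_encode(0.5)), 0.5)
  # round-trip error bounded by 1/40 everywhere
  v <- seq(0, 1, length.out = 101)
  expect_lt(max(abs(ordinal_decode(ordinal_encode(v)) - v)), 1 / 40 + 1e-12)
})

test_that("all printed intermediate shapes are reproduced (shape probe)", {
  m <- build_meta_network(3L, seed = 1)
  Tn <- 60
  x <- array(rnorm(64 * 64 * Tn * 3) * 0.1, c(64, 64, Tn, 3))
  enc <- ns$meta_encode(m, x, training = FALSE)
  expect_equal(dim(enc$features), c(60, 120))
  # encoder block outputs: 32x32x32, 16x16x48, 8x8x64, 4x4x80, 2x2x120
  spat <- c(32, 16, 8, 4, 2)
  wid <- c(32, 48, 64, 80, 120)
  for (i in 1:5) {
    d <- enc$caches[[paste0("enc", i)]]$relu |> dim()
    expect_equal(d, c(spat[i], spat[i], Tn, wid[i]))
  }
  est <- ns$meta_estimate(m, enc$features)
  expect_equal(dim(est$probs), c(60, 40))
  expect_equal(dim(est$caches$fc1$x), c(60, 120))   # biLSTM output
  expect_equal(dim(est$caches$fc2$x), c(60, 80))    # linear output
  gen <- ns$meta_generate(m, enc$features)
  expect_equal(dim(gen$g), c(60, 120))
  # generator temporal encoder-decoder: 40 -> 20 -> 40 -> 60
  expect_equal(nrow(gen$caches$gen2$conv$xp) - 2, 40)
  expect_equal(nrow(gen$caches$gen3$conv$xp) - 2, 20)
  expect_equal(nrow(gen$caches$gen4$conv$xp) - 2, 40)
})

test_that("grayscale variant accepts single-channel sequences", {
  m <- build_meta_network(1L, seed = 2)
  x <- array(rnorm(64 * 64 * 60) * 0.1, c(64, 64, 60, 1))
  enc <- ns$meta_encode(m, x, training = FALSE)
  expect_equal(dim(enc$features), c(60, 120))
})

test_that("k = 0 adaptation equals a plain forward pass and is idempotent", {
  set.seed(77)
  m <- build_meta_network(3L, seed = 3)
  seqs <- list(list(frames = lapply(1:60, function(i)
    array(runif(64 * 64 * 3, 0.4, 0.6), c(64, 64, 3))), ppg = NULL))
  a <- adapt_and_predict(m, seqs, k = 0)
  b <- adapt_and_predict(m, seqs, k = 0)
  expect_identical(a$ppg$samples, b$ppg$samples)
  expect_length(a$ppg$samples, 60)
  expect_true(all(a$ppg$samples >= 0 & a$ppg$samples <= 1))
})

test_that("model initialization is deterministic under a seed", {
  a <- build_meta_network(3L, seed = 9)
  b <- build_meta_network(3L, seed = 9)
  expect_identical(a$params, b$params)
})
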
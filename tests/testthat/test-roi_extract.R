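test_that("compute_center matches the arithmetic-mean oracle", {
  expect_equal(compute_center(cbind(10, 20)), c(10, 20))
  expect_equal(compute_center(cbind(c(0, 2, 0, 2), c(0, 0, 2, 2))), c(1, 1))
  set.seed(21)
  pts <- cbind(runif(5, 0, 100), runif(5, 0, 100))
  sx <- 0; sy <- 0
  for (i in 1:5) { sx <- sx + pts[i, 1]; sy <- sy + pts[i, 2] }
  expect_equal(compute_center(pts), c(sx / 5, sy / 5))
  expect_error(compute_center(matrix(0, 0, 2)), "empty")
})

test_that("center_distance is Euclidean, symmetric and zero iff equal", {
  expect_equal(center_distance(c(100, 100), c(100, 100)), 0)
  expect_equal(center_distance(c(100, 100), c(103, 104)), 5)
  expect_equal(center_distance(c(0, 0), c(1, 1)), sqrt(2))
  expect_equal(center_distance(c(3, 9), c(-2, 1)),
               center_distance(c(-2, 1), c(3, 9)))
})

test_that("threshold update: ties keep, exceedance moves by mode", {
  tr <- roi_track("left_eye", c(100, 100), side = 100)
  expect_equal(tr$threshold, 5)
  # d == threshold exactly (3-4-5 triangle): strictly-greater rule keeps
  kept <- update_center(tr, c(103, 104), "replace")
  expect_equal(kept$center, c(100, 100))
  expect_false(attr(kept, "moved"))
  moved_r <- update_center(tr, c(110, 110), "replace")
  expect_equal(moved_r$center, c(110, 110))
  moved_s <- update_center(tr, c(110, 110), "smooth")
  expect_equal(moved_s$center, c(105, 105))
})

test_that("crop_roi returns the exact output sizes and constant fields", {
  clip <- static_clip()
  frame <- clip$frames[[1]]
  lm <- clip$landmarks[[1]]
  eye <- roi_track("left_eye", compute_center(lm$left_eye), 30)
  expect_equal(dim(crop_roi(frame, eye, 100)), c(100, 100, 3))
  mouth <- roi_track("lower_face", compute_center(lm$mouth), 60)
  expect_equal(dim(crop_roi(frame, mouth, 400)), c(400, 400, 3))
  gray <- matrix(0.37, 120, 160)
  expect_equal(as.numeric(crop_roi(gray, eye, 50)), rep(0.37, 2500))
  far <- roi_track("left_eye", c(1000, 1000), 30)
  expect_error(crop_roi(frame, far, 100), "outside")
})

test_that("mouth_distortion matches a brute-force inverse-mapping oracle", {
  set.seed(31)
  n <- 24
  checker <- (outer(0:(n - 1) %/% 4, 0:(n - 1) %/% 4, "+") %% 2)
  center <- c(11, 11); radius <- 10; strength <- 0.3
  out <- mouth_distortion(checker, center, radius, strength)
  # scalar per-pixel oracle
  oracle <- checker
  for (yy in 0:(n - 1)) for (xx in 0:(n - 1)) {
    dx <- xx - center[1]; dy <- yy - center[2]
    r <- sqrt(dx^2 + dy^2)
    if (r > 0 && r < radius) {
      sc <- 1 - strength * (1 - r / radius)
      sx <- center[1] + dx * sc; sy <- center[2] + dy * sc
      x0 <- floor(sx); y0 <- floor(sy)
      fx <- sx - x0; fy <- sy - y0
      x1 <- min(x0 + 1, n - 1); y1 <- min(y0 + 1, n - 1)
      oracle[yy + 1, xx + 1] <-
        checker[y0 + 1, x0 + 1] * (1 - fx) * (1 - fy) +
        checker[y0 + 1, x1 + 1] * fx * (1 - fy) +
        checker[y1 + 1, x0 + 1] * (1 - fx) * fy +
        checker[y1 + 1, x1 + 1] * fx * fy
    }
  }
  expect_equal(out, oracle, tolerance = 1e-12)
  # identity cases
  expect_identical(mouth_distortion(checker, center, radius, 0), checker)
  expect_equal(out[12, 12], checker[12, 12])
  # pixels at or beyond the radius untouched
  expect_equal(out[1, ], checker[1, ])
})

test_that("a static face with exact landmarks yields constant centers", {
  clip <- static_clip()
  res <- process_video(clip$frames[1:20], clip$landmarks[1:20],
                       small_extractor())
  for (rn in unique(res$log$roi)) {
    expect_equal(length(unique(res$log$cx[res$log$roi == rn])), 1)
    expect_equal(length(unique(res$log$cy[res$log$roi == rn])), 1)
  }
})

test_that("sub-threshold landmark noise leaves exported centers constant", {
  clip <- static_clip()
  lms <- clip$landmarks[1:30]
  # inject noise well below threshold/2 on every landmark group
  set.seed(8)
  noisy <- lapply(lms, function(lf)
    lapply(lf, function(p) p + matrix(runif(length(p), -0.3, 0.3), nrow(p), 2)))
  res <- process_video(clip$frames[1:30], noisy, small_extractor())
  for (rn in unique(res$log$roi))
    expect_equal(length(unique(res$log$cx[res$log$roi == rn])), 1)
})

test_that("a super-threshold step is tracked within one frame (replace)", {
  clip <- static_clip()
  lms <- clip$landmarks[1:10]
  shift <- 20   # far beyond 5% of any ROI side here
  for (k in 6:10)
    lms[[k]] <- lapply(lms[[k]], function(p) p + shift)
  res <- process_video(clip$frames[1:10], lms,
                       small_extractor(update_mode = "replace"))
  for (rn in unique(res$log$roi)) {
    cx <- res$log$cx[res$log$roi == rn]
    expect_equal(cx[6], cx[1] + shift)
    expect_equal(cx[10], cx[1] + shift)
  }
})

test_that("failure policy: reuse last coordinates, abort on consecutive", {
  clip <- static_clip()
  lms <- clip$landmarks[1:40]
  lms[31] <- list(NULL)   # detection failure at frame index 30
  res <- process_video(clip$frames[1:40], lms, small_extractor())
  expect_equal(nrow(res$log), 40 * 3)
  cx30 <- res$log$cx[res$log$frame == 30 & res$log$roi == "left_eye"]
  cx29 <- res$log$cx[res$log$frame == 29 & res$log$roi == "left_eye"]
  expect_equal(cx30, cx29)

  lms[31] <- list(NULL); lms[32] <- list(NULL)
  expect_error(
    process_video(clip$frames[1:40], lms,
                  small_extractor(max_consecutive_failures = 2)),
    "frame 31")
  expect_error(
    process_video(c(list(NULL), clip$frames[2:5]),
                  c(list(NULL), clip$landmarks[2:5]), small_extractor()),
    "first frame")
})

test_that("exports use the documented naming, formats and sizes", {
  dir <- withr::local_tempdir()
  clip <- static_clip()
  process_video(clip$frames[1:3], clip$landmarks[1:3],
                extractor_config(eye_out = 24, mouth_out = 32), out_dir = dir)
  expect_true(file.exists(file.path(dir, "left_eye", "left_eye_000000.png")))
  expect_true(file.exists(file.path(dir, "lower_face", "lower_face_000002.png")))
  log <- utils::read.csv(file.path(dir, "track_log.csv"))
  expect_named(log, c("frame", "roi", "cx", "cy", "d", "moved"))

  # grayscale export goes to PGM and round-trips
  dir2 <- withr::local_tempdir()
  res <- process_video(clip$frames[1:2], clip$landmarks[1:2],
                       extractor_config(eye_out = 16, mouth_out = 16,
                                        grayscale = TRUE),
                       out_dir = dir2, keep_frames = TRUE)
  f <- file.path(dir2, "left_eye", "left_eye_000000.pgm")
  expect_true(file.exists(f))
  expect_equal(read_pnm(f), res$crops$left_eye[[1]], tolerance = 1 / 255)
})

test_that("output crops always have the configured sizes", {
  clip <- static_clip()
  res <- process_video(clip$frames[1:2], clip$landmarks[1:2],
                       extractor_config(), keep_frames = TRUE)
  expect_equal(dim(res$crops$left_eye[[1]]), c(100, 100, 3))
  expect_equal(dim(res$crops$right_eye[[2]]), c(100, 100, 3))
  expect_equal(dim(res$crops$lower_face[[1]]), c(400, 400, 3))
})
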
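# Synthetic pulse-bearing face videos.
#
# The generator renders an ellipsoidal "skin" region on a dark background.
# The mean skin colour is modulated by a pulse waveform
#   w(theta) = sin(theta) + 0.3 sin(2 theta),   theta = 2*pi*f*t + phase
# with f = heart_rate / 60. The asymmetric second harmonic gives one
# well-defined peak per beat, so the peak-based BPM converter sees realistic
# (non-sinusoidal) pulses. The face performs a seeded random-walk translation
# and ground-truth landmarks ride rigidly on it. Stored alongside each clip
# are the exact landmark positions and the noise-free PPG waveform sampled at
# the frame rate.

#' Pulse waveform: fundamental plus one harmonic
#'
#' @param theta phase in radians
#' @return waveform values (dimensionless)
#' @export
pulse_waveform <- function(theta) sin(theta) + 0.3 * sin(2 * theta)

#' Configuration for a synthetic face clip
#'
#' @param width,height frame size in pixels
#' @param fps frames per second
#' @param duration clip length in seconds
#' @param heart_rate simulated heart rate in BPM (45--240)
#' @param pulse_amplitude peak colour modulation, colour units on `[0, 1]`
#' @param noise_sigma per-pixel Gaussian noise SD, colour units
#' @param jitter_step random-walk translation step SD, pixels per frame
#' @param phase0 initial pulse phase in radians (`NULL`: drawn from the seed)
#' @param seed integer seed controlling jitter, noise and phase
#' @return object of class `scene_config`
#' @export
scene_config <- function(width = 640, height = 480, fps = 30, duration = 10,
                         heart_rate = 72, pulse_amplitude = 0.02,
                         noise_sigma = 0.005, jitter_step = 0.5,
                         phase0 = NULL, seed = 1L) {
  if (!is_scalar_num(fps) || fps <= 0) stop_cfg("fps must be > 0")
  if (!is_scalar_num(duration) || duration <= 0) stop_cfg("duration must be > 0")
  if (!is_scalar_num(heart_rate) || heart_rate < 45 || heart_rate > 240)
    stop_cfg("heart_rate must lie in [45, 240] BPM")
  if (pulse_amplitude < 0 || noise_sigma < 0 || jitter_step < 0)
    stop_cfg("amplitudes must be >= 0")
  structure(list(width = width, height = height, fps = fps,
                 duration = duration, heart_rate = heart_rate,
                 pulse_amplitude = pulse_amplitude, noise_sigma = noise_sigma,
                 jitter_step = jitter_step, phase0 = phase0,
                 seed = as.integer(seed)),
            class = "scene_config")
}

# landmark layout (face-local offsets from the ellipse centre), scaled from
# the ellipse semi-axes a (horizontal) and b (vertical)
face_landmarks_local <- function(a, b) {
  eye_y <- -0.35 * b
  dx <- max(2, 0.05 * a); dy <- max(1, 0.025 * b)
  eye <- function(cx) cbind(x = cx + c(-dx, dx, 0, 0),
                            y = eye_y + c(0, 0, -dy, dy))
  ang <- seq(0, 2 * pi, length.out = 7)[-7]
  mouth <- cbind(x = 0.18 * a * cos(ang), y = 0.55 * b + 0.08 * b * sin(ang))
  list(left_eye = eye(0.5 * a),      # image-left for the viewer = subject right
       right_eye = eye(-0.5 * a),
       mouth = mouth,
       nose = cbind(x = 0, y = 0.15 * b))
}

#' Generate a synthetic face clip
#'
#' @param config a [scene_config()]
#' @return object of class `synthetic_clip`: list with `frames` (list of
#'   `H x W x 3` arrays on `[0, 1]`), `landmarks` (list of landmark frames:
#'   named lists of `n x 2` point matrices, 0-based pixel coordinates),
#'   `ppg` (a [ppg_trace()] sampled at `fps`), `heart_rate`, `fps`
#' @export
generate_clip <- function(config) {
  if (!inherits(config, "scene_config")) stop_cfg("config must be a scene_config")
  set.seed(config$seed)
  w <- config$width; h <- config$height
  n <- round(config$fps * config$duration)
  if (n < 1) stop_cfg("duration too short for one frame")
  a <- 0.22 * w; b <- 0.33 * h
  cx0 <- w / 2; cy0 <- h / 2
  lm_local <- face_landmarks_local(a, b)
  skin <- c(0.80, 0.60, 0.50)
  chan_w <- c(0.7, 1.0, 0.8)         # green channel carries the strongest pulse
  bg <- 0.15
  phase0 <- config$phase0 %||% stats::runif(1, 0, 2 * pi)
  f <- config$heart_rate / 60
  tt <- (seq_len(n) - 1) / config$fps
  wv <- pulse_waveform(2 * pi * f * tt + phase0)
  ppg <- config$pulse_amplitude * wv     # the modulation actually applied
  # random walk of the face centre
  if (config$jitter_step > 0) {
    dxs <- cumsum(stats::rnorm(n, 0, config$jitter_step))
    dys <- cumsum(stats::rnorm(n, 0, config$jitter_step))
  } else {
    dxs <- dys <- rep(0, n)
  }
  xs <- matrix(rep(0:(w - 1), each = h), h, w)
  ys <- matrix(rep(0:(h - 1), w), h, w)
  frames <- vector("list", n)
  landmarks <- vector("list", n)
  for (k in seq_len(n)) {
    cx <- cx0 + dxs[k]; cy <- cy0 + dys[k]
    mask <- ((xs - cx) / a)^2 + ((ys - cy) / b)^2 <= 1
    fr <- array(bg, c(h, w, 3))
    for (c in 1:3) {
      plane <- fr[, , c]
      val <- skin[c] + chan_w[c] * ppg[k]
      plane[mask] <- val
      if (config$noise_sigma > 0)
        plane <- plane + stats::rnorm(h * w, 0, config$noise_sigma)
      fr[, , c] <- clamp(plane, 0, 1)
    }
    frames[[k]] <- fr
    landmarks[[k]] <- lapply(lm_local, function(p)
      cbind(x = p[, 1] + cx, y = p[, 2] + cy))
  }
  structure(list(frames = frames, landmarks = landmarks,
                 ppg = ppg_trace(ppg, config$fps),
                 heart_rate = config$heart_rate, fps = config$fps,
                 config = config),
            class = "synthetic_clip")
}

#' Ground-truth landmark stream, optionally perturbed
#'
#' Returns the stored landmark frames of a synthetic clip, with optional
#' seeded Gaussian jitter (independent per coordinate) to exercise the ROI
#' stabilizer.
#'
#' @param clip a [generate_clip()] result
#' @param sigma landmark noise SD in pixels
#' @param seed integer seed for the perturbation
#' @return list of landmark frames (one per video frame)
#' @export
landmark_provider <- function(clip, sigma = 0, seed = 1L) {
  stopifnot(inherits(clip, "synthetic_clip"))
  if (sigma <= 0) return(clip$landmarks)
  set.seed(as.integer(seed))
  lapply(clip$landmarks, function(lf)
    lapply(lf, function(p) p + matrix(stats::rnorm(length(p), 0, sigma),
                                      nrow(p), 2)))
}

#' Write a clip to disk as numbered PNG frames plus a ground-truth file
#'
#' @param clip a [generate_clip()] result
#' @param out_dir output directory (created if needed)
#' @return `out_dir`, invisibly
#' @export
write_clip <- function(clip, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (k in seq_along(clip$frames))
    write_png(clip$frames[[k]], file.path(out_dir, sprintf("frame_%06d.png", k - 1)))
  n <- length(clip$frames)
  write_ubfc_trace(clip$ppg$samples, rep(clip$heart_rate, n),
                   (seq_len(n) - 1) / clip$fps,
                   file.path(out_dir, "ground_truth.txt"))
  invisible(out_dir)
}
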
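# Region-of-interest extraction with threshold stabilization.
#
# Three ROIs simulate the camera views of a head-mounted display: left eye,
# right eye and lower face. Each ROI is a square whose centre is the mean of
# its landmark group. To suppress landmark jitter, a new detection only moves
# an ROI when the Euclidean distance between the previous and current centre
# exceeds a threshold of 5% of the ROI side; below (or at) the threshold the
# previous centre is kept. When it is exceeded, the "smooth" update moves to
# the midpoint of the old and new centres and the "replace" update adopts the
# new centre outright.
#
# Coordinates are 0-based pixels, x to the right, y down.

#' Extractor configuration
#'
#' @param update_mode `"smooth"` (average of old and new centres) or
#'   `"replace"` (adopt the new centre)
#' @param eye_out output side of the eye crops, pixels
#' @param mouth_out output side of the lower-face crop, pixels
#' @param max_consecutive_failures abort after this many consecutive
#'   landmark-detection failures
#' @param distortion_strength radial magnification strength for the mouth
#'   region (0 disables)
#' @param eye_scale ROI side for the eyes as a multiple of the landmark
#'   bounding-box diagonal
#' @param grayscale export single-channel frames (PGM) instead of RGB (PNG)
#' @return object of class `extractor_config`
#' @export
extractor_config <- function(update_mode = c("smooth", "replace"),
                             eye_out = 100, mouth_out = 400,
                             max_consecutive_failures = 2,
                             distortion_strength = 0.3,
                             eye_scale = 2.2,
                             grayscale = FALSE) {
  update_mode <- match.arg(update_mode)
  if (eye_out <= 0 || mouth_out <= 0) stop_cfg("output sizes must be > 0")
  if (distortion_strength < 0) stop_cfg("distortion_strength must be >= 0")
  structure(list(update_mode = update_mode, eye_out = eye_out,
                 mouth_out = mouth_out,
                 max_consecutive_failures = as.integer(max_consecutive_failures),
                 distortion_strength = distortion_strength,
                 eye_scale = eye_scale, grayscale = grayscale),
            class = "extractor_config")
}

#' Centre of a landmark group
#'
#' The ROI centre is the arithmetic mean of the group's point coordinates.
#'
#' @param points `n x 2` matrix (or list of length-2 points)
#' @return numeric `(x, y)`
#' @export
compute_center <- function(points) {
  if (is.list(points)) points <- do.call(rbind, points)
  points <- as.matrix(points)
  if (nrow(points) == 0) stop_cfg("landmark group is empty")
  if (!all(is.finite(points))) stop_cfg("landmark coordinates must be finite")
  c(mean(points[, 1]), mean(points[, 2]))
}

#' Euclidean distance between two ROI centres
#' @param prev,curr numeric `(x, y)`
#' @return distance in pixels
#' @export
center_distance <- function(prev, curr) {
  stopifnot(all(is.finite(prev)), all(is.finite(curr)))
  sqrt(sum((curr - prev)^2))
}

#' Create per-ROI stabilizer state
#'
#' The movement threshold is always 5% of the ROI side.
#'
#' @param name one of `"left_eye"`, `"right_eye"`, `"lower_face"`
#' @param center numeric `(x, y)` pixels
#' @param side ROI square side, pixels
#' @return object of class `roi_track`
#' @export
roi_track <- function(name, center, side) {
  if (side <= 0) stop_cfg("ROI side must be > 0")
  structure(list(name = name, center = as.numeric(center), side = side,
                 threshold = 0.05 * side, fail_count = 0L),
            class = "roi_track")
}

#' Apply the threshold-stabilized centre update
#'
#' Movement requires the centre displacement to be strictly greater than the
#' threshold; a displacement equal to the threshold keeps the old centre.
#'
#' @param track an [roi_track()]
#' @param new_center newly detected `(x, y)`
#' @param mode `"smooth"` or `"replace"`
#' @return updated track, with attributes `moved` (logical) and `d` (pixels)
#' @export
update_center <- function(track, new_center, mode = c("smooth", "replace")) {
  mode <- match.arg(mode)
  d <- center_distance(track$center, new_center)
  moved <- d > track$threshold
  if (moved) {
    track$center <- if (mode == "smooth")
      (track$center + as.numeric(new_center)) / 2
    else as.numeric(new_center)
  }
  attr(track, "moved") <- moved
  attr(track, "d") <- d
  track
}

# integer pixel range of a square crop (0-based half-open), clamped indices
crop_indices <- function(center, side, n) {
  len <- max(1L, round(side))
  start <- round(center - side / 2)
  idx <- start + seq_len(len) - 1L      # 0-based positions
  clamp(idx, 0L, n - 1L) + 1L           # 1-based array indices, edge replicated
}

#' Crop a square ROI and resize to its output size
#'
#' The crop has edge `side` centred on the track centre; portions outside the
#' frame are filled by edge replication. The result is resized to
#' `out_size x out_size` (eyes: 100, lower face: 400 by default).
#'
#' @param frame image array (`H x W` or `H x W x C`)
#' @param track an [roi_track()]
#' @param out_size output side in pixels
#' @return square image of side `out_size`
#' @export
crop_roi <- function(frame, track, out_size) {
  d <- dim(frame)
  h <- d[1]; w <- d[2]
  cx <- track$center[1]; cy <- track$center[2]
  if (cx + track$side / 2 < 0 || cx - track$side / 2 > w - 1 ||
      cy + track$side / 2 < 0 || cy - track$side / 2 > h - 1)
    stop_cfg("ROI '%s' lies fully outside the frame", track$name)
  ri <- crop_indices(cy, track$side, h)
  ci <- crop_indices(cx, track$side, w)
  crop <- if (length(d) == 3) frame[ri, ci, , drop = FALSE]
          else frame[ri, ci, drop = FALSE]
  resize_image(crop, out_size, out_size)
}

#' Radial "approximation" distortion for the mouth region
#'
#' Magnifies the area inside `radius` of `center` so the face appears closer
#' to the camera: an output pixel at distance `r < radius` samples the input
#' at `r * (1 - strength * (1 - r/radius))` along the same ray (inverse
#' mapping, bilinear). Pixels at `r >= radius` are untouched.
#'
#' @param crop square image (`H x W` or `H x W x C`)
#' @param center `(x, y)` distortion centre, 0-based pixels within the crop
#' @param radius distortion radius, pixels (> 0)
#' @param strength magnification strength, >= 0 (0 is the identity)
#' @return distorted image, same size
#' @export
mouth_distortion <- function(crop, center, radius, strength = 0.3) {
  if (radius <= 0) stop_cfg("radius must be > 0")
  if (strength < 0) stop_cfg("strength must be >= 0")
  if (strength == 0) return(crop)
  d <- dim(crop)
  h <- d[1]; w <- d[2]
  xs <- matrix(rep(0:(w - 1), each = h), h, w)
  ys <- matrix(rep(0:(h - 1), w), h, w)
  dx <- xs - center[1]; dy <- ys - center[2]
  r <- sqrt(dx * dx + dy * dy)
  inside <- r < radius & r > 0
  scale <- rep(1, length(r)); dim(scale) <- dim(r)
  scale[inside] <- 1 - strength * (1 - r[inside] / radius)
  sx <- clamp(center[1] + dx * scale, 0, w - 1)
  sy <- clamp(center[2] + dy * scale, 0, h - 1)
  x0 <- floor(sx); y0 <- floor(sy)
  fx <- sx - x0; fy <- sy - y0
  x1 <- pmin(x0 + 1, w - 1); y1 <- pmin(y0 + 1, h - 1)
  sample_plane <- function(m) {
    g <- function(yy, xx) m[cbind(as.vector(yy) + 1, as.vector(xx) + 1)]
    v <- g(y0, x0) * (1 - fx) * (1 - fy) + g(y0, x1) * fx * (1 - fy) +
         g(y1, x0) * (1 - fx) * fy + g(y1, x1) * fx * fy
    matrix(v, h, w)
  }
  if (length(d) == 3) {
    out <- crop
    for (c in seq_len(d[3])) out[, , c] <- sample_plane(crop[, , c])
    out
  } else sample_plane(crop)
}

# ROI side lengths from one landmark frame. The eyes use a multiple of the
# landmark bounding-box diagonal; the lower face spans from the mouth centre
# up to just below the eye line (so all sides scale with apparent face size
# and the 5% threshold follows camera distance).
roi_sides <- function(lm, eye_scale) {
  diag_of <- function(p) {
    sqrt(diff(range(p[, 1]))^2 + diff(range(p[, 2]))^2)
  }
  eye_line <- (compute_center(lm$left_eye)[2] + compute_center(lm$right_eye)[2]) / 2
  mouth_c <- compute_center(lm$mouth)
  lf_side <- 2 * 0.9 * max(mouth_c[2] - eye_line, 1)
  list(left_eye = max(eye_scale * diag_of(lm$left_eye), 4),
       right_eye = max(eye_scale * diag_of(lm$right_eye), 4),
       lower_face = lf_side)
}

#' Stream a video through the stabilized ROI extractor
#'
#' Processes one frame at a time (constant memory in the video length). On a
#' landmark-detection failure (a `NULL` entry in the landmark stream) the
#' last detected coordinates are kept; when failures occur on
#' `max_consecutive_failures` consecutive frames, processing aborts with a
#' diagnostic naming the offending frame. Exported file names encode the
#' source-frame index; RGB frames are written as PNG and single-channel
#' frames as PGM.
#'
#' @param frames list of image arrays, or a function `(i) -> frame` for true
#'   streaming
#' @param landmark_stream list of landmark frames (entries may be `NULL` to
#'   signal a detection failure)
#' @param config an [extractor_config()]
#' @param n_frames number of frames (required when `frames` is a function)
#' @param out_dir if non-`NULL`, write `<roi>/<roi>_<index>.png|pgm` below it
#' @param on_frame optional callback `function(index, crops)` receiving the
#'   named list of ROI crops for each frame (used for in-memory pipelines)
#' @param keep_frames if `TRUE`, accumulate and return all crops (memory
#'   grows with video length; meant for short clips)
#' @return list with `log` (data frame: frame, roi, cx, cy, d, moved) and,
#'   when `keep_frames`, `crops` (per-ROI lists of images)
#' @export
process_video <- function(frames, landmark_stream, config = extractor_config(),
                          n_frames = NULL, out_dir = NULL, on_frame = NULL,
                          keep_frames = FALSE) {
  get_frame <- if (is.function(frames)) frames else function(i) frames[[i]]
  n <- n_frames %||% length(frames)
  if (!is.function(frames) && length(landmark_stream) != n)
    stop_cfg("frame and landmark streams differ in length")
  roi_names <- c("left_eye", "right_eye", "lower_face")
  out_sizes <- c(left_eye = config$eye_out, right_eye = config$eye_out,
                 lower_face = config$mouth_out)
  if (!is.null(out_dir))
    for (rn in roi_names)
      dir.create(file.path(out_dir, rn), recursive = TRUE, showWarnings = FALSE)
  tracks <- NULL
  last_lm <- NULL
  fail_run <- 0L
  log_rows <- vector("list", n)
  crops_all <- if (keep_frames)
    stats::setNames(lapply(roi_names, function(x) vector("list", n)), roi_names)
  for (i in seq_len(n)) {
    lm <- landmark_stream[[i]]
    if (is.null(lm)) {
      fail_run <- fail_run + 1L
      if (is.null(last_lm))
        stop_cfg("landmark detection failed on the first frame")
      if (fail_run >= config$max_consecutive_failures)
        stop_cfg("landmark detection failed on %d consecutive frames (last: frame %d)",
                 fail_run, i - 1L)
      lm <- last_lm
    } else {
      fail_run <- 0L
      last_lm <- lm
    }
    centers <- list(left_eye = compute_center(lm$left_eye),
                    right_eye = compute_center(lm$right_eye),
                    lower_face = compute_center(lm$mouth))
    if (is.null(tracks)) {
      sides <- roi_sides(lm, config$eye_scale)
      tracks <- lapply(roi_names, function(rn)
        roi_track(rn, centers[[rn]], sides[[rn]]))
      names(tracks) <- roi_names
      moved_d <- lapply(roi_names, function(rn) c(moved = TRUE, d = 0))
    }
    frame <- get_frame(i)
    if (is.null(frame)) stop_cfg("frame %d is unreadable", i - 1L)
    if (config$grayscale && length(dim(frame)) == 3) frame <- rgb_to_gray(frame)
    crops <- list()
    for (rn in roi_names) {
      tracks[[rn]] <- update_center(tracks[[rn]], centers[[rn]],
                                    config$update_mode)
      crop <- crop_roi(frame, tracks[[rn]], out_sizes[[rn]])
      if (rn == "lower_face" && config$distortion_strength > 0) {
        # distortion centre/radius in output-crop coordinates
        sc <- out_sizes[[rn]] / tracks[[rn]]$side
        mc <- (centers$lower_face - tracks[[rn]]$center) * sc +
              (out_sizes[[rn]] - 1) / 2
        nose_c <- compute_center(lm$nose)
        radius <- max(center_distance(centers$lower_face, nose_c) * sc, 1)
        crop <- mouth_distortion(crop, mc, radius, config$distortion_strength)
      }
      crops[[rn]] <- crop
      log_rows[[i]] <- rbind(log_rows[[i]], data.frame(
        frame = i - 1L, roi = rn,
        cx = tracks[[rn]]$center[1], cy = tracks[[rn]]$center[2],
        d = attr(tracks[[rn]], "d"), moved = attr(tracks[[rn]], "moved")))
      if (!is.null(out_dir)) {
        if (length(dim(crop)) == 3)
          write_png(crop, file.path(out_dir, rn,
                                    sprintf("%s_%06d.png", rn, i - 1L)))
        else
          write_pgm(crop, file.path(out_dir, rn,
                                    sprintf("%s_%06d.pgm", rn, i - 1L)))
      }
      if (keep_frames) crops_all[[rn]][[i]] <- crop
    }
    if (!is.null(on_frame)) on_frame(i - 1L, crops)
  }
  log <- do.call(rbind, log_rows)
  if (!is.null(out_dir))
    utils::write.csv(log, file.path(out_dir, "track_log.csv"),
                     row.names = FALSE)
  res <- list(log = log)
  if (keep_frames) res$crops <- crops_all
  res
}
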
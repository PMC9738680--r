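# PPG traces, frame-rate rescaling and PPG -> BPM conversion.
#
# The BPM converter re-specifies what a heart-rate analysis library would do:
# band-pass the waveform to the plausible pulse band (0.75--4 Hz), detect
# beats as local maxima above an adaptive threshold (rolling mean + 0.5
# rolling SD over 2 s) with a refractory period of 60/240 s, and report
# 60 / median inter-beat interval per analysis window. The median makes a
# single missed or spurious peak inconsequential.

#' A uniformly sampled PPG waveform
#'
#' @param samples numeric amplitude series (>= 2 samples)
#' @param fs sampling rate in Hz
#' @return object of class `ppg_trace`
#' @export
ppg_trace <- function(samples, fs) {
  if (!is_scalar_num(fs) || fs <= 0) stop_cfg("fs must be > 0")
  if (length(samples) < 2) stop_cfg("a PPG trace needs at least 2 samples")
  structure(list(samples = as.numeric(samples), fs = fs), class = "ppg_trace")
}

#' @export
print.ppg_trace <- function(x, ...) {
  cat(sprintf("PPG trace: %d samples at %g Hz (%.1f s)\n",
              length(x$samples), x$fs, length(x$samples) / x$fs))
  invisible(x)
}

#' Rescale a frame (or sample) sequence to a new rate
#'
#' Nearest-frame selection without blending: output element `i` (0-based) is
#' input element `floor(i * src / dst)`. The output length is
#' `round(n * dst / src)`.
#'
#' @param frames list (video frames) or numeric vector (samples)
#' @param src_fps,dst_fps source and target rates in Hz
#' @return sequence of the same kind at the target rate
#' @export
resample_fps <- function(frames, src_fps, dst_fps = 30) {
  if (!is_scalar_num(src_fps) || src_fps <= 0) stop_cfg("src_fps must be > 0")
  n <- length(frames)
  n_out <- round(n * dst_fps / src_fps)
  idx <- pmin(floor((seq_len(n_out) - 1) * src_fps / dst_fps + 1e-9) + 1, n)
  frames[idx]
}

#' Zero out spectral components outside a frequency band
#'
#' FFT band-pass with a hard mask: bins whose (two-sided) frequency magnitude
#' lies outside `[f_lo, f_hi]` are zeroed, including DC. Applying the mask
#' twice equals applying it once.
#'
#' @param x numeric series
#' @param fs sampling rate in Hz
#' @param f_lo,f_hi band edges in Hz (inclusive)
#' @return filtered series (real)
#' @export
fft_bandpass <- function(x, fs, f_lo = 0.75, f_hi = 4) {
  n <- length(x)
  fr <- (seq_len(n) - 1) * fs / n
  fr <- pmin(fr, fs - fr)             # two-sided frequency magnitude
  X <- stats::fft(x)
  X[fr < f_lo | fr > f_hi] <- 0
  Re(stats::fft(X, inverse = TRUE)) / n
}

# rolling mean / SD with partial windows at the edges (cumsum based)
rolling_stats <- function(x, w) {
  n <- length(x)
  half <- max(1L, floor(w / 2))
  cs <- cumsum(c(0, x))
  cs2 <- cumsum(c(0, x * x))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  cnt <- hi - lo + 1
  mu <- (cs[hi + 1] - cs[lo]) / cnt
  va <- pmax((cs2[hi + 1] - cs2[lo]) / cnt - mu * mu, 0)
  list(mean = mu, sd = sqrt(va))
}

# local maxima above a threshold with a minimum spacing (greedy by height)
detect_peaks <- function(x, thr, min_dist) {
  n <- length(x)
  if (n < 3) return(integer(0))
  cand <- which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n]) + 1L
  cand <- cand[x[cand] > thr[cand]]
  if (!length(cand)) return(integer(0))
  cand <- cand[order(-x[cand])]
  keep <- integer(0)
  for (i in cand)
    if (!length(keep) || all(abs(keep - i) >= min_dist)) keep <- c(keep, i)
  sort(keep)
}

#' Convert a PPG trace to a heart-rate series
#'
#' Sliding windows; in each window the trace is band-passed to 0.75--4 Hz,
#' beats are detected as thresholded local maxima at least 60/240 s apart and
#' the window BPM is 60 / median inter-beat interval. Windows with fewer than
#' 3 peaks, or a BPM outside `[30, 250]`, are marked invalid.
#'
#' @param trace a [ppg_trace()]
#' @param window_s analysis window length in seconds
#' @param stride_s window stride in seconds
#' @return data frame with columns `time` (window centre, s), `bpm`, `valid`
#' @export
ppg_to_bpm <- function(trace, window_s = 8, stride_s = 1) {
  stopifnot(inherits(trace, "ppg_trace"))
  fs <- trace$fs
  x <- trace$samples
  wn <- round(window_s * fs)
  if (wn > length(x)) stop_cfg("trace shorter than one analysis window")
  st <- max(1L, round(stride_s * fs))
  starts <- seq(1L, length(x) - wn + 1L, by = st)
  min_dist <- max(1L, round(fs * 60 / 240))
  out <- data.frame(time = numeric(0), bpm = numeric(0), valid = logical(0))
  for (s in starts) {
    xwin <- x[s:(s + wn - 1L)]
    seg <- fft_bandpass(xwin, fs)
    # a (near-)flat window carries no pulse; the relative guard keeps the
    # conversion invariant to positive rescaling of the trace
    flat <- stats::sd(xwin) == 0 || stats::sd(seg) < 1e-9 * stats::sd(xwin)
    rs <- rolling_stats(seg, round(2 * fs))
    pk <- if (flat) integer(0)
          else detect_peaks(seg, rs$mean + 0.5 * rs$sd, min_dist)
    bpm <- NA_real_
    ok <- FALSE
    if (length(pk) >= 3) {
      ibi <- stats::median(diff(pk)) / fs
      bpm <- 60 / ibi
      ok <- is.finite(bpm) && bpm >= 30 && bpm <= 250
    }
    out <- rbind(out, data.frame(time = (s - 1 + wn / 2) / fs, bpm = bpm,
                                 valid = ok))
  }
  out
}

#' Summarize a BPM series as a single heart rate
#'
#' @param bpm_series output of [ppg_to_bpm()]
#' @return median BPM over valid windows (NA if none)
#' @export
summarize_bpm <- function(bpm_series) {
  v <- bpm_series$bpm[bpm_series$valid]
  if (!length(v)) return(NA_real_)
  stats::median(v)
}
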
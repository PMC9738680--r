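# Causal Eulerian motion magnification.
#
# Each frame is decomposed into a Gaussian pyramid, every level is filtered
# temporally with a causal recursive band-pass (the difference of two
# first-order low-pass filters with cutoffs f_lo and f_hi, so no future
# frames are used), and alpha times the filtered component is added back
# before collapsing the pyramid. Chrominance/colour amplification is not
# used: the same spatial band-pass is applied to all channels, amplifying
# motion, and with alpha = 0 the stream is returned unchanged.

#' Magnification configuration
#'
#' @param amplification gain alpha applied to the band-passed motion
#'   component (>= 0; 0 disables)
#' @param band numeric `(f_lo, f_hi)` temporal pass band in Hz
#' @param levels number of pyramid levels (>= 1)
#' @return object of class `magnify_config`
#' @export
magnify_config <- function(amplification = 10, band = c(0.5, 4), levels = 4) {
  if (amplification < 0) stop_cfg("amplification must be >= 0")
  if (length(band) != 2 || band[1] < 0 || band[1] >= band[2])
    stop_cfg("band must satisfy 0 <= f_lo < f_hi")
  if (levels < 1) stop_cfg("levels must be >= 1")
  structure(list(amplification = amplification, band = band,
                 levels = as.integer(levels)),
            class = "magnify_config")
}

# one-pole low-pass smoothing coefficient for cutoff f at sample rate fs
iir_alpha <- function(f, fs) 1 - exp(-2 * pi * f / fs)

#' Apply causal Eulerian motion magnification to a frame stream
#'
#' @param frames list of image arrays (`H x W x C` or `H x W`)
#' @param fps frame rate in Hz
#' @param config a [magnify_config()]
#' @return list of magnified frames, same length and sizes
#' @export
magnify_stream <- function(frames, fps, config = magnify_config()) {
  stopifnot(inherits(config, "magnify_config"))
  if (config$band[2] > fps / 2)
    stop_cfg("band upper edge %.3g Hz exceeds the Nyquist rate %.3g Hz",
             config$band[2], fps / 2)
  if (config$amplification == 0) return(frames)
  a_lo <- iir_alpha(config$band[1], fps)
  a_hi <- iir_alpha(config$band[2], fps)
  state <- NULL   # per level: two low-pass accumulators
  out <- vector("list", length(frames))
  for (k in seq_along(frames)) {
    fr <- frames[[k]]
    d <- dim(fr)
    # Gaussian pyramid (levels limited by frame size)
    pyr <- list(fr)
    for (l in seq_len(config$levels - 1L)) {
      prev <- pyr[[l]]
      if (min(dim(prev)[1:2]) < 8) break
      pyr[[l + 1]] <- pyr_down(prev)
    }
    if (is.null(state))
      state <- lapply(pyr, function(p) list(y1 = p, y2 = p))
    add <- 0
    for (l in rev(seq_along(pyr))) {
      st <- state[[l]]
      st$y1 <- st$y1 + a_hi * (pyr[[l]] - st$y1)
      st$y2 <- st$y2 + a_lo * (pyr[[l]] - st$y2)
      state[[l]] <- st
      bp <- st$y1 - st$y2          # band-passed component of this level
      add <- if (identical(dim(bp)[1:2], d[1:2])) add + bp
             else add + pyr_up(bp, d[1], d[2])
    }
    out[[k]] <- fr + config$amplification * add
  }
  out
}
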
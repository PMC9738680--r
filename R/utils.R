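#' @keywords internal
#' @useDynLib hmdrppg, .registration = TRUE
#' @importFrom Rcpp evalCpp
"_PACKAGE"

# ---- small shared helpers ----------------------------------------------

#' Derive a per-module seed from a single run seed
#'
#' A single user-facing seed fans out deterministically to sub-seeds for the
#' scene generator, landmark noise, weight initialization, dropout, etc.
#' The result is always a valid 32-bit integer seed.
#'
#' @param seed integer run seed
#' @param tag character label naming the consumer
#' @return an integer in `[0, 2^31 - 1)`
#' @export
derive_seed <- function(seed, tag) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(tag))
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
  as.integer((abs(seed) * 7919 + h * 104729 + 13) %% 2147483611)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

is_scalar_num <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

stop_cfg <- function(...) stop(sprintf(...), call. = FALSE)

# ---- image primitives ---------------------------------------------------
# Images are numeric arrays H x W (grayscale) or H x W x C, values on [0, 1].
# Coordinates are 0-based (x to the right, y down); pixel (x, y) lives at
# array index [y + 1, x + 1].

#' Resize an image by bilinear or nearest-neighbour interpolation
#'
#' Uses half-pixel centre alignment, so resizing to the original size is the
#' identity and constant images stay constant.
#'
#' @param img numeric array `H x W` or `H x W x C`
#' @param out_h,out_w output size in pixels
#' @param method `"bilinear"` (default) or `"nearest"`
#' @return resized array with the same number of channels
#' @export
resize_image <- function(img, out_h, out_w, method = c("bilinear", "nearest")) {
  method <- match.arg(method)
  d <- dim(img)
  h <- d[1]; w <- d[2]
  nc <- if (length(d) == 3) d[3] else 1L
  if (h == out_h && w == out_w) return(img)
  # source coordinates (0-based, half-pixel centres)
  sy <- clamp((seq_len(out_h) - 0.5) * h / out_h - 0.5, 0, h - 1)
  sx <- clamp((seq_len(out_w) - 0.5) * w / out_w - 0.5, 0, w - 1)
  if (method == "nearest") {
    iy <- pmin(floor(sy + 0.5) + 1, h)
    ix <- pmin(floor(sx + 0.5) + 1, w)
    out <- if (nc == 1L && length(d) == 2) img[iy, ix, drop = FALSE]
           else img[iy, ix, , drop = FALSE]
    return(out)
  }
  y0 <- floor(sy); x0 <- floor(sx)
  fy <- sy - y0;  fx <- sx - x0
  y0 <- y0 + 1; x0 <- x0 + 1
  y1 <- pmin(y0 + 1, h); x1 <- pmin(x0 + 1, w)
  ch <- function(m) {
    a <- m[y0, x0, drop = FALSE] * ((1 - fy) %o% (1 - fx)) +
         m[y1, x0, drop = FALSE] * (fy %o% (1 - fx)) +
         m[y0, x1, drop = FALSE] * ((1 - fy) %o% fx) +
         m[y1, x1, drop = FALSE] * (fy %o% fx)
    a
  }
  if (length(d) == 2) return(ch(img))
  out <- array(0, c(out_h, out_w, nc))
  for (c in seq_len(nc)) out[, , c] <- ch(img[, , c])
  out
}

# 5-tap binomial blur [1 4 6 4 1]/16, separable, edge replication
blur5 <- function(m) {
  k <- c(1, 4, 6, 4, 1) / 16
  h <- nrow(m); w <- ncol(m)
  ri <- function(i, n) clamp(i, 1L, n)
  acc <- 0
  for (o in -2:2) acc <- acc + k[o + 3] * m[ri(seq_len(h) + o, h), , drop = FALSE]
  m2 <- acc
  acc <- 0
  for (o in -2:2) acc <- acc + k[o + 3] * m2[, ri(seq_len(w) + o, w), drop = FALSE]
  acc
}

blur_image <- function(img) {
  d <- dim(img)
  if (length(d) == 2) return(blur5(img))
  out <- img
  for (c in seq_len(d[3])) out[, , c] <- blur5(img[, , c])
  out
}

# blur then keep every other row/column (1, 3, 5, ...): n -> ceiling(n/2)
pyr_down <- function(img) {
  b <- blur_image(img)
  d <- dim(b)
  ri <- seq(1, d[1], by = 2); ci <- seq(1, d[2], by = 2)
  if (length(d) == 2) b[ri, ci, drop = FALSE] else b[ri, ci, , drop = FALSE]
}

pyr_up <- function(img, out_h, out_w) resize_image(img, out_h, out_w)

#' Convert an RGB image to grayscale (Rec. 601 luma)
#' @param img `H x W x 3` array
#' @return `H x W` matrix
#' @export
rgb_to_gray <- function(img) {
  stopifnot(length(dim(img)) == 3, dim(img)[3] == 3)
  0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
}
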
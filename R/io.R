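# Frame and trace input/output.
#
# Exported frames follow the HMD extractor convention: RGB frames are written
# as PNG ("Portable Network Graphics", visible-light sensor) and single
# channel frames as PGM ("Portable Gray Image", infrared sensor). Binary PPM
# and PGM round-trip through the readers below; PNG is write-only (8-bit
# truecolour, filter 0) since nothing downstream re-reads it.

to_u8 <- function(x) {
  v <- as.integer(round(clamp(x, 0, 1) * 255))
  dim(v) <- dim(x)
  v
}

#' Write a grayscale image as binary PGM (P5)
#' @param img `H x W` matrix on `[0, 1]`
#' @param path output file
#' @export
write_pgm <- function(img, path) {
  stopifnot(is.matrix(img))
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(c("P5", paste(ncol(img), nrow(img)), "255"), con)
  writeBin(as.raw(t(to_u8(img))), con)
  invisible(path)
}

#' Write an RGB image as binary PPM (P6)
#' @param img `H x W x 3` array on `[0, 1]`
#' @param path output file
#' @export
write_ppm <- function(img, path) {
  stopifnot(length(dim(img)) == 3, dim(img)[3] == 3)
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(c("P6", paste(dim(img)[2], dim(img)[1]), "255"), con)
  px <- aperm(to_u8(img), c(3, 2, 1))  # interleave RGB, row-major
  writeBin(as.raw(px), con)
  invisible(path)
}

read_pnm_header <- function(con) {
  tok <- character(0)
  while (length(tok) < 4) {
    line <- readLines(con, n = 1)
    line <- sub("#.*", "", line)
    tok <- c(tok, strsplit(trimws(line), "\\s+")[[1]])
  }
  tok
}

#' Read a binary PGM or PPM image
#' @param path file written by [write_pgm()] or [write_ppm()]
#' @return matrix (PGM) or `H x W x 3` array (PPM) on `[0, 1]`
#' @export
read_pnm <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  tok <- read_pnm_header(con)
  magic <- tok[1]
  w <- as.integer(tok[2]); h <- as.integer(tok[3])
  if (magic == "P5") {
    v <- as.integer(readBin(con, "raw", n = w * h)) / 255
    return(t(matrix(v, nrow = w, ncol = h)))
  }
  if (magic == "P6") {
    v <- as.integer(readBin(con, "raw", n = 3 * w * h)) / 255
    return(aperm(array(v, c(3, w, h)), c(3, 2, 1)))
  }
  stop_cfg("unsupported PNM magic '%s' in %s", magic, path)
}

# ---- minimal PNG encoder -------------------------------------------------
# 8-bit RGB, no interlace, filter type 0 on every scanline. The zlib stream
# is obtained from R's gzip compressor by re-wrapping the raw deflate data
# with a zlib header and an Adler-32 checksum.

crc32_table <- local({
  tab <- NULL
  function() {
    if (is.null(tab)) {
      t <- integer(256)
      for (n in 0:255) {
        c <- n
        for (k in 1:8)
          c <- if (bitwAnd(c, 1L) != 0L)
            bitwXor(-306674912L, bitwShiftR(c, 1))  # 0xEDB88320 as signed
          else bitwShiftR(c, 1)
        t[n + 1] <- c
      }
      tab <<- t
    }
    tab
  }
})

crc32 <- function(bytes) {
  tab <- crc32_table()
  crc <- -1L
  for (b in as.integer(bytes)) {
    idx <- bitwAnd(bitwXor(crc, b), 255L)
    crc <- bitwXor(tab[idx + 1], bitwShiftR(crc, 8))
  }
  bitwXor(crc, -1L)
}

u32_be <- function(x) {
  x <- as.numeric(x) %% 4294967296
  as.raw(c(x %/% 16777216, (x %/% 65536) %% 256, (x %/% 256) %% 256, x %% 256))
}

adler32 <- function(bytes) {
  v <- as.integer(bytes)
  a <- 1; b <- 0
  # process in chunks so the running sums stay in double precision range
  step <- 4096
  for (i in seq(1, length(v), by = step)) {
    ch <- v[i:min(i + step - 1, length(v))]
    for (x in ch) { a <- a + x; b <- b + a }
    a <- a %% 65521; b <- b %% 65521
  }
  (b * 65536 + a)
}

zlib_compress <- function(bytes) {
  gz <- memCompress(bytes, type = "gzip")
  if (gz[1] == as.raw(0x78)) return(gz)        # already a zlib stream
  # gzip-wrapped deflate: re-wrap with a zlib header and Adler-32 trailer
  deflate <- gz[11:(length(gz) - 8)]
  c(as.raw(c(0x78, 0x9c)), deflate, u32_be(adler32(bytes)))
}

png_chunk <- function(type, data) {
  body <- c(charToRaw(type), data)
  c(u32_be(length(data)), body, u32_be(crc32(body)))
}

#' Write an RGB image as PNG
#'
#' Minimal deterministic encoder (8-bit truecolour, no interlace).
#'
#' @param img `H x W x 3` array on `[0, 1]`
#' @param path output file
#' @export
write_png <- function(img, path) {
  stopifnot(length(dim(img)) == 3, dim(img)[3] == 3)
  h <- dim(img)[1]; w <- dim(img)[2]
  px <- aperm(to_u8(img), c(3, 2, 1))          # RGB interleaved, row-major
  dim(px) <- c(3 * w, h)
  scan <- rbind(0L, px)                        # filter byte 0 per scanline
  ihdr <- c(u32_be(w), u32_be(h), as.raw(c(8, 2, 0, 0, 0)))
  out <- c(
    as.raw(c(0x89, 0x50, 0x4e, 0x47, 0x0d, 0x0a, 0x1a, 0x0a)),
    png_chunk("IHDR", ihdr),
    png_chunk("IDAT", zlib_compress(as.raw(scan))),
    png_chunk("IEND", raw(0))
  )
  writeBin(out, path)
  invisible(path)
}

#' Read a PNG written by [write_png()]
#'
#' Supports the encoder's own subset: 8-bit truecolour, no interlace,
#' filter type 0 on every scanline.
#'
#' @param path PNG file
#' @return `H x W x 3` array on `[0, 1]`
#' @export
read_png <- function(path) {
  bytes <- readBin(path, "raw", file.size(path))
  sig <- as.raw(c(0x89, 0x50, 0x4e, 0x47, 0x0d, 0x0a, 0x1a, 0x0a))
  if (!identical(bytes[1:8], sig)) stop_cfg("%s is not a PNG file", path)
  u32 <- function(i) sum(as.integer(bytes[i:(i + 3)]) * c(256^3, 256^2, 256, 1))
  pos <- 9
  w <- h <- NULL
  idat <- raw(0)
  while (pos + 7 <= length(bytes)) {
    len <- u32(pos)
    type <- rawToChar(bytes[(pos + 4):(pos + 7)])
    data_i <- pos + 8
    if (type == "IHDR") {
      w <- u32(data_i); h <- u32(data_i + 4)
      if (bytes[data_i + 8] != as.raw(8) || bytes[data_i + 9] != as.raw(2))
        stop_cfg("read_png only supports 8-bit truecolour (own encoder subset)")
    } else if (type == "IDAT") {
      idat <- c(idat, bytes[data_i:(data_i + len - 1)])
    } else if (type == "IEND") break
    pos <- data_i + len + 4
  }
  scan <- memDecompress(idat, type = "gzip")
  dim(scan) <- c(3 * w + 1, h)
  if (any(scan[1, ] != as.raw(0)))
    stop_cfg("read_png only supports filter type 0 (own encoder subset)")
  px <- as.integer(scan[-1, , drop = FALSE]) / 255
  dim(px) <- c(3, w, h)
  aperm(px, c(3, 2, 1))
}

# ---- ground-truth traces -------------------------------------------------

#' Read a UBFC-style ground-truth file
#'
#' Three whitespace-delimited lines: PPG samples, BPM samples, timestamps
#' in seconds.
#'
#' @param path text file
#' @return list with numeric vectors `ppg`, `bpm`, `time`
#' @export
read_ubfc_trace <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 3) stop_cfg("ground-truth file %s needs 3 lines", path)
  parse <- function(s) as.numeric(strsplit(trimws(s), "\\s+")[[1]])
  list(ppg = parse(lines[1]), bpm = parse(lines[2]), time = parse(lines[3]))
}

#' Write a UBFC-style ground-truth file
#' @param ppg,bpm,time numeric vectors (equal length)
#' @param path output file
#' @export
write_ubfc_trace <- function(ppg, bpm, time, path) {
  stopifnot(length(ppg) == length(bpm), length(bpm) == length(time))
  fmt <- function(v) paste(formatC(v, format = "g", digits = 10), collapse = " ")
  writeLines(c(fmt(ppg), fmt(bpm), fmt(time)), path)
  invisible(path)
}
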
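# 16-bit grayscale PNG writer for distance-field rasters. The png package
# writes 8-bit only, so the file is assembled directly: IHDR (bit depth 16,
# colour type 0), one IDAT holding a zlib stream of stored-deflate blocks,
# IEND. readPNG handles 16-bit input natively on the way back.

u32be <- function(x) {
  as.raw(c(bitwAnd(bitwShiftR(x, 24), 255L), bitwAnd(bitwShiftR(x, 16), 255L),
           bitwAnd(bitwShiftR(x, 8), 255L), bitwAnd(x, 255L)))
}

pngChunk <- function(type, data) {
  body <- c(charToRaw(type), data)
  c(u32be(length(data)), body, as.raw(cpp_crc32(body)))
}

adler32 <- function(raw) {
  MOD <- 65521
  x <- as.integer(raw)
  a <- 1L; b <- 0L
  # process in blocks to avoid integer overflow (5552 is the zlib block size)
  i <- 1L; n <- length(x)
  while (i <= n) {
    j <- min(n, i + 5551L)
    seg <- x[i:j]
    cs <- cumsum(seg)
    b <- (b + length(seg) * a + sum(cs %% MOD)) %% MOD
    a <- (a + cs[length(cs)]) %% MOD
    i <- j + 1L
  }
  bitwOr(bitwShiftL(b, 16), a)
}

zlibStored <- function(data) {
  n <- length(data)
  blocks <- list(as.raw(c(0x78, 0x01)))
  i <- 1L
  repeat {
    len <- min(65535L, n - i + 1L)
    final <- if (i + len - 1L >= n) as.raw(1) else as.raw(0)
    blocks[[length(blocks) + 1L]] <- c(
      final,
      as.raw(c(bitwAnd(len, 255L), bitwShiftR(len, 8))),
      as.raw(c(bitwAnd(bitwXor(len, 65535L), 255L),
               bitwShiftR(bitwXor(len, 65535L), 8))),
      data[i:(i + len - 1L)])
    i <- i + len
    if (i > n) break
  }
  blocks[[length(blocks) + 1L]] <- u32be(adler32(data))
  do.call(c, blocks)
}

#' Write a distance field as a 16-bit grayscale PNG
#'
#' Values are clipped to \code{[0, 1]} and stored as
#' \code{round(F * 65535)}.
#'
#' @param field numeric matrix in \code{[0, 1]} (rows = image rows).
#' @param path output file.
#' @return \code{path}, invisibly.
#' @seealso [readFieldPNG()]
#' @export
writeFieldPNG <- function(field, path) {
  stopifnot(is.matrix(field))
  v <- round(pmin(pmax(field, 0), 1) * 65535)
  H <- nrow(field); W <- ncol(field)
  # PNG scanlines are rows; 2 bytes per sample big-endian, filter byte 0
  vi <- as.integer(t(v))                      # row-major
  hi <- as.raw(vi %/% 256L); lo <- as.raw(vi %% 256L)
  samples <- as.raw(rbind(hi, lo))            # interleave hi/lo
  dim(samples) <- NULL
  scan <- matrix(samples, nrow = 2L * W)
  raw_rows <- rbind(as.raw(0), scan)
  ihdr <- c(u32be(W), u32be(H), as.raw(c(16, 0, 0, 0, 0)))
  out <- c(as.raw(c(0x89, 0x50, 0x4E, 0x47, 0x0D, 0x0A, 0x1A, 0x0A)),
           pngChunk("IHDR", ihdr),
           pngChunk("IDAT", zlibStored(as.vector(raw_rows))),
           pngChunk("IEND", raw(0)))
  writeBin(out, path)
  invisible(path)
}

#' Read a 16-bit field PNG back to a numeric matrix in [0, 1]
#' @param path PNG file written by [writeFieldPNG()].
#' @return numeric matrix.
#' @export
readFieldPNG <- function(path) {
  m <- png::readPNG(path)
  if (length(dim(m)) == 3L) m <- m[, , 1L]
  m
}
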
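#' Read a 16-bit grayscale PNG as an integer matrix
#'
#' Raw captures are 12-bit data stored losslessly in 16-bit single-channel
#' PNG containers. Values are returned as integers on the stored 16-bit code
#' scale (0--65535); 12-bit data therefore occupy 0--4095.
#'
#' @param path path to a PNG file.
#' @param max12bit if \code{TRUE} (default), error when any value exceeds
#'   4095, i.e. the file is not 12-bit data in a 16-bit container.
#' @return integer matrix (rows = image rows).
#' @export
readPNG16 <- function(path, max12bit = TRUE) {
  img <- png::readPNG(path, info = TRUE)
  info <- attr(img, "info")
  if (length(dim(img)) != 2L)
    stop("expected a single-channel grayscale PNG: ", path)
  bits <- 16L
  if (!is.null(info) && !is.null(info$bit.depth)) bits <- info$bit.depth
  if (bits != 16L)
    stop("expected 16-bit PNG, got ", bits, "-bit: ", path)
  m <- round(img * 65535)
  if (max12bit && any(m > 4095))
    stop("pixel values exceed the 12-bit range in: ", path)
  storage.mode(m) <- "integer"
  attr(m, "info") <- NULL
  m
}

#' Write an integer matrix as a 16-bit grayscale PNG
#'
#' Minimal lossless PNG encoder (deflate via \code{memCompress}, CRC32 via
#' \pkg{digest}); written files round-trip exactly through
#' \code{\link{readPNG16}}.
#'
#' @param image integer matrix, values in 0--65535.
#' @param path output file path.
#' @return invisibly, \code{path}.
#' @export
writePNG16 <- function(image, path) {
  if (any(image < 0 | image > 65535))
    stop("pixel values out of the 16-bit range")
  m <- matrix(as.integer(round(image)), nrow(image), ncol(image))
  h <- nrow(m); w <- ncol(m)
  # scanlines: filter byte 0 + big-endian 16-bit samples, row-major
  hi <- as.raw(m %/% 256L)
  lo <- as.raw(m %% 256L)
  scan <- raw(h * (1L + 2L * w))
  rowstart <- (seq_len(h) - 1L) * (1L + 2L * w)
  scan[rowstart + 1L] <- as.raw(0L)
  # interleave hi/lo per row; matrices are column-major so index explicitly
  colidx <- rep(seq_len(w), each = 1L)
  for (r in seq_len(h)) {
    o <- rowstart[r] + 1L
    scan[o + 2L * seq_len(w) - 1L] <- hi[r + h * (colidx - 1L)]
    scan[o + 2L * seq_len(w)] <- lo[r + h * (colidx - 1L)]
  }
  u32 <- function(x) as.raw(c(x %/% 16777216, x %/% 65536, x %/% 256, x) %% 256)
  chunk <- function(type, data) {
    body <- c(charToRaw(type), data)
    hex <- digest::digest(body, algo = "crc32", serialize = FALSE)
    hex <- formatC(hex, width = 8, flag = "0")
    crc <- sum(strtoi(substring(hex, c(1, 3, 5, 7), c(2, 4, 6, 8)), 16L) *
                 c(16777216, 65536, 256, 1))
    c(u32(length(data)), body, u32(crc))
  }
  ihdr <- c(u32(w), u32(h), as.raw(c(16L, 0L, 0L, 0L, 0L)))
  idat <- memCompress(scan, type = "gzip")  # zlib stream per the PNG spec
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.raw(c(137, 80, 78, 71, 13, 10, 26, 10)), con)
  writeBin(chunk("IHDR", ihdr), con)
  writeBin(chunk("IDAT", idat), con)
  writeBin(chunk("IEND", raw(0)), con)
  invisible(path)
}
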
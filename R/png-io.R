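# Minimal PNG I/O on top of base R's zlib bindings.
#
# The pipeline needs to persist 8-bit RGB frames and 8-bit grayscale masks
# and read them back; no image-I/O package is part of this package's
# dependency contract, so a small self-contained codec is provided.
# Scope: 8-bit depth, color types 0 (gray) and 2 (RGB), no interlacing.
# The writer always emits filter type 0 (None); the reader additionally
# understands filter types 1-4 so files from mainstream encoders with
# these properties also load.

png_magic <- as.raw(c(0x89, 0x50, 0x4e, 0x47, 0x0d, 0x0a, 0x1a, 0x0a))

u32_to_raw <- function(x) {
  x <- as.numeric(x)
  as.raw(c(x %/% 16777216, (x %/% 65536) %% 256, (x %/% 256) %% 256, x %% 256))
}

raw_to_u32 <- function(r) {
  sum(as.numeric(r) * c(16777216, 65536, 256, 1))
}

# CRC-32 (ISO 3309) of a raw vector. A pure-R byte loop is too slow for
# megabyte chunks, so zlib's C implementation is borrowed via the gzip
# file format: the last 8 trailer bytes of a .gz member are CRC32 and
# ISIZE of the uncompressed data, both little-endian.
crc32 <- function(bytes) {
  tf <- tempfile(fileext = ".gz")
  on.exit(unlink(tf))
  con <- gzfile(tf, "wb")
  writeBin(bytes, con)
  close(con)
  sz <- file.size(tf)
  fc <- file(tf, "rb")
  on.exit(close(fc), add = TRUE)
  seek(fc, sz - 8)
  crc_le <- readBin(fc, "raw", n = 4)
  sum(as.numeric(crc_le) * c(1, 256, 65536, 16777216))
}

png_chunk <- function(type, data) {
  type_raw <- charToRaw(type)
  payload <- c(type_raw, data)
  c(u32_to_raw(length(data)), payload, u32_to_raw(crc32(payload)))
}

#' Write an 8-bit PNG image
#'
#' @param image either a `height x width` matrix (grayscale) or a
#'   `height x width x 3` array (RGB) of values in 0..255.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_png <- function(image, path) {
  d <- dim(image)
  if (is.matrix(image)) {
    h <- d[1]; w <- d[2]; channels <- 1L; color_type <- 0L
  } else if (length(d) == 3 && d[3] == 3) {
    h <- d[1]; w <- d[2]; channels <- 3L; color_type <- 2L
  } else {
    stopf("write_png: image must be a matrix or an H x W x 3 array")
  }
  v <- as.integer(round(image))
  if (anyNA(v) || min(v) < 0L || max(v) > 255L) {
    stopf("write_png: pixel values must be in 0..255")
  }
  # Scanlines: filter byte 0 + row bytes (R arrays are column-major).
  if (channels == 1L) {
    px <- matrix(as.raw(v), h, w)
    rows <- t(px)                          # w x h: column i = scanline i
    stream <- rbind(as.raw(0L), rows)
  } else {
    a <- array(as.raw(v), dim = d)
    interleaved <- matrix(as.raw(0L), nrow = 3L * w, ncol = h)
    interleaved[seq(1L, 3L * w, by = 3L), ] <- t(a[, , 1])
    interleaved[seq(2L, 3L * w, by = 3L), ] <- t(a[, , 2])
    interleaved[seq(3L, 3L * w, by = 3L), ] <- t(a[, , 3])
    stream <- rbind(as.raw(0L), interleaved)
  }
  ihdr <- c(u32_to_raw(w), u32_to_raw(h),
            as.raw(c(8L, color_type, 0L, 0L, 0L)))
  idat <- memCompress(as.raw(stream), type = "gzip")  # zlib stream
  out <- c(png_magic,
           png_chunk("IHDR", ihdr),
           png_chunk("IDAT", idat),
           png_chunk("IEND", raw(0)))
  writeBin(out, path)
  invisible(path)
}

paeth_predict <- function(a, b, c) {
  p <- a + b - c
  pa <- abs(p - a); pb <- abs(p - b); pc <- abs(p - c)
  ifelse(pa <= pb & pa <= pc, a, ifelse(pb <= pc, b, c))
}

#' Read an 8-bit PNG image
#'
#' Supports non-interlaced 8-bit grayscale and RGB files (the subset
#' [write_png()] produces, plus standard filter types 1-4).
#'
#' @param path file path.
#' @return a matrix (grayscale) or H x W x 3 array (RGB) of integers 0..255.
#' @export
read_png <- function(path) {
  bytes <- readBin(path, "raw", n = file.size(path))
  if (length(bytes) < 8 || !identical(bytes[1:8], png_magic)) {
    stopf("read_png: %s is not a PNG file", path)
  }
  pos <- 9L
  idat <- list()
  w <- h <- depth <- color_type <- interlace <- NULL
  while (pos + 7L <= length(bytes)) {
    len <- raw_to_u32(bytes[pos:(pos + 3L)])
    type <- rawToChar(bytes[(pos + 4L):(pos + 7L)])
    data_start <- pos + 8L
    data <- if (len > 0) bytes[data_start:(data_start + len - 1L)] else raw(0)
    if (type == "IHDR") {
      w <- raw_to_u32(data[1:4]); h <- raw_to_u32(data[5:8])
      depth <- as.integer(data[9]); color_type <- as.integer(data[10])
      interlace <- as.integer(data[13])
    } else if (type == "IDAT") {
      idat[[length(idat) + 1L]] <- data
    } else if (type == "IEND") {
      break
    }
    pos <- data_start + len + 4L
  }
  if (is.null(w)) stopf("read_png: missing IHDR")
  if (depth != 8L || !(color_type %in% c(0L, 2L)) || interlace != 0L) {
    stopf("read_png: only non-interlaced 8-bit gray/RGB supported")
  }
  channels <- if (color_type == 0L) 1L else 3L
  raw_stream <- memDecompress(do.call(c, idat), type = "gzip")
  bpr <- w * channels          # bytes per row, excluding the filter byte
  stopifnot(length(raw_stream) == h * (bpr + 1L))
  sl <- matrix(as.integer(raw_stream), nrow = bpr + 1L, ncol = h)
  filters <- sl[1L, ]
  cur <- sl[-1L, , drop = FALSE]   # bpr x h, column = scanline
  recon <- matrix(0L, bpr, h)
  off <- channels                  # "left" pixel offset in bytes
  prev <- integer(bpr)
  for (i in seq_len(h)) {
    x <- cur[, i]
    f <- filters[i]
    if (f == 0L) {
      r <- x
    } else if (f == 2L) {
      r <- (x + prev) %% 256L
    } else {
      r <- integer(bpr)
      for (j in seq_len(bpr)) {
        a <- if (j > off) r[j - off] else 0L
        b <- prev[j]
        cc <- if (j > off) prev[j - off] else 0L
        pred <- switch(as.character(f),
          "1" = a,
          "3" = floor((a + b) / 2),
          "4" = paeth_predict(a, b, cc),
          stopf("read_png: unsupported filter type %d", f))
        r[j] <- (x[j] + pred) %% 256L
      }
    }
    recon[, i] <- r
    prev <- r
  }
  if (channels == 1L) {
    t(matrix(recon, w, h))       # -> h x w
  } else {
    out <- array(0L, dim = c(h, w, 3L))
    for (k in 1:3) {
      out[, , k] <- t(matrix(recon[seq(k, bpr, by = 3L), ], w, h))
    }
    out
  }
}
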
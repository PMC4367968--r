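# Minimal baseline TIFF support (no TIFF package ships with this R stack).
# Covers what eye-surface photographs need: uncompressed, strip-organized,
# 8- or 16-bit grayscale and 8-bit RGB, either byte order. Writing always
# emits little-endian 8-bit grayscale in a single strip.

.tiff_read_raw <- function(path) {
  raw <- readBin(path, "raw", n = file.info(path)$size)
  if (length(raw) < 8L) stop("not a TIFF file: ", path)
  order_mark <- rawToChar(raw[1:2])
  endian <- switch(order_mark, II = "little", MM = "big",
                   stop("not a TIFF file (bad byte-order mark): ", path))
  int_at <- function(off, size, n = 1L) {
    # 4-byte values are read signed (R has no unsigned 32-bit); TIFF
    # offsets in the files this package handles stay far below 2^31
    readBin(raw[(off + 1L):(off + size * n)], "integer",
            n = n, size = size, signed = size == 4L, endian = endian)
  }
  if (int_at(2L, 2L) != 42L) stop("not a TIFF file (bad magic): ", path)
  ifd <- int_at(4L, 4L)
  n_entries <- int_at(ifd, 2L)
  tags <- list()
  for (i in seq_len(n_entries)) {
    e <- ifd + 2L + (i - 1L) * 12L
    tag <- int_at(e, 2L)
    type <- int_at(e + 2L, 2L)
    count <- int_at(e + 4L, 4L)
    tsize <- c(1L, 1L, 2L, 4L)[type]  # BYTE, ASCII, SHORT, LONG
    if (is.na(tsize)) next  # skip RATIONAL etc.
    val_off <- if (tsize * count <= 4L) e + 8L else int_at(e + 8L, 4L)
    tags[[as.character(tag)]] <- int_at(val_off, tsize, count)
  }
  need <- function(tag, default = NULL) {
    v <- tags[[as.character(tag)]]
    if (is.null(v)) {
      if (is.null(default)) stop("TIFF missing required tag ", tag, ": ", path)
      default
    } else v
  }
  width <- need(256); height <- need(257)
  bits <- need(258, 8L); spp <- need(277, 1L)
  compression <- need(259, 1L)
  if (compression != 1L)
    stop("only uncompressed TIFF is supported (compression tag ",
         compression, "): ", path)
  photometric <- need(262, 1L)
  offs <- need(273); counts <- need(279)
  rows_per_strip <- need(278, height)
  if (length(unique(bits)) != 1L)
    stop("mixed bits-per-sample TIFF not supported: ", path)
  bits <- bits[1]
  if (!(spp == 1L && bits %in% c(8L, 16L)) && !(spp == 3L && bits == 8L))
    stop("unsupported TIFF layout (", spp, " samples x ", bits, " bits): ",
         path)

  bytes_per_sample <- bits %/% 8L
  sample_stream <- integer(0)
  for (i in seq_along(offs)) {
    n_samples <- counts[i] %/% bytes_per_sample
    seg <- readBin(raw[(offs[i] + 1L):(offs[i] + counts[i])], "integer",
                   n = n_samples, size = bytes_per_sample,
                   signed = FALSE, endian = endian)
    sample_stream <- c(sample_stream, seg)
  }
  if (length(sample_stream) < width * height * spp)
    stop("TIFF pixel data truncated: ", path)
  sample_stream <- sample_stream[seq_len(width * height * spp)]

  if (spp == 3L) {  # chunky RGB -> luminance (ITU-R BT.601)
    px <- matrix(sample_stream, nrow = 3L)
    gray <- 0.299 * px[1, ] + 0.587 * px[2, ] + 0.114 * px[3, ]
  } else {
    gray <- as.numeric(sample_stream)
    if (bits == 16L) gray <- gray / 65535 * 255
  }
  img <- matrix(gray, nrow = height, ncol = width, byrow = TRUE)
  if (photometric == 0L) img <- 255 - img  # WhiteIsZero
  img
}

.tiff_write_gray8 <- function(pixels, path) {
  pixels <- pmin(pmax(round(pixels), 0), 255)
  height <- nrow(pixels); width <- ncol(pixels)
  data <- as.raw(as.integer(t(pixels)))  # row-major strip
  con <- file(path, "wb")
  on.exit(close(con))
  w2 <- function(x) writeBin(as.integer(x), con, size = 2L, endian = "little")
  w4 <- function(x) writeBin(as.integer(x), con, size = 4L, endian = "little")
  entry <- function(tag, type, count, value) {
    w2(tag); w2(type); w4(count); w4(value)
  }
  data_offset <- 8L
  ifd_offset <- data_offset + length(data)
  writeBin(charToRaw("II"), con); w2(42L); w4(ifd_offset)
  writeBin(data, con)
  w2(9L)  # entry count
  entry(256, 4, 1, width)          # ImageWidth
  entry(257, 4, 1, height)         # ImageLength
  entry(258, 3, 1, 8)              # BitsPerSample
  entry(259, 3, 1, 1)              # Compression = none
  entry(262, 3, 1, 1)              # Photometric = BlackIsZero
  entry(273, 4, 1, data_offset)    # StripOffsets
  entry(277, 3, 1, 1)              # SamplesPerPixel
  entry(278, 4, 1, height)         # RowsPerStrip
  entry(279, 4, 1, length(data))   # StripByteCounts
  w4(0L)  # no next IFD
  invisible(path)
}
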
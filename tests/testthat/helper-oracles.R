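# Independent brute-force oracles used to validate the package kernels.
# These deliberately avoid the package's own algorithms: plain-R
# definition-level computations, vectorized only where the definition
# allows it.

# shift a matrix by (dr, dc), padding with `fill`
shift_mat <- function(m, dr, dc, fill = NA) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  rs <- seq_len(nr) - dr; cs <- seq_len(nc) - dc
  ok_r <- rs >= 1 & rs <= nr; ok_c <- cs >= 1 & cs <= nc
  out[ok_r, ok_c] <- m[rs[ok_r], cs[ok_c]]
  out
}

.offsets8 <- cbind(dr = rep(-1:1, 3), dc = rep(-1:1, each = 3))
.offsets8 <- .offsets8[!(.offsets8[, 1] == 0 & .offsets8[, 2] == 0), ]

# label connected components of a logical mask (8-connectivity, optionally
# only joining pixels of equal value) by iterative minimum-label diffusion
label_components <- function(mask, values = NULL) {
  lab <- matrix(seq_along(mask), nrow(mask), ncol(mask))
  lab[!mask] <- NA
  repeat {
    new_lab <- lab
    for (k in seq_len(nrow(.offsets8))) {
      sh <- shift_mat(lab, .offsets8[k, 1], .offsets8[k, 2])
      ok <- !is.na(sh) & !is.na(new_lab)
      if (!is.null(values)) {
        vsh <- shift_mat(values, .offsets8[k, 1], .offsets8[k, 2])
        ok <- ok & (vsh == values)
      }
      upd <- ok & sh < new_lab
      new_lab[upd] <- sh[upd]
    }
    if (identical(new_lab, lab)) break
    lab <- new_lab
  }
  lab
}

# exhaustive prominence maxima: for every summit plateau, descend the
# threshold ladder until its component touches higher ground (or an
# equal-valued summit of higher priority = smaller minimum linear index);
# prominence = summit - saddle, or summit - min(img) if never connected.
oracle_prominent_maxima <- function(img, tol) {
  nr <- nrow(img); nc <- ncol(img)
  plat <- label_components(matrix(TRUE, nr, nc), values = img)
  higher <- matrix(FALSE, nr, nc)
  for (k in seq_len(nrow(.offsets8))) {
    sh <- shift_mat(img, .offsets8[k, 1], .offsets8[k, 2], fill = -Inf)
    higher <- higher | (sh > img)
  }
  summit_ids <- setdiff(unique(as.vector(plat)),
                        unique(as.vector(plat[higher])))
  if (!length(summit_ids)) return(matrix(numeric(0), 0, 2))
  summits <- lapply(summit_ids, function(id) {
    idx <- which(plat == id)
    rows <- (idx - 1) %% nr + 1; cols <- (idx - 1) %/% nr + 1
    list(id = id, value = img[idx[1]], minidx = min(idx),
         x = floor(mean(cols - 1) + 0.5),  # ties away from zero
         y = floor(mean(rows - 1) + 0.5),
         member = idx)
  })
  vmin <- min(img)
  levels_desc <- sort(unique(as.vector(img)), decreasing = TRUE)
  # per-threshold component labels
  comp_at <- lapply(levels_desc, function(t) label_components(img >= t))
  out <- NULL
  for (s in summits) {
    prom <- s$value - vmin
    for (ti in seq_along(levels_desc)) {
      t <- levels_desc[ti]
      if (t > s$value) next
      lab <- comp_at[[ti]]
      members <- which(lab == lab[s$member[1]])
      conn_higher <- any(img[members] > s$value)
      conn_priority <- any(vapply(summits, function(o)
        o$value == s$value && o$minidx < s$minidx &&
          any(o$member %in% members), logical(1)))
      if (conn_higher || conn_priority) { prom <- s$value - t; break }
    }
    if (prom > tol) out <- rbind(out, c(s$x, s$y))
  }
  if (is.null(out)) matrix(numeric(0), 0, 2) else out
}

# brute-force grayscale opening by a ball element (definition-level loops)
oracle_ball_open <- function(img, radius) {
  nr <- nrow(img); nc <- ncol(img)
  r <- floor(radius)
  off <- expand.grid(dx = -r:r, dy = -r:r)
  off <- off[off$dx^2 + off$dy^2 <= radius^2, ]
  off$h <- sqrt(radius^2 - off$dx^2 - off$dy^2)
  ero <- matrix(Inf, nr, nc)
  for (k in seq_len(nrow(off))) {
    sh <- shift_mat(img, -off$dy[k], -off$dx[k], fill = Inf)
    ero <- pmin(ero, sh - off$h[k])
  }
  dil <- matrix(-Inf, nr, nc)
  for (k in seq_len(nrow(off))) {
    sh <- shift_mat(ero, -off$dy[k], -off$dx[k], fill = -Inf)
    dil <- pmax(dil, sh + off$h[k])
  }
  dil
}

# scalar even-odd point-in-polygon (crossing count), one point at a time
oracle_point_in_polygon <- function(px, py, poly) {
  n <- nrow(poly); crossings <- 0
  for (i in seq_len(n)) {
    j <- if (i == n) 1 else i + 1
    x1 <- poly[i, 1]; y1 <- poly[i, 2]; x2 <- poly[j, 1]; y2 <- poly[j, 2]
    if (y1 == y2) next
    if ((y1 > py) != (y2 > py)) {
      xint <- (x2 - x1) * (py - y1) / (y2 - y1) + x1
      if (px < xint) crossings <- crossings + 1
    }
  }
  crossings %% 2 == 1
}

# random quantized test image with plateaus (for maxima oracle comparisons)
random_quantized_image <- function(seed, max_dim = 40, levels = 8) {
  set.seed(seed)
  nr <- sample(8:max_dim, 1); nc <- sample(8:max_dim, 1)
  matrix(sample(0:levels, nr * nc, replace = TRUE) * (240 / levels), nr, nc)
}

as_eye_image <- function(m, pixelSize = 1.85) {
  methods::new("EyeImage", pixels = m, pixelSize = pixelSize)
}

# minimal writers for TIFF variants the package reader must accept
write_tiff_raw <- function(path, width, height, data_raw, bits, spp,
                           photometric = 1L) {
  con <- file(path, "wb"); on.exit(close(con))
  w2 <- function(x) writeBin(as.integer(x), con, size = 2L, endian = "little")
  w4 <- function(x) writeBin(as.integer(x), con, size = 4L, endian = "little")
  entry <- function(tag, type, count, value) { w2(tag); w2(type); w4(count)
    w4(value) }
  data_offset <- 8L
  ifd_offset <- data_offset + length(data_raw)
  writeBin(charToRaw("II"), con); w2(42L); w4(ifd_offset)
  writeBin(data_raw, con)
  n_entries <- if (spp == 3L) 10L else 9L
  w2(n_entries)
  entry(256, 4, 1, width); entry(257, 4, 1, height)
  if (spp == 3L) {
    # BitsPerSample count 3 exceeds 4 bytes: store after the IFD
    bps_offset <- ifd_offset + 2L + n_entries * 12L + 4L
    entry(258, 3, 3, bps_offset)
  } else entry(258, 3, 1, bits)
  entry(259, 3, 1, 1); entry(262, 3, 1, photometric)
  entry(273, 4, 1, data_offset); entry(277, 3, 1, spp)
  entry(278, 4, 1, height)
  entry(279, 4, 1, length(data_raw))
  if (spp == 3L) entry(284, 3, 1, 1)
  w4(0L)
  if (spp == 3L) { w2(bits); w2(bits); w2(bits) }
  invisible(path)
}

write_rgb_tiff <- function(path, r, g, b) {
  height <- nrow(r); width <- ncol(r)
  px <- rbind(as.vector(t(r)), as.vector(t(g)), as.vector(t(b)))
  write_tiff_raw(path, width, height, as.raw(as.integer(px)), 8L, 3L)
}

write_gray16_tiff <- function(path, m) {
  height <- nrow(m); width <- ncol(m)
  vals <- as.integer(t(m))
  data <- writeBin(vals, raw(), size = 2L, endian = "little")
  write_tiff_raw(path, width, height, data, 16L, 1L)
}

# minimal ImageJ .roi polygon record (big-endian)
write_imagej_roi <- function(path, xs, ys) {
  con <- file(path, "wb"); on.exit(close(con))
  wb2 <- function(x) writeBin(as.integer(x), con, size = 2L, endian = "big")
  writeBin(charToRaw("Iout"), con)
  wb2(227)            # version
  writeBin(as.raw(c(0, 0)), con)  # type polygon (0) + pad
  left <- min(xs); top <- min(ys)
  wb2(top); wb2(left); wb2(max(ys)); wb2(max(xs))
  wb2(length(xs))
  writeBin(raw(64 - 18), con)  # zero-fill up to coordinate block
  wb2(xs - left); wb2(ys - top)
  invisible(path)
}
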
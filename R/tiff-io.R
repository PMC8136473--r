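# Minimal multi-page grayscale TIFF codec.
#
# Scope: uncompressed, single-sample (grayscale) baseline TIFF stacks with
# 8- or 16-bit unsigned integer or 32-bit IEEE float samples -- the formats
# synchrotron reconstruction pipelines emit ("32bit real images in TIF
# format"). The reader accepts either byte order and strip layouts; the
# writer emits little-endian, one strip per page. Anything outside this
# subset is rejected with a distinct diagnostic rather than guessed at.

.u16raw <- function(v) {
  v <- as.integer(v)
  as.raw(rbind(v %% 256L, v %/% 256L))
}

.u32raw <- function(v) {
  v <- as.numeric(v)
  b0 <- v %% 256; v <- v %/% 256
  b1 <- v %% 256; v <- v %/% 256
  b2 <- v %% 256; v <- v %/% 256
  as.raw(rbind(b0, b1, b2, v %% 256))
}

# one 12-byte IFD entry, little-endian
.ifd_entry <- function(tag, type, count, value) {
  val <- if (type == 3L) c(.u16raw(value), as.raw(c(0, 0))) else .u32raw(value)
  c(.u16raw(tag), .u16raw(type), .u32raw(count), val)
}

.write_tiff_stack <- function(arr, path, bits = 32L) {
  stopifnot(length(dim(arr)) == 3L)
  if (!bits %in% c(8L, 16L, 32L))
    stop("unsupported bits per sample: ", bits, " (use 8, 16 or 32)")
  h <- dim(arr)[1]; w <- dim(arr)[2]; np <- dim(arr)[3]
  if (bits < 32L) {
    if (any(arr != round(arr)) || any(arr < 0) || any(arr > 2^bits - 1))
      stop("integer TIFF output requires whole values in [0, 2^bits - 1]")
  }
  d_bytes <- as.numeric(h) * w * (bits / 8)
  pad <- d_bytes %% 2
  ifd_size <- 2 + 10 * 12 + 4
  data_off <- 8 + (seq_len(np) - 1) * (d_bytes + pad + ifd_size)
  ifd_off <- data_off + d_bytes + pad

  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(charToRaw("II"), .u16raw(42L), .u32raw(ifd_off[1])), con)
  sample_format <- if (bits == 32L) 3L else 1L
  for (p in seq_len(np)) {
    v <- as.vector(t(arr[, , p]))  # row-major page samples
    if (bits == 8L) {
      writeBin(as.raw(v), con)
    } else if (bits == 16L) {
      writeBin(.u16raw(v), con)
    } else {
      writeBin(as.numeric(v), con, size = 4L, endian = "little")
    }
    if (pad > 0) writeBin(as.raw(0L), con)
    ifd <- c(
      .u16raw(10L),
      .ifd_entry(256L, 4L, 1L, w),
      .ifd_entry(257L, 4L, 1L, h),
      .ifd_entry(258L, 3L, 1L, bits),
      .ifd_entry(259L, 3L, 1L, 1L),            # no compression
      .ifd_entry(262L, 3L, 1L, 1L),            # BlackIsZero
      .ifd_entry(273L, 4L, 1L, data_off[p]),
      .ifd_entry(277L, 3L, 1L, 1L),
      .ifd_entry(278L, 4L, 1L, h),
      .ifd_entry(279L, 4L, 1L, d_bytes),
      .ifd_entry(339L, 3L, 1L, sample_format),
      .u32raw(if (p < np) ifd_off[p + 1] else 0L)
    )
    writeBin(ifd, con)
  }
  invisible(path)
}

.read_tiff_stack <- function(path) {
  raw <- readBin(path, "raw", n = file.size(path))
  if (length(raw) < 8L) stop("not a TIFF file (truncated header): ", path)
  endian <- if (raw[1] == as.raw(0x49) && raw[2] == as.raw(0x49)) "little"
            else if (raw[1] == as.raw(0x4d) && raw[2] == as.raw(0x4d)) "big"
            else stop("not a TIFF file (bad byte-order mark): ", path)
  rd_u16 <- function(off, n = 1L)
    readBin(raw[(off + 1):(off + 2L * n)], "integer", n = n, size = 2L,
            endian = endian, signed = FALSE)
  rd_u32 <- function(off, n = 1L) {
    v <- readBin(raw[(off + 1):(off + 4L * n)], "integer", n = n, size = 4L,
                 endian = endian)
    v <- as.numeric(v)
    ifelse(v < 0, v + 2^32, v)
  }
  if (rd_u16(2L) != 42L) stop("not a TIFF file (bad magic number): ", path)

  pages <- list()
  ifd_off <- rd_u32(4L)
  while (ifd_off != 0) {
    n_entries <- rd_u16(ifd_off)
    tags <- list()
    for (e in seq_len(n_entries)) {
      eo <- ifd_off + 2 + (e - 1) * 12
      tag <- rd_u16(eo); type <- rd_u16(eo + 2); count <- rd_u32(eo + 4)
      type_size <- c(`1` = 1, `2` = 1, `3` = 2, `4` = 4)[as.character(type)]
      if (is.na(type_size)) next  # ignore exotic tag types
      nbytes <- type_size * count
      voff <- if (nbytes > 4) rd_u32(eo + 8) else eo + 8
      vals <- if (type == 3L) rd_u16(voff, count)
              else if (type == 4L) rd_u32(voff, count)
              else as.integer(raw[(voff + 1):(voff + count)])
      tags[[as.character(tag)]] <- vals
    }
    tg <- function(id, default = NULL) {
      v <- tags[[as.character(id)]]
      if (is.null(v)) default else v
    }
    w <- tg(256); h <- tg(257)
    if (is.null(w) || is.null(h)) stop("TIFF page lacks dimensions: ", path)
    bits <- tg(258, 1L)[1]
    if (tg(259, 1L) != 1L)
      stop("unsupported TIFF: compressed data (compression tag ",
           tg(259), "): ", path)
    if (tg(277, 1L) != 1L)
      stop("unsupported TIFF: multi-sample (colour) data: ", path)
    if (!is.null(tg(284)) && tg(284) != 1L)
      stop("unsupported TIFF: planar configuration ", tg(284), ": ", path)
    fmt <- tg(339, 1L)[1]
    if (!(bits %in% c(8L, 16L) && fmt == 1L) && !(bits == 32L && fmt == 3L))
      stop("unsupported TIFF sample format: ", bits, "-bit, format code ",
           fmt, " (expected 8/16-bit unsigned or 32-bit float): ", path)
    offs <- tg(273); cnts <- tg(279)
    if (is.null(offs) || is.null(cnts))
      stop("unsupported TIFF: missing strip layout: ", path)
    dat <- raw(0)
    for (s in seq_along(offs))
      dat <- c(dat, raw[(offs[s] + 1):(offs[s] + cnts[s])])
    n <- as.numeric(w) * h
    vals <- if (bits == 8L) as.integer(dat[seq_len(n)])
            else if (bits == 16L)
              readBin(dat, "integer", n = n, size = 2L, endian = endian,
                      signed = FALSE)
            else readBin(dat, "double", n = n, size = 4L, endian = endian)
    pages[[length(pages) + 1L]] <- list(w = w, h = h, bits = bits,
                                        vals = vals)
    ifd_off <- rd_u32(ifd_off + 2 + n_entries * 12)
  }
  if (length(pages) == 0L) stop("TIFF file contains no pages: ", path)
  ws <- vapply(pages, `[[`, numeric(1), "w")
  hs <- vapply(pages, `[[`, numeric(1), "h")
  bs <- vapply(pages, `[[`, numeric(1), "bits")
  if (length(unique(ws)) != 1L || length(unique(hs)) != 1L ||
      length(unique(bs)) != 1L)
    stop("inconsistent page shapes in TIFF stack: ", path)
  h <- hs[1]; w <- ws[1]
  arr <- array(0, dim = c(h, w, length(pages)))
  for (p in seq_along(pages))
    arr[, , p] <- t(matrix(pages[[p]]$vals, nrow = w))
  list(data = arr, bits = bs[1],
       sample_format = if (bs[1] == 32) "float" else "uint")
}
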
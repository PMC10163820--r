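## Minimal multi-page TIFF I/O for the subset this pipeline emits:
## single-channel (grayscale), uncompressed, little-endian, one of 8-bit
## unsigned (masks), 16-bit unsigned (camera counts) or 32-bit IEEE float
## (ratio / correction images, NaN = missing). No pre-installed R package
## reads TIFF in this environment, so the package carries its own reader and
## writer for exactly this subset and rejects everything else.

.tiff_tag <- function(id, type, count, value_raw) {
  ## value_raw: exactly 4 bytes (value or offset), already little-endian
  c(writeBin(as.integer(id), raw(), size = 2, endian = "little"),
    writeBin(as.integer(type), raw(), size = 2, endian = "little"),
    writeBin(as.integer(count), raw(), size = 4, endian = "little"),
    value_raw)
}

.le4 <- function(x) writeBin(as.integer(x), raw(), size = 4, endian = "little")
.le2pad <- function(x) c(writeBin(as.integer(x), raw(), size = 2, endian = "little"),
                         as.raw(c(0, 0)))

#' Write a stack of matrices as a multi-page grayscale TIFF
#'
#' @param frames matrix or list of equally shaped matrices.
#' @param path output file.
#' @param bits 8 or 16 (unsigned integer, values rounded and clamped) or 32
#'   (IEEE float, NA written as NaN).
#' @return `path`, invisibly.
#' @export
write_tiff_stack <- function(frames, path, bits = 16L) {
  if (is.matrix(frames)) frames <- list(frames)
  stopifnot(length(frames) >= 1L)
  bits <- as.integer(bits)
  if (!bits %in% c(8L, 16L, 32L)) stop("bits must be 8, 16 or 32")
  d <- dim(frames[[1L]])
  for (f in frames) if (!identical(dim(f), d)) stop("frames differ in shape")
  H <- d[1L]; W <- d[2L]
  bytes_px <- bits %/% 8L
  n <- length(frames)
  ifd_size <- 2L + 10L * 12L + 4L
  data_off <- integer(n); ifd_off <- integer(n)
  off <- 8L
  for (k in seq_len(n)) {
    data_off[k] <- off
    off <- off + H * W * bytes_px
    ifd_off[k] <- off
    off <- off + ifd_size
  }
  sample_format <- if (bits == 32L) 3L else 1L
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("II"), con)
  writeBin(as.integer(42), con, size = 2, endian = "little")
  writeBin(.le4(ifd_off[1L]), con)
  for (k in seq_len(n)) {
    v <- t(frames[[k]])  # scanline (row-major) order
    if (bits == 32L) {
      vv <- as.numeric(v)
      vv[is.na(vv)] <- NaN
      writeBin(vv, con, size = 4, endian = "little")
    } else {
      vv <- as.integer(pmin(pmax(round(as.numeric(v)), 0), 2^bits - 1))
      writeBin(vv, con, size = bytes_px, endian = "little")
    }
    tags <- c(.tiff_tag(256L, 4L, 1L, .le4(W)),
              .tiff_tag(257L, 4L, 1L, .le4(H)),
              .tiff_tag(258L, 3L, 1L, .le2pad(bits)),
              .tiff_tag(259L, 3L, 1L, .le2pad(1L)),
              .tiff_tag(262L, 3L, 1L, .le2pad(1L)),
              .tiff_tag(273L, 4L, 1L, .le4(data_off[k])),
              .tiff_tag(277L, 3L, 1L, .le2pad(1L)),
              .tiff_tag(278L, 4L, 1L, .le4(H)),
              .tiff_tag(279L, 4L, 1L, .le4(H * W * bytes_px)),
              .tiff_tag(339L, 3L, 1L, .le2pad(sample_format)))
    writeBin(writeBin(10L, raw(), size = 2, endian = "little"), con)
    writeBin(tags, con)
    writeBin(.le4(if (k < n) ifd_off[k + 1L] else 0L), con)
  }
  invisible(path)
}

.rd_int <- function(raw, off, size, signed = FALSE) {
  ## off is 0-based; returns integer/double
  b <- as.integer(raw[off + seq_len(size)])
  sum(b * 256^(seq_len(size) - 1))
}

#' Read a multi-page grayscale TIFF written in the supported subset
#'
#' Accepts uncompressed, little-endian, single-sample TIFFs with 8/16-bit
#' unsigned or 32-bit float pixels (multiple strips allowed). Anything else
#' (RGB, compressed, big-endian, tiled) is rejected.
#'
#' @param path file path.
#' @return list of numeric matrices (32-bit NaN read back as NA).
#' @export
read_tiff_stack <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- readBin(path, "raw", n = file.size(path))
  if (length(raw) < 8L) stop("not a TIFF file: ", path)
  order <- rawToChar(raw[1:2])
  if (order == "MM") stop("big-endian TIFF not supported")
  if (order != "II" || .rd_int(raw, 2L, 2L) != 42L) stop("not a TIFF file: ", path)
  ifd <- .rd_int(raw, 4L, 4L)
  frames <- list()
  while (ifd != 0) {
    n_tags <- .rd_int(raw, ifd, 2L)
    tags <- list()
    for (i in seq_len(n_tags)) {
      base <- ifd + 2L + (i - 1L) * 12L
      id <- .rd_int(raw, base, 2L)
      type <- .rd_int(raw, base + 2L, 2L)
      count <- .rd_int(raw, base + 4L, 4L)
      tsize <- switch(as.character(type), "1" = 1L, "3" = 2L, "4" = 4L, NA_integer_)
      if (is.na(tsize)) { tags[[as.character(id)]] <- NULL; next }
      total <- tsize * count
      voff <- if (total <= 4L) base + 8L else .rd_int(raw, base + 8L, 4L)
      vals <- vapply(seq_len(count), function(j)
        .rd_int(raw, voff + (j - 1L) * tsize, tsize), numeric(1))
      tags[[as.character(id)]] <- vals
    }
    g <- function(id, default = NULL) {
      v <- tags[[as.character(id)]]
      if (is.null(v)) default else v
    }
    W <- g(256); H <- g(257)
    if (is.null(W) || is.null(H)) stop("TIFF lacks image dimensions")
    bits <- g(258, 1)
    if (length(bits) > 1L || g(277, 1) > 1L)
      stop("multi-sample (e.g. RGB) TIFF not supported; grayscale required")
    if (g(259, 1) != 1) stop("compressed TIFF not supported")
    fmt <- g(339, 1)
    if (!(bits %in% c(8, 16) && fmt == 1) && !(bits == 32 && fmt == 3))
      stop("unsupported TIFF pixel type: ", bits, "-bit, sample format ", fmt)
    offsets <- g(273); counts <- g(279)
    if (is.null(offsets) || is.null(counts)) stop("TIFF lacks strip layout")
    buf <- raw(0)
    for (s in seq_along(offsets))
      buf <- c(buf, raw[offsets[s] + seq_len(counts[s])])
    if (bits == 32) {
      v <- readBin(buf, "numeric", n = H * W, size = 4, endian = "little")
      v[is.nan(v)] <- NA_real_
    } else {
      v <- readBin(buf, "integer", n = H * W, size = bits / 8,
                   endian = "little", signed = FALSE)
    }
    frames[[length(frames) + 1L]] <- matrix(as.numeric(v), H, W, byrow = TRUE)
    ifd <- .rd_int(raw, ifd + 2L + n_tags * 12L, 4L)
  }
  if (length(frames) == 0L) stop("TIFF contains no images")
  frames
}
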
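#' Minimal baseline TIFF stack I/O
#'
#' A small built-in codec for the subset of TIFF that single-channel
#' microscopy stacks use: multi-page, uncompressed, grayscale, 8- or 16-bit
#' unsigned integer samples, strip-organized. Both little- and big-endian
#' files are read; files are written 16-bit little-endian with one strip per
#' page. Anything outside this subset (compression, tiles, palette/RGB
#' pages) is rejected with an error naming the offending page.
#'
#' @param path file path.
#' @return `read_tiff_stack()` returns a list of integer matrices, one per
#'   page, in page order (row 1 = top image row).
#' @name tiff_io
NULL

#' @rdname tiff_io
#' @export
read_tiff_stack <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", 4)
  endian <- if (identical(magic[1:2], as.raw(c(0x49, 0x49)))) "little"
            else if (identical(magic[1:2], as.raw(c(0x4d, 0x4d)))) "big"
            else stop("not a TIFF file: ", path)
  u16 <- function(r, i) sum(as.integer(r[i + if (endian == "little") 0:1 else 1:0]) *
                              if (endian == "little") c(1, 256) else c(256, 1))
  rd16 <- function(n) readBin(con, "integer", n, size = 2, signed = FALSE, endian = endian)
  rd32 <- function(n) readBin(con, "integer", n, size = 4, endian = endian)
  if (u16(magic, 3) != 42L) stop("bad TIFF magic number in ", path)
  offset <- rd32(1)
  pages <- list()
  page_i <- 0L
  while (offset != 0) {
    page_i <- page_i + 1L
    seek(con, offset)
    n_entries <- rd16(1)
    tags <- vector("list", n_entries)
    for (e in seq_len(n_entries)) {
      tag <- rd16(1); type <- rd16(1); count <- rd32(1)
      value_raw <- readBin(con, "raw", 4)
      tags[[e]] <- list(tag = tag, type = type, count = count, raw = value_raw)
    }
    next_ifd <- rd32(1)
    read_values <- function(entry) {
      # SHORT(3) and LONG(4) only; inline if they fit in 4 bytes
      size <- if (entry$type == 3) 2L else if (entry$type == 4) 4L else
        stop("unsupported TIFF tag type ", entry$type, " on page ", page_i)
      total <- size * entry$count
      if (total <= 4) {
        vals <- integer(entry$count)
        for (k in seq_len(entry$count)) {
          b <- entry$raw[((k - 1L) * size + 1L):(k * size)]
          ints <- as.integer(b)
          if (endian == "big") ints <- rev(ints)
          vals[k] <- sum(ints * 256^(seq_along(ints) - 1L))
        }
        vals
      } else {
        off <- sum(as.integer(if (endian == "little") entry$raw else rev(entry$raw)) * 256^(0:3))
        here <- seek(con)
        seek(con, off)
        vals <- if (size == 2L) rd16(entry$count) else rd32(entry$count)
        seek(con, here)
        vals
      }
    }
    tagval <- function(code, default = NULL) {
      hit <- Filter(function(e) e$tag == code, tags)
      if (!length(hit)) {
        if (is.null(default)) stop("TIFF page ", page_i, " missing tag ", code)
        return(default)
      }
      read_values(hit[[1]])
    }
    width <- tagval(256); height <- tagval(257)
    bits <- tagval(258, 8L)
    if (!all(bits %in% c(8L, 16L)) || length(bits) != 1L)
      stop("page ", page_i, ": only 8/16-bit grayscale supported")
    if (tagval(259, 1L)[1] != 1L)
      stop("page ", page_i, ": compressed TIFF not supported")
    if (tagval(277, 1L)[1] != 1L)
      stop("page ", page_i, ": not single-sample grayscale")
    strip_off <- tagval(273)
    strip_cnt <- tagval(279, width * height * bits / 8)
    rows_per_strip <- tagval(278, height)[1]
    vals <- integer(0)
    for (s in seq_along(strip_off)) {
      seek(con, strip_off[s])
      n_px <- strip_cnt[s] / (bits / 8)
      vals <- c(vals, readBin(con, "integer", n_px, size = bits / 8,
                              signed = FALSE, endian = endian))
    }
    if (length(vals) != width * height)
      stop("page ", page_i, ": truncated pixel data")
    # TIFF is row-major; R matrices are column-major
    pages[[page_i]] <- matrix(vals, nrow = height, ncol = width, byrow = TRUE)
    offset <- next_ifd
  }
  pages
}

#' @rdname tiff_io
#' @param pages a matrix or list of equally-typed integer/numeric matrices;
#'   values are rounded and clamped to the 16-bit range 0..65535.
#' @export
write_tiff_stack <- function(pages, path) {
  if (is.matrix(pages)) pages <- list(pages)
  stopifnot(length(pages) >= 1)
  con <- file(path, "wb")
  on.exit(close(con))
  w16 <- function(x) writeBin(as.integer(x), con, size = 2, endian = "little")
  w32 <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  writeBin(as.raw(c(0x49, 0x49)), con); w16(42L)
  n_tags <- 8L
  ifd_size <- 2L + n_tags * 12L + 4L
  # layout: header (8) | per-page pixel data | per-page IFDs
  data_off <- 8L
  sizes <- vapply(pages, function(p) 2L * length(p), integer(1))
  data_offsets <- data_off + cumsum(c(0L, sizes[-length(sizes)]))
  ifd0 <- data_off + sum(sizes)
  ifd_offsets <- ifd0 + (seq_along(pages) - 1L) * ifd_size
  w32(ifd_offsets[1])
  for (p in pages) {
    v <- round(as.vector(t(p)))
    v[v < 0] <- 0; v[v > 65535] <- 65535
    writeBin(as.integer(v), con, size = 2, endian = "little")
  }
  entry <- function(tag, type, count, value) {
    w16(tag); w16(type); w32(count)
    if (type == 3) { w16(value); w16(0L) } else w32(value)
  }
  for (i in seq_along(pages)) {
    p <- pages[[i]]
    w16(n_tags)
    entry(256, 4, 1, ncol(p))              # ImageWidth
    entry(257, 4, 1, nrow(p))              # ImageLength
    entry(258, 3, 1, 16L)                  # BitsPerSample
    entry(259, 3, 1, 1L)                   # Compression: none
    entry(262, 3, 1, 1L)                   # Photometric: BlackIsZero
    entry(273, 4, 1, data_offsets[i])      # StripOffsets
    entry(278, 4, 1, nrow(p))              # RowsPerStrip
    entry(279, 4, 1, sizes[i])             # StripByteCounts
    w32(if (i < length(pages)) ifd_offsets[i + 1] else 0L)
  }
  invisible(path)
}
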
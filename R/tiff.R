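# Minimal baseline TIFF codec (uncompressed, grayscale, one page per
# channel). No TIFF package ships with the supported R stack, so the subset
# of the format this pipeline needs is implemented here: little-endian
# writing of float32 or uint16 pages, and reading of uncompressed
# uint8/16/32, int, or float32/64 pages in either byte order, with single or
# multiple strips. Conformance is cross-checked against an external reader
# in the test suite.

TIFF_TAGS <- c(width = 256L, length = 257L, bits = 258L, compression = 259L,
               photometric = 262L, strip_offsets = 273L, spp = 277L,
               rows_per_strip = 278L, strip_bytes = 279L,
               sample_format = 339L)

# -- writing -----------------------------------------------------------------

w_u16 <- function(con, x) writeBin(as.integer(x), con, size = 2,
                                   endian = "little")
w_u32 <- function(con, x) writeBin(as.integer(x), con, size = 4,
                                   endian = "little")

tiff_entry <- function(con, tag, type, count, value) {
  w_u16(con, tag); w_u16(con, type); w_u32(con, count)
  if (type == 3L) { w_u16(con, value); w_u16(con, 0L) }  # SHORT padded
  else w_u32(con, value)                                 # LONG
}

#' Write matrices as a multi-page grayscale TIFF
#'
#' One uncompressed little-endian page per matrix, in list order. `float32`
#' is the default sample format; integer data up to 2^24 round-trips
#' bit-exactly through it. Use `format = "uint16"` for raw camera counts.
#'
#' @param pages List of numeric matrices (rows = scan lines).
#' @param path Output file path.
#' @param format `"float32"` (default) or `"uint16"`.
#' @return `path`, invisibly.
#' @keywords internal
write_tiff_pages <- function(pages, path, format = c("float32", "uint16")) {
  format <- match.arg(format)
  stopifnot(is.list(pages), length(pages) > 0L)
  bps <- if (format == "float32") 32L else 16L
  sfmt <- if (format == "float32") 3L else 1L
  bytespp <- bps / 8L
  n_ifd_bytes <- 2L + 10L * 12L + 4L
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("II", con, nchars = 2, eos = NULL)
  w_u16(con, 42L)
  # page i: data then IFD; first IFD sits after page 1's data
  data_bytes <- vapply(pages, function(m) length(m) * bytespp, numeric(1))
  offs_data <- 8 + cumsum(c(0, head(data_bytes + n_ifd_bytes, -1)))
  offs_ifd <- offs_data + data_bytes
  w_u32(con, offs_ifd[1])
  for (i in seq_along(pages)) {
    m <- pages[[i]]
    stopifnot(is.matrix(m), is.numeric(m))
    v <- as.vector(t(m))  # TIFF stores rows sequentially
    if (format == "uint16") {
      if (any(v < 0 | v > 65535 | v != round(v)))
        stop("uint16 TIFF requires integer intensities in [0, 65535]")
      writeBin(as.integer(v), con, size = 2, endian = "little")
    } else {
      writeBin(as.numeric(v), con, size = 4, endian = "little")
    }
    w_u16(con, 10L)
    tiff_entry(con, 256L, 4L, 1L, ncol(m))
    tiff_entry(con, 257L, 4L, 1L, nrow(m))
    tiff_entry(con, 258L, 3L, 1L, bps)
    tiff_entry(con, 259L, 3L, 1L, 1L)
    tiff_entry(con, 262L, 3L, 1L, 1L)
    tiff_entry(con, 273L, 4L, 1L, offs_data[i])
    tiff_entry(con, 277L, 3L, 1L, 1L)
    tiff_entry(con, 278L, 4L, 1L, nrow(m))
    tiff_entry(con, 279L, 4L, 1L, data_bytes[i])
    tiff_entry(con, 339L, 3L, 1L, sfmt)
    w_u32(con, if (i < length(pages)) offs_ifd[i + 1] else 0L)
  }
  invisible(path)
}

# -- reading -----------------------------------------------------------------

#' Read all pages of an uncompressed grayscale TIFF
#'
#' @param path TIFF file.
#' @return List of numeric matrices, one per page.
#' @keywords internal
read_tiff_pages <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  raw <- readBin(path, "raw", n = file.info(path)$size)
  if (length(raw) < 8L) stop("not a TIFF file (too short)")
  order_tag <- rawToChar(raw[1:2])
  endian <- switch(order_tag, II = "little", MM = "big",
                   stop("not a TIFF file (bad byte-order mark)"))
  u <- function(at, size, n = 1L)  # unsigned int at 0-based offset
    readBin(raw[(at + 1):(at + size * n)], "integer", n = n, size = size,
            endian = endian, signed = size > 2)
  if (u(2, 2) != 42L) stop("not a TIFF file (bad magic)")
  ifd_off <- u(4, 4)
  pages <- list()
  while (ifd_off != 0L) {
    n_entries <- u(ifd_off, 2)
    tags <- list()
    for (k in seq_len(n_entries)) {
      at <- ifd_off + 2 + (k - 1) * 12
      tag <- u(at, 2); type <- u(at + 2, 2); count <- u(at + 4, 4)
      tsize <- switch(as.character(type), `1` = 1L, `3` = 2L, `4` = 4L, NA_integer_)
      if (is.na(tsize)) next  # skip rationals etc.; not needed
      vals <- if (tsize * count <= 4L) u(at + 8, tsize, count)
              else u(u(at + 8, 4), tsize, count)
      tags[[as.character(tag)]] <- vals
    }
    need <- function(tag, default = NULL) {
      v <- tags[[as.character(tag)]]
      if (is.null(v)) {
        if (is.null(default)) stop(sprintf("TIFF tag %d missing", tag))
        default
      } else v
    }
    wd <- need(256L); ht <- need(257L)
    bits <- need(258L, 1L)[1]
    if (need(259L, 1L) != 1L) stop("compressed TIFF not supported")
    if (need(277L, 1L) != 1L) stop("multi-sample TIFF pages not supported")
    sfmt <- need(339L, 1L)
    strip_off <- need(273L); strip_bytes <- need(279L)
    n_px <- wd * ht
    bytespp <- bits / 8L
    vals <- numeric(0)
    for (s in seq_along(strip_off)) {
      seg <- raw[(strip_off[s] + 1):(strip_off[s] + strip_bytes[s])]
      n_s <- strip_bytes[s] / bytespp
      v <- if (sfmt == 3L)
        readBin(seg, "double", n = n_s, size = bytespp, endian = endian)
      else
        readBin(seg, "integer", n = n_s, size = bytespp, endian = endian,
                signed = sfmt == 2L || bytespp > 2L)
      if (sfmt == 1L && bytespp == 4L && any(v < 0))
        v[v < 0] <- v[v < 0] + 2^32  # uint32 wrap
      vals <- c(vals, as.numeric(v))
    }
    if (length(vals) != n_px) stop("TIFF strip data does not match page size")
    pages[[length(pages) + 1L]] <- matrix(vals, nrow = ht, ncol = wd,
                                          byrow = TRUE)
    ifd_off <- u(ifd_off + 2 + n_entries * 12, 4)
  }
  if (length(pages) == 0L) stop("TIFF contains no pages")
  pages
}
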
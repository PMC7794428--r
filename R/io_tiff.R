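# Minimal multi-page TIFF I/O: uncompressed 8/16-bit single-channel
# grayscale only.  No R TIFF reader is assumed to be installed; this
# implements just enough of the TIFF 6.0 baseline for CASA stacks and is
# cross-checked against an independent reference reader in the tests.

TIFF_TYPE_BYTES <- c(`1` = 1, `2` = 1, `3` = 2, `4` = 4, `5` = 8)

#' Write a frame stack as a multi-page TIFF
#'
#' Writes uncompressed grayscale pages (8-bit by default).  The spatial
#' calibration and frame rate are recorded in the first page's
#' ImageDescription tag so that [read_tiff_stack()] can restore them.
#'
#' @param stack a [frame_stack()].
#' @param path output file path.
#' @param bits_per_sample 8 or 16.
#' @return `path`, invisibly.
#' @export
write_tiff_stack <- function(stack, path, bits_per_sample = 8) {
  stopifnot(inherits(stack, "frame_stack"))
  if (!bits_per_sample %in% c(8, 16))
    stopf("bits_per_sample must be 8 or 16")
  maxv <- 2^bits_per_sample - 1
  nrp <- dim(stack$frames[[1]])[1]
  ncp <- dim(stack$frames[[1]])[2]
  npix <- nrp * ncp
  bpp <- bits_per_sample / 8
  desc <- sprintf("coralcasa;microns_per_pixel=%.10g;frame_rate_hz=%.10g",
                  stack$microns_per_pixel, stack$frame_rate_hz)
  desc_raw <- c(charToRaw(desc), as.raw(0))
  if (length(desc_raw) %% 2 == 1) desc_raw <- c(desc_raw, as.raw(0))

  n_pages <- length(stack$frames)
  pad <- function(n) (n + 1) %/% 2 * 2
  # layout: header | page1 data | desc | IFD1 | page2 data | IFD2 | ...
  data_off <- integer(n_pages); ifd_off <- integer(n_pages)
  off <- 8
  for (i in seq_len(n_pages)) {
    data_off[i] <- off
    off <- off + pad(npix * bpp)
    if (i == 1) off <- off + length(desc_raw)
    ifd_off[i] <- off
    n_entries <- if (i == 1) 10L else 9L
    off <- off + 2 + 12 * n_entries + 4
  }

  con <- file(path, "wb")
  on.exit(close(con))
  w16 <- function(x) writeBin(as.integer(x), con, size = 2,
                              endian = "little")
  w32 <- function(x) writeBin(as.integer(x), con, size = 4,
                              endian = "little")
  entry <- function(tag, type, count, value) {
    w16(tag); w16(type); w32(count)
    if (type == 3) { w16(value); w16(0) } else w32(value)
  }
  writeBin(charToRaw("II"), con); w16(42L); w32(ifd_off[1])
  for (i in seq_len(n_pages)) {
    v <- round(clip(stack$frames[[i]], 0, maxv))
    v <- as.integer(t(v))  # row-major
    if (bpp == 1) writeBin(as.raw(v), con)
    else writeBin(v, con, size = 2, endian = "little")
    nbytes <- npix * bpp
    if (nbytes %% 2 == 1) writeBin(as.raw(0), con)
    desc_off <- 0
    if (i == 1) { desc_off <- data_off[1] + pad(nbytes); writeBin(desc_raw, con) }
    n_entries <- if (i == 1) 10L else 9L
    w16(n_entries)
    entry(256, 4, 1, ncp)               # ImageWidth
    entry(257, 4, 1, nrp)               # ImageLength
    entry(258, 3, 1, bits_per_sample)   # BitsPerSample
    entry(259, 3, 1, 1)                 # Compression = none
    entry(262, 3, 1, 1)                 # Photometric = BlackIsZero
    if (i == 1) entry(270, 2, length(desc_raw), desc_off)
    entry(273, 4, 1, data_off[i])       # StripOffsets (single strip)
    entry(277, 3, 1, 1)                 # SamplesPerPixel
    entry(278, 4, 1, nrp)               # RowsPerStrip
    entry(279, 4, 1, npix * bpp)        # StripByteCounts
    w32(if (i < n_pages) ifd_off[i + 1] else 0)
  }
  invisible(path)
}

#' Read a multi-page TIFF as a frame stack
#'
#' Supports baseline uncompressed 8/16-bit single-channel grayscale TIFFs
#' (either byte order, any strip layout).  Calibration and frame rate are
#' taken from the ImageDescription written by [write_tiff_stack()] when
#' present; otherwise they must be supplied.
#'
#' @param path TIFF file path.
#' @param microns_per_pixel,frame_rate_hz calibration overrides (required if
#'   the file carries none).
#' @return a [frame_stack()].
#' @export
read_tiff_stack <- function(path, microns_per_pixel = NULL,
                            frame_rate_hz = NULL) {
  raw <- readBin(path, "raw", file.info(path)$size)
  if (length(raw) < 8) stopf("not a TIFF file: %s", path)
  order_tag <- rawToChar(raw[1:2])
  endian <- switch(order_tag, II = "little", MM = "big",
                   stopf("not a TIFF file: %s", path))
  u16 <- function(off) readBin(raw[(off + 1):(off + 2)], "integer",
                               size = 2, signed = FALSE, endian = endian)
  u32 <- function(off) {
    v <- readBin(raw[(off + 1):(off + 4)], "integer", size = 4,
                 endian = endian)
    if (v < 0) v <- v + 2^32
    v
  }
  if (u16(2) != 42) stopf("bad TIFF magic in %s", path)

  frames <- list()
  desc <- NULL
  ifd <- u32(4)
  while (ifd != 0) {
    n <- u16(ifd)
    tags <- list()
    for (k in seq_len(n)) {
      e <- ifd + 2 + (k - 1) * 12
      tag <- u16(e); type <- u16(e + 2); count <- u32(e + 4)
      nb <- TIFF_TYPE_BYTES[[as.character(type)]] * count
      voff <- if (nb > 4) u32(e + 8) else e + 8
      vals <- switch(as.character(type),
        `1` = as.integer(raw[(voff + 1):(voff + count)]),
        `2` = rawToChar(raw[(voff + 1):(voff + count - 1)]),
        `3` = vapply(seq_len(count) - 1L,
                     function(j) u16(voff + 2 * j), numeric(1)),
        `4` = vapply(seq_len(count) - 1L,
                     function(j) u32(voff + 4 * j), numeric(1)),
        `5` = vapply(seq_len(count) - 1L, function(j)
                     u32(voff + 8 * j) / u32(voff + 8 * j + 4), numeric(1)),
        NULL)
      tags[[as.character(tag)]] <- vals
    }
    g <- function(tag, default = NULL) {
      v <- tags[[as.character(tag)]]
      if (is.null(v)) default else v
    }
    width <- g(256); height <- g(257)
    if (is.null(width) || is.null(height)) stopf("TIFF page missing size")
    bits <- g(258, 1)[1]
    if (!bits %in% c(8, 16))
      stopf("unsupported TIFF bit depth %d (8/16-bit grayscale only)", bits)
    if (g(259, 1) != 1) stopf("compressed TIFF not supported")
    if (g(277, 1) != 1) stopf("multi-channel TIFF not supported")
    if (is.null(desc)) desc <- g(270)
    offs <- g(273); counts <- g(279)
    if (is.null(offs) || is.null(counts)) stopf("TIFF page missing strips")
    bytes <- unlist(lapply(seq_along(offs), function(s)
      raw[(offs[s] + 1):(offs[s] + counts[s])]))
    vals <- if (bits == 8) as.integer(bytes)
    else {
      v <- readBin(bytes, "integer", n = length(bytes) / 2, size = 2,
                   signed = FALSE, endian = endian)
      v
    }
    if (g(262, 1) == 0) vals <- (2^bits - 1) - vals  # WhiteIsZero
    frames[[length(frames) + 1]] <- matrix(vals, nrow = height,
                                           ncol = width, byrow = TRUE)
    ifd <- u32(ifd + 2 + n * 12)
  }

  if (!is.null(desc) && grepl("coralcasa", desc)) {
    pick <- function(key) {
      m <- regmatches(desc, regexec(paste0(key, "=([0-9.eE+-]+)"), desc))[[1]]
      if (length(m) == 2) as.numeric(m[2]) else NULL
    }
    if (is.null(microns_per_pixel)) microns_per_pixel <- pick("microns_per_pixel")
    if (is.null(frame_rate_hz)) frame_rate_hz <- pick("frame_rate_hz")
  }
  if (is.null(microns_per_pixel) || is.null(frame_rate_hz))
    stopf(paste("TIFF carries no calibration: supply microns_per_pixel",
                "and frame_rate_hz"))
  frame_stack(frames, microns_per_pixel, frame_rate_hz)
}
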
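# Minimal baseline TIFF 6.0 I/O: 16-bit unsigned grayscale, uncompressed,
# little-endian, multi-page, single strip per page. No R TIFF package is
# available in the target environment, so the subset of the format the
# pipeline needs is implemented here and round-trip tested.

.tiff_tag <- function(id, type, count, value) {
  # returns raw(12); value must already fit in 4 bytes (all our tags do)
  con <- rawConnection(raw(0), "wb")
  on.exit(close(con))
  writeBin(as.integer(id), con, size = 2, endian = "little")
  writeBin(as.integer(type), con, size = 2, endian = "little")
  writeBin(as.integer(count), con, size = 4, endian = "little")
  if (type == 3L) { # SHORT: left-justified in the 4-byte slot
    writeBin(as.integer(value), con, size = 2, endian = "little")
    writeBin(0L, con, size = 2, endian = "little")
  } else {
    writeBin(as.integer(value), con, size = 4, endian = "little")
  }
  rawConnectionValue(con)
}

#' Write a grayscale image stack as a multi-page TIFF
#'
#' @param stack An integer/numeric matrix or 3-D array (rows, cols, frames)
#'   with values in [0, 65535], or a list of matrices.
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
write_tiff <- function(stack, path) {
  if (is.list(stack)) {
    frames <- stack
  } else if (length(dim(stack)) == 3L) {
    frames <- lapply(seq_len(dim(stack)[3]), function(i) stack[, , i])
  } else {
    frames <- list(stack)
  }
  h <- nrow(frames[[1]]); w <- ncol(frames[[1]])
  nbytes <- 2L * h * w
  n_tags <- 10L
  ifd_size <- 2L + 12L * n_tags + 4L
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("II", con, eos = NULL)
  writeBin(42L, con, size = 2, endian = "little")
  # each page is [pixel strip][IFD]; first IFD sits after the first strip
  writeBin(8L + nbytes, con, size = 4, endian = "little")
  offset <- 8L
  n <- length(frames)
  for (i in seq_len(n)) {
    fr <- frames[[i]]
    if (nrow(fr) != h || ncol(fr) != w) stop("all frames must share dimensions")
    v <- as.integer(round(pmin(pmax(fr, 0), 65535)))
    v <- ifelse(v > 32767L, v - 65536L, v)  # two's-complement for writeBin
    # pixel data (row-major strip), then the IFD for this page
    data_off <- offset
    writeBin(as.vector(t(matrix(v, h, w))), con, size = 2, endian = "little")
    ifd_off <- data_off + nbytes
    tags <- list(
      .tiff_tag(256, 4, 1, w),            # ImageWidth
      .tiff_tag(257, 4, 1, h),            # ImageLength
      .tiff_tag(258, 3, 1, 16),           # BitsPerSample
      .tiff_tag(259, 3, 1, 1),            # Compression = none
      .tiff_tag(262, 3, 1, 1),            # Photometric = BlackIsZero
      .tiff_tag(273, 4, 1, data_off),     # StripOffsets
      .tiff_tag(277, 3, 1, 1),            # SamplesPerPixel
      .tiff_tag(278, 4, 1, h),            # RowsPerStrip
      .tiff_tag(279, 4, 1, nbytes),       # StripByteCounts
      .tiff_tag(339, 3, 1, 1)             # SampleFormat = unsigned int
    )
    writeBin(as.integer(length(tags)), con, size = 2, endian = "little")
    for (tg in tags) writeBin(tg, con)
    next_off <- if (i < n) ifd_off + ifd_size + nbytes else 0L
    writeBin(as.integer(next_off), con, size = 4, endian = "little")
    offset <- ifd_off + ifd_size
  }
  invisible(path)
}

#' Read a multi-page grayscale TIFF written by \code{\link{write_tiff}}
#'
#' Supports uncompressed little-endian 8- or 16-bit grayscale baseline TIFF
#' with one strip per page.
#'
#' @param path File path.
#' @return 3-D integer array (rows, cols, frames).
#' @export
read_tiff <- function(path) {
  raw_all <- readBin(path, "raw", file.info(path)$size)
  rd_u16 <- function(off) {
    as.integer(raw_all[off + 1]) + 256L * as.integer(raw_all[off + 2])
  }
  rd_u32 <- function(off) {
    as.integer(raw_all[off + 1]) + 256 * as.integer(raw_all[off + 2]) +
      65536 * as.integer(raw_all[off + 3]) + 16777216 * as.integer(raw_all[off + 4])
  }
  if (rawToChar(raw_all[1:2]) != "II" || rd_u16(2) != 42L)
    stop("not a little-endian TIFF")
  ifd <- rd_u32(4)
  frames <- list()
  while (ifd != 0) {
    n_tags <- rd_u16(ifd)
    tagv <- function(id, default = NULL) {
      for (j in seq_len(n_tags)) {
        e <- ifd + 2 + 12 * (j - 1)
        if (rd_u16(e) == id) {
          type <- rd_u16(e + 2)
          return(if (type == 3L) rd_u16(e + 8) else rd_u32(e + 8))
        }
      }
      default
    }
    w <- tagv(256); h <- tagv(257)
    bps <- tagv(258, 1L)
    if (!is.null(tagv(259)) && tagv(259) != 1L) stop("compressed TIFF not supported")
    off <- tagv(273); nb <- tagv(279)
    if (bps == 16L) {
      vals <- readBin(raw_all[(off + 1):(off + nb)], "integer", n = nb / 2,
                      size = 2, signed = FALSE, endian = "little")
    } else if (bps == 8L) {
      vals <- as.integer(raw_all[(off + 1):(off + nb)])
    } else stop("unsupported bit depth: ", bps)
    frames[[length(frames) + 1]] <- matrix(vals, nrow = h, ncol = w, byrow = TRUE)
    ifd <- rd_u32(ifd + 2 + 12 * n_tags)
  }
  array(unlist(frames), dim = c(nrow(frames[[1]]), ncol(frames[[1]]),
                                length(frames)))
}
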
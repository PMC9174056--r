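# Minimal multi-page TIFF I/O (little-endian, uncompressed, one strip per
# page, 32-bit float or 16-bit unsigned). No TIFF package exists in the
# supported environment, so the format is written by hand; channel names and
# pixel size travel in a JSON ImageDescription tag on the first page.

.tiffTypes <- c(SHORT = 3L, LONG = 4L, ASCII = 2L)

#' Write a multi-channel image as a multi-page TIFF
#'
#' One page per channel, uncompressed little-endian, 32-bit float (intensity
#' images) or 16-bit unsigned (label images). Channel names and the pixel
#' size are stored as a JSON ImageDescription so [readTiffStack()] can
#' round-trip a [ChannelStack] losslessly.
#'
#' @param x a [ChannelStack], a numeric matrix, or a `ny x nx x nc` array.
#' @param path output file path.
#' @param channels channel names (defaulted from `x` when a ChannelStack).
#' @param pixelSize pixel size in micrometres.
#' @param dtype `"float32"` or `"uint16"`.
#' @return `path`, invisibly.
#' @export
writeTiffStack <- function(x, path, channels = NULL, pixelSize = NULL,
                           dtype = c("float32", "uint16")) {
  dtype <- match.arg(dtype)
  if (is(x, "ChannelStack")) {
    if (is.null(channels)) channels <- x@channels
    if (is.null(pixelSize)) pixelSize <- x@pixelSize
    x <- x@data
  }
  if (is.matrix(x)) x <- array(x, c(dim(x), 1L))
  d <- dim(x)
  ny <- d[1]; nx <- d[2]; nc <- d[3]
  if (is.null(channels)) channels <- paste0("ch", seq_len(nc))
  if (is.null(pixelSize)) pixelSize <- 1

  bps <- if (dtype == "float32") 32L else 16L
  sampFmt <- if (dtype == "float32") 3L else 1L
  bytesPerPx <- bps / 8L
  stripBytes <- ny * nx * bytesPerPx

  desc <- jsonlite::toJSON(list(channels = channels,
                                pixel_size_um = pixelSize),
                           auto_unbox = TRUE)
  descRaw <- c(charToRaw(as.character(desc)), as.raw(0L))
  if (length(descRaw) %% 2 == 1) descRaw <- c(descRaw, as.raw(0L))
  descBytes <- length(descRaw)

  dataOffsets <- 8L + (seq_len(nc) - 1L) * stripBytes
  descOffset <- 8L + nc * stripBytes
  nEntries <- ifelse(seq_len(nc) == 1L, 11L, 10L)
  ifdSizes <- 2L + 12L * nEntries + 4L
  ifdOffsets <- descOffset + descBytes + c(0L, cumsum(ifdSizes))[seq_len(nc)]

  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("II"), con)
  writeBin(42L, con, size = 2, endian = "little")
  writeBin(as.integer(ifdOffsets[1]), con, size = 4, endian = "little")

  for (c in seq_len(nc)) {
    page <- as.numeric(t(x[, , c]))  # TIFF is row-major
    if (dtype == "float32") {
      writeBin(page, con, size = 4, endian = "little")
    } else {
      page <- as.integer(round(pmax(0, pmin(65535, page))))
      writeBin(page, con, size = 2, endian = "little")
    }
  }
  writeBin(descRaw, con)

  writeEntry <- function(tag, type, count, value) {
    writeBin(as.integer(tag), con, size = 2, endian = "little")
    writeBin(as.integer(type), con, size = 2, endian = "little")
    writeBin(as.integer(count), con, size = 4, endian = "little")
    if (type == 3L && count == 1L) {  # SHORT packed left-justified
      writeBin(as.integer(value), con, size = 2, endian = "little")
      writeBin(0L, con, size = 2, endian = "little")
    } else {
      writeBin(as.integer(value), con, size = 4, endian = "little")
    }
  }

  for (c in seq_len(nc)) {
    entries <- list(
      list(256L, 3L, 1L, nx),
      list(257L, 3L, 1L, ny),
      list(258L, 3L, 1L, bps),
      list(259L, 3L, 1L, 1L),
      list(262L, 3L, 1L, 1L)
    )
    if (c == 1L) entries <- c(entries, list(list(270L, 2L, descBytes, descOffset)))
    entries <- c(entries, list(
      list(273L, 4L, 1L, dataOffsets[c]),
      list(277L, 3L, 1L, 1L),
      list(278L, 3L, 1L, ny),
      list(279L, 4L, 1L, stripBytes),
      list(339L, 3L, 1L, sampFmt)
    ))
    writeBin(length(entries), con, size = 2, endian = "little")
    for (e in entries) writeEntry(e[[1]], e[[2]], e[[3]], e[[4]])
    nextOff <- if (c < nc) ifdOffsets[c + 1] else 0L
    writeBin(as.integer(nextOff), con, size = 4, endian = "little")
  }
  invisible(path)
}

#' Read a multi-page TIFF written by this package
#'
#' Supports uncompressed little-endian TIFFs with 16-bit unsigned or 32-bit
#' float samples (one sample per pixel), possibly striped. Returns a
#' [ChannelStack] when the ImageDescription carries channel metadata,
#' otherwise a bare array.
#'
#' @param path TIFF file path.
#' @param asArray return the raw array even when metadata is present.
#' @return a [ChannelStack] or a `ny x nx x nc` array.
#' @export
readTiffStack <- function(path, asArray = FALSE) {
  raw <- readBin(path, "raw", n = file.info(path)$size)
  if (!(rawToChar(raw[1:2]) %in% c("II"))) {
    stop("only little-endian TIFF is supported")
  }
  u16 <- function(off) sum(as.integer(raw[off + 1:2]) * c(1, 256))
  u32 <- function(off) sum(as.numeric(raw[off + 1:4]) * c(1, 256, 65536, 16777216))
  ifdOff <- u32(4)
  pages <- list()
  meta <- NULL
  while (ifdOff != 0) {
    n <- u16(ifdOff)
    tags <- list()
    for (i in seq_len(n)) {
      e <- ifdOff + 2 + (i - 1) * 12
      tag <- u16(e)
      type <- u16(e + 2)
      count <- u32(e + 4)
      val <- if (type == 3L && count == 1L) u16(e + 8) else u32(e + 8)
      tags[[as.character(tag)]] <- list(type = type, count = count, val = val,
                                        off = e + 8)
    }
    getVals <- function(tag) {
      t <- tags[[as.character(tag)]]
      if (is.null(t)) return(NULL)
      if (t$count == 1L) return(t$val)
      sz <- if (t$type == 3L) 2 else 4
      vapply(seq_len(t$count) - 1, function(k) {
        if (t$type == 3L) u16(t$val + 2 * k) else u32(t$val + 4 * k)
      }, numeric(1))
    }
    nx <- getVals(256); ny <- getVals(257)
    bps <- getVals(258)
    if (!is.null(getVals(259)) && getVals(259) != 1) stop("compressed TIFF unsupported")
    offs <- getVals(273)
    counts <- getVals(279)
    fmt <- getVals(339); if (is.null(fmt)) fmt <- 1L
    if (!is.null(tags[["270"]]) && is.null(meta)) {
      t <- tags[["270"]]
      b <- raw[t$val + seq_len(t$count)]
      txt <- rawToChar(b[b != as.raw(0L)])
      meta <- tryCatch(jsonlite::fromJSON(txt), error = function(e) NULL)
    }
    buf <- unlist(lapply(seq_along(offs), function(k) {
      raw[offs[k] + seq_len(counts[k])]
    }))
    vals <- if (bps == 32 && fmt == 3) {
      readBin(buf, "numeric", n = nx * ny, size = 4, endian = "little")
    } else if (bps == 16 && fmt == 1) {
      readBin(buf, "integer", n = nx * ny, size = 2, signed = FALSE,
              endian = "little")
    } else stop("unsupported sample type: ", bps, "-bit format ", fmt)
    pages[[length(pages) + 1]] <- t(matrix(vals, nrow = nx, ncol = ny))
    nextOff <- u32(ifdOff + 2 + n * 12)
    ifdOff <- nextOff
  }
  arr <- array(unlist(pages), c(dim(pages[[1]]), length(pages)))
  if (asArray || is.null(meta) ||
      length(meta$channels) != length(pages)) {
    return(arr)
  }
  new("ChannelStack", data = arr, channels = as.character(meta$channels),
      pixelSize = as.numeric(meta$pixel_size_um))
}
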
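# Minimal baseline TIFF support: multi-page, single-sample grayscale,
# uncompressed. No image-IO package exists in this R installation, so the
# handful of baseline tags needed for scientific grayscale stacks is handled
# here directly. Supported on read: 8/16-bit unsigned and 32/64-bit float,
# II and MM byte order, multi-strip. Written: single strip per page, II.

.TAG <- c(ImageWidth = 256L, ImageLength = 257L, BitsPerSample = 258L,
          Compression = 259L, Photometric = 262L, StripOffsets = 273L,
          SamplesPerPixel = 277L, RowsPerStrip = 278L,
          StripByteCounts = 279L, SampleFormat = 339L)

.read_ifd_entries <- function(con, endian) {
  n <- readBin(con, "integer", 1, size = 2, signed = FALSE, endian = endian)
  entries <- vector("list", n)
  for (i in seq_len(n)) {
    tag <- readBin(con, "integer", 1, size = 2, signed = FALSE, endian = endian)
    type <- readBin(con, "integer", 1, size = 2, signed = FALSE, endian = endian)
    count <- readBin(con, "integer", 1, size = 4, endian = endian)
    raw4 <- readBin(con, "raw", 4)
    entries[[i]] <- list(tag = tag, type = type, count = count, raw = raw4)
  }
  nxt <- readBin(con, "integer", 1, size = 4, endian = endian)
  list(entries = entries, next_ifd = nxt)
}

.type_size <- function(type) {
  switch(as.character(type),
         "1" = 1L, "2" = 1L, "3" = 2L, "4" = 4L, "6" = 1L, "8" = 2L,
         "9" = 4L, "11" = 4L, "12" = 8L,
         stop("unsupported TIFF field type: ", type))
}

.entry_values <- function(con, e, endian) {
  sz <- .type_size(e$type)
  nbytes <- sz * e$count
  if (nbytes <= 4) {
    raw <- e$raw[seq_len(nbytes)]
  } else {
    offset <- readBin(e$raw, "integer", 1, size = 4, endian = endian)
    old <- seek(con)
    seek(con, offset)
    raw <- readBin(con, "raw", nbytes)
    seek(con, old)
  }
  switch(as.character(e$type),
    "3" = readBin(raw, "integer", e$count, size = 2, signed = FALSE,
                  endian = endian),
    "4" = readBin(raw, "integer", e$count, size = 4, endian = endian),
    "1" = as.integer(readBin(raw, "integer", e$count, size = 1,
                             signed = FALSE, endian = endian)),
    "11" = readBin(raw, "double", e$count, size = 4, endian = endian),
    "12" = readBin(raw, "double", e$count, size = 8, endian = endian),
    stop("unsupported TIFF field type: ", e$type))
}

.read_tiff_pages <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  order_bytes <- readBin(con, "raw", 2)
  order_str <- rawToChar(order_bytes)
  if (order_str == "II") endian <- "little"
  else if (order_str == "MM") endian <- "big"
  else stop("not a TIFF file (bad byte-order mark): ", path)
  magic <- readBin(con, "integer", 1, size = 2, signed = FALSE, endian = endian)
  if (magic != 42L) stop("not a TIFF file (bad magic number): ", path)
  ifd_off <- readBin(con, "integer", 1, size = 4, endian = endian)
  pages <- list()
  while (ifd_off != 0L) {
    seek(con, ifd_off)
    ifd <- .read_ifd_entries(con, endian)
    tags <- list()
    for (e in ifd$entries) {
      nm <- names(.TAG)[match(e$tag, .TAG)]
      if (!is.na(nm)) tags[[nm]] <- .entry_values(con, e, endian)
    }
    need <- c("ImageWidth", "ImageLength", "StripOffsets", "StripByteCounts")
    if (!all(need %in% names(tags)))
      stop("TIFF page missing required tags: ",
           paste(setdiff(need, names(tags)), collapse = ", "))
    bits <- if (is.null(tags$BitsPerSample)) 1L else tags$BitsPerSample[1]
    comp <- if (is.null(tags$Compression)) 1L else tags$Compression
    spp <- if (is.null(tags$SamplesPerPixel)) 1L else tags$SamplesPerPixel
    fmt <- if (is.null(tags$SampleFormat)) 1L else tags$SampleFormat[1]
    if (comp != 1L) stop("compressed TIFF not supported (Compression=", comp, ")")
    if (spp != 1L)
      stop("color/multi-sample TIFF not supported; expected grayscale ",
           "(SamplesPerPixel=", spp, ")")
    w <- tags$ImageWidth; h <- tags$ImageLength
    raw <- raw(0)
    for (k in seq_along(tags$StripOffsets)) {
      seek(con, tags$StripOffsets[k])
      raw <- c(raw, readBin(con, "raw", tags$StripByteCounts[k]))
    }
    npx <- as.numeric(w) * as.numeric(h)
    vals <- if (fmt == 3L && bits == 32L) {
      readBin(raw, "double", npx, size = 4, endian = endian)
    } else if (fmt == 3L && bits == 64L) {
      readBin(raw, "double", npx, size = 8, endian = endian)
    } else if (fmt %in% c(1L, 2L) && bits == 8L) {
      as.numeric(readBin(raw, "integer", npx, size = 1, signed = fmt == 2L,
                         endian = endian))
    } else if (fmt %in% c(1L, 2L) && bits == 16L) {
      as.numeric(readBin(raw, "integer", npx, size = 2, signed = fmt == 2L,
                         endian = endian))
    } else {
      stop("unsupported TIFF sample layout: ", bits, "-bit, SampleFormat=", fmt)
    }
    # TIFF stores row-major (rows of the image consecutively)
    pages[[length(pages) + 1L]] <- matrix(vals, nrow = h, ncol = w, byrow = TRUE)
    ifd_off <- ifd$next_ifd
  }
  if (!length(pages)) stop("TIFF file contains no images: ", path)
  pages
}

.u16 <- function(x) writeBin(as.integer(x), raw(), size = 2, endian = "little")
.u32 <- function(x) writeBin(as.integer(x), raw(), size = 4, endian = "little")

.ifd_entry <- function(tag, type, count, value_raw) {
  pad <- as.raw(rep(0, 4 - length(value_raw)))
  c(.u16(tag), .u16(type), .u32(count), value_raw, pad)
}

.write_tiff_pages <- function(pages, path, bitDepth = "float64") {
  spec <- switch(bitDepth,
    uint8 = list(bits = 8L, fmt = 1L, size = 1L),
    uint16 = list(bits = 16L, fmt = 1L, size = 2L),
    float32 = list(bits = 32L, fmt = 3L, size = 4L),
    float64 = list(bits = 64L, fmt = 3L, size = 8L),
    stop("bitDepth must be uint8, uint16, float32 or float64"))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("II"), con)
  writeBin(.u16(42L), con)
  pos <- 8L  # after header; first IFD offset patched below
  writeBin(.u32(0L), con)  # placeholder for first IFD offset
  pos <- 8L
  n <- length(pages)
  for (i in seq_len(n)) {
    m <- pages[[i]]
    h <- nrow(m); w <- ncol(m)
    nbytes <- as.integer(h * w * spec$size)
    data_off <- pos
    vals <- as.vector(t(m))  # row-major
    if (spec$fmt == 1L) {
      writeBin(as.integer(round(vals)), con, size = spec$size,
               endian = "little")
    } else {
      writeBin(as.numeric(vals), con, size = spec$size, endian = "little")
    }
    ifd_off <- data_off + nbytes
    entries <- list(
      .ifd_entry(256L, 4L, 1L, .u32(w)),
      .ifd_entry(257L, 4L, 1L, .u32(h)),
      .ifd_entry(258L, 3L, 1L, .u16(spec$bits)),
      .ifd_entry(259L, 3L, 1L, .u16(1L)),       # no compression
      .ifd_entry(262L, 3L, 1L, .u16(1L)),       # BlackIsZero
      .ifd_entry(273L, 4L, 1L, .u32(data_off)),
      .ifd_entry(277L, 3L, 1L, .u16(1L)),
      .ifd_entry(278L, 4L, 1L, .u32(h)),
      .ifd_entry(279L, 4L, 1L, .u32(nbytes)),
      .ifd_entry(339L, 3L, 1L, .u16(spec$fmt))
    )
    ifd_len <- 2L + 12L * length(entries) + 4L
    # the next IFD sits after the next page's pixel data
    next_off <- if (i < n) {
      nxt <- pages[[i + 1]]
      ifd_off + ifd_len +
        as.integer(nrow(nxt) * ncol(nxt) * spec$size)
    } else 0L
    writeBin(.u16(length(entries)), con)
    for (e in entries) writeBin(e, con)
    writeBin(.u32(next_off), con)
    pos <- ifd_off + ifd_len
  }
  # patch first IFD offset: data of page 1 starts at byte 8
  first_ifd <- 8L + as.integer(nrow(pages[[1]]) * ncol(pages[[1]]) * spec$size)
  seek(con, 4)
  writeBin(.u32(first_ifd), con)
  invisible(path)
}

#' Read a multi-page grayscale TIFF as a TimeLapseStack
#'
#' Frames are ordered by page (acquisition) order. The frame interval and
#' pixel size are supplied by the caller; vendor metadata dialects are not
#' parsed. Color (multi-sample), compressed or single-frame files raise an
#' error.
#'
#' @param path path to a multi-page grayscale TIFF.
#' @param frameIntervalS seconds between consecutive frames.
#' @param pixelSizeUm micrometers per pixel.
#' @param originName field-of-view label; defaults to the file name.
#' @return A [TimeLapseStack-class].
#' @seealso [writeStack()]
#' @export
readStack <- function(path, frameIntervalS, pixelSizeUm,
                      originName = basename(path)) {
  if (!file.exists(path)) stop("cannot read image file: ", path)
  pages <- .read_tiff_pages(path)
  if (length(pages) < 2L)
    stop("single-frame image; a time-lapse stack needs at least 2 frames: ",
         path)
  d1 <- dim(pages[[1]])
  if (!all(vapply(pages, function(p) identical(dim(p), d1), logical(1))))
    stop("TIFF pages differ in shape: ", path)
  arr <- array(0, c(length(pages), d1[1], d1[2]))
  for (i in seq_along(pages)) arr[i, , ] <- pages[[i]]
  TimeLapseStack(arr, frameIntervalS, pixelSizeUm, originName)
}

#' Write a TimeLapseStack as a multi-page grayscale TIFF
#'
#' The default 64-bit float samples round-trip any R double exactly
#' (`readStack(writeStack(x)) == x` pixel for pixel); `uint8`/`uint16`
#' round values to integers.
#'
#' @param stack a [TimeLapseStack-class].
#' @param path output path.
#' @param bitDepth one of `"float64"` (default), `"float32"`, `"uint16"`,
#'   `"uint8"`.
#' @return `path`, invisibly.
#' @export
writeStack <- function(stack, path, bitDepth = "float64") {
  stopifnot(is(stack, "TimeLapseStack"))
  pages <- lapply(seq_len(nFrames(stack)), function(i) getFrame(stack, i))
  .write_tiff_pages(pages, path, bitDepth = bitDepth)
  invisible(path)
}
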
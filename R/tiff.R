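# Minimal classic-TIFF codec: uncompressed, single-band, strip-organised,
# little- or big-endian, with the GeoTIFF tags needed for a geographic grid
# (ModelPixelScale, ModelTiepoint, GeoKeyDirectory) and the GDAL nodata tag.
# No R GeoTIFF bindings are available in this package's dependency set, so
# the format is handled here directly; interoperability is exercised against
# an independent TIFF implementation in the test suite.

TIFF_TYPE_SIZES <- c(`1` = 1L, `2` = 1L, `3` = 2L, `4` = 4L, `11` = 4L, `12` = 8L)

.rd <- function(raw, offset, what, n, size, endian, signed = TRUE) {
  readBin(raw[(offset + 1):(offset + n * size)], what = what, n = n,
          size = size, endian = endian, signed = signed)
}

tiff_read_raw <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- readBin(path, "raw", n = file.info(path)$size)
  if (length(raw) < 8) stop("not a TIFF file: ", path)
  order_tag <- rawToChar(raw[1:2])
  endian <- switch(order_tag, II = "little", MM = "big",
                   stop("not a TIFF file (bad byte order mark): ", path))
  magic <- .rd(raw, 2, integer(), 1, 2, endian)
  if (magic != 42L) stop("not a classic TIFF file: ", path)
  ifd_offset <- .rd(raw, 4, integer(), 1, 4, endian)
  n_entries <- .rd(raw, ifd_offset, integer(), 1, 2, endian)
  tags <- list()
  for (i in seq_len(n_entries)) {
    base <- ifd_offset + 2 + (i - 1) * 12
    tag <- .rd(raw, base, integer(), 1, 2, endian, signed = FALSE)
    type <- .rd(raw, base + 2, integer(), 1, 2, endian)
    count <- .rd(raw, base + 4, integer(), 1, 4, endian)
    size <- TIFF_TYPE_SIZES[as.character(type)]
    if (is.na(size)) next  # unknown tag type: skip
    nbytes <- size * count
    value_off <- if (nbytes <= 4) base + 8 else .rd(raw, base + 8, integer(), 1, 4, endian)
    value <- switch(as.character(type),
      `1` = .rd(raw, value_off, integer(), count, 1, endian, signed = FALSE),
      `2` = {
        txt <- raw[(value_off + 1):(value_off + count)]
        nul <- which(txt == as.raw(0))
        if (length(nul)) txt <- txt[seq_len(nul[1] - 1L)]
        rawToChar(txt)
      },
      `3` = .rd(raw, value_off, integer(), count, 2, endian, signed = FALSE),
      `4` = .rd(raw, value_off, integer(), count, 4, endian),
      `11` = .rd(raw, value_off, double(), count, 4, endian),
      `12` = .rd(raw, value_off, double(), count, 8, endian))
    tags[[as.character(tag)]] <- value
  }
  list(raw = raw, endian = endian, tags = tags)
}

tiff_tag <- function(tf, id, default = NULL) {
  v <- tf$tags[[as.character(id)]]
  if (is.null(v)) default else v
}

# Returns list(values = matrix, spec-ish geo fields, nodata, sample_format)
tiff_read <- function(path) {
  tf <- tiff_read_raw(path)
  width <- tiff_tag(tf, 256)
  height <- tiff_tag(tf, 257)
  if (is.null(width) || is.null(height)) stop("TIFF missing image dimensions: ", path)
  spp <- tiff_tag(tf, 277, 1L)
  if (spp != 1L)
    stop("multi-band TIFF not supported (SamplesPerPixel = ", spp, "): ", path)
  compression <- tiff_tag(tf, 259, 1L)
  if (compression != 1L)
    stop("compressed TIFF not supported (Compression = ", compression, "): ", path)
  bits <- tiff_tag(tf, 258, 1L)
  fmt <- tiff_tag(tf, 339, 1L)  # 1 uint, 2 int, 3 float
  strip_offsets <- tiff_tag(tf, 273)
  strip_counts <- tiff_tag(tf, 279)
  if (is.null(strip_offsets) || is.null(strip_counts))
    stop("TIFF missing strip layout: ", path)
  size <- bits %/% 8L
  vals <- numeric(0)
  for (k in seq_along(strip_offsets)) {
    n <- strip_counts[k] %/% size
    piece <- switch(as.character(fmt),
      `1` = .rd(tf$raw, strip_offsets[k], integer(), n, size, tf$endian,
                signed = size < 2),
      `2` = .rd(tf$raw, strip_offsets[k], integer(), n, size, tf$endian,
                signed = TRUE),
      `3` = .rd(tf$raw, strip_offsets[k], double(), n, size, tf$endian),
      stop("unsupported TIFF sample format: ", fmt))
    if (fmt == 1L && size == 2L) {  # readBin cannot do unsigned 16-bit directly
      piece <- .rd(tf$raw, strip_offsets[k], integer(), n, 2, tf$endian,
                   signed = TRUE)
      piece <- ifelse(piece < 0, piece + 65536, piece)
    }
    vals <- c(vals, piece)
  }
  if (length(vals) != width * height)
    stop("TIFF pixel count mismatch in ", path)
  values <- matrix(vals, nrow = height, ncol = width, byrow = TRUE)

  scale <- tiff_tag(tf, 33550)    # (sx, sy, sz)
  tiepoint <- tiff_tag(tf, 33922) # (i, j, k, x, y, z)
  nodata_txt <- tiff_tag(tf, 42113)
  geo <- NULL
  if (!is.null(scale) && !is.null(tiepoint)) {
    # cell-center registration recovered from raster-space tiepoint (i, j)
    xmin <- tiepoint[4] - tiepoint[1] * scale[1]
    ymax <- tiepoint[5] + tiepoint[2] * scale[2]
    geo <- list(cell_size = scale[1], xmin = xmin, ymax = ymax)
  }
  list(values = values, geo = geo,
       nodata = if (is.null(nodata_txt)) NULL else as.numeric(nodata_txt),
       sample_format = fmt, bits = bits)
}

.u16 <- function(x) writeBin(as.integer(x), raw(), size = 2, endian = "little")
.u32 <- function(x) writeBin(as.integer(x), raw(), size = 4, endian = "little")
.f64 <- function(x) writeBin(as.numeric(x), raw(), size = 8, endian = "little")

# type: 3 = SHORT, 4 = LONG, 2 = ASCII, 12 = DOUBLE
tiff_entry <- function(tag, type, count, value_raw, extra_offset = NULL) {
  stopifnot(length(value_raw) <= 4 || !is.null(extra_offset))
  payload <- if (length(value_raw) <= 4) {
    c(value_raw, raw(4 - length(value_raw)))
  } else {
    .u32(extra_offset)
  }
  c(.u16(tag), .u16(type), .u32(count), payload)
}

# values: numeric matrix (row 1 = top). type: "int16", "float32", "float64".
tiff_write <- function(path, values, cell_size, xmin, ymax,
                       type = c("int16", "float32", "float64"),
                       nodata = NULL) {
  type <- match.arg(type)
  height <- nrow(values)
  width <- ncol(values)
  px <- as.vector(t(values))  # row-major
  size <- switch(type, int16 = 2L, float32 = 4L, float64 = 8L)
  fmt <- switch(type, int16 = 2L, float32 = 3L, float64 = 3L)
  bits <- size * 8L

  pixel_raw <- if (type == "int16") {
    writeBin(as.integer(px), raw(), size = 2, endian = "little")
  } else {
    writeBin(as.numeric(px), raw(), size = size, endian = "little")
  }

  geo_scale <- .f64(c(cell_size, cell_size, 0))
  geo_tie <- .f64(c(0, 0, 0, xmin, ymax, 0))
  # GTModelType = geographic, GTRasterType = PixelIsArea, GeographicType = WGS84
  geo_keys <- .u16(c(1, 1, 0, 3,
                     1024, 0, 1, 2,
                     1025, 0, 1, 1,
                     2048, 0, 1, 4326))
  nodata_raw <- if (!is.null(nodata)) {
    c(charToRaw(format(nodata, scientific = FALSE)), as.raw(0))
  }

  tags <- list(
    list(tag = 256, type = 4L, count = 1L, inline = .u32(width)),
    list(tag = 257, type = 4L, count = 1L, inline = .u32(height)),
    list(tag = 258, type = 3L, count = 1L, inline = .u16(bits)),
    list(tag = 259, type = 3L, count = 1L, inline = .u16(1)),
    list(tag = 262, type = 3L, count = 1L, inline = .u16(1)),
    list(tag = 273, type = 4L, count = 1L, inline = NULL, data = pixel_raw),
    list(tag = 277, type = 3L, count = 1L, inline = .u16(1)),
    list(tag = 278, type = 4L, count = 1L, inline = .u32(height)),
    list(tag = 279, type = 4L, count = 1L, inline = .u32(length(pixel_raw))),
    list(tag = 339, type = 3L, count = 1L, inline = .u16(fmt)),
    list(tag = 33550, type = 12L, count = 3L, inline = NULL, data = geo_scale),
    list(tag = 33922, type = 12L, count = 6L, inline = NULL, data = geo_tie),
    list(tag = 34735, type = 3L, count = 16L, inline = NULL, data = geo_keys))
  if (!is.null(nodata_raw))
    tags <- c(tags, list(list(tag = 42113, type = 2L,
                              count = length(nodata_raw), inline = NULL,
                              data = nodata_raw)))

  n <- length(tags)
  ifd_size <- 2L + n * 12L + 4L
  data_start <- 8L + ifd_size
  # lay out out-of-line blocks in tag order, word-aligned
  offset <- data_start
  for (i in seq_along(tags)) {
    if (!is.null(tags[[i]]$data)) {
      if (offset %% 2L == 1L) offset <- offset + 1L
      tags[[i]]$offset <- offset
      offset <- offset + length(tags[[i]]$data)
    }
  }

  entries <- raw(0)
  for (t in tags) {
    if (!is.null(t$inline)) {
      entries <- c(entries, tiff_entry(t$tag, t$type, t$count, t$inline))
    } else {
      # strip-offset tag points at the pixel block itself
      val <- if (t$tag == 273) .u32(t$offset) else NULL
      if (!is.null(val)) {
        entries <- c(entries, tiff_entry(t$tag, t$type, t$count, val))
      } else {
        entries <- c(entries, tiff_entry(t$tag, t$type, t$count, raw(5),
                                         extra_offset = t$offset))
      }
    }
  }

  body <- raw(offset - data_start)
  for (t in tags) {
    if (!is.null(t$data))
      body[(t$offset - data_start + 1):(t$offset - data_start + length(t$data))] <-
        t$data
  }

  out <- c(charToRaw("II"), .u16(42), .u32(8),  # IFD immediately after header
           .u16(n), entries, .u32(0), body)
  writeBin(out, path)
  invisible(path)
}
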
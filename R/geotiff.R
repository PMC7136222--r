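#' Read a scaled-integer GeoTIFF into a layer
#'
#' Reads a single-band GeoTIFF whose stored integers encode physical values
#' as `value = stored * scale_factor` — the encoding used by the final data
#' products (16-bit integers with scale factor 0.1, i.e. one decimal of
#' MgC ha^-1 per quantum). Float rasters are read unchanged apart from the
#' scale factor. The file's nodata tag is honoured; if the tag is absent a
#' warning is emitted and every cell is treated as valid.
#'
#' @param path Path to a single-band GeoTIFF.
#' @param scale_factor Positive multiplier applied to stored values
#'   (default 1).
#' @return A [layer()].
#' @seealso [write_scaled_int_geotiff()]
#' @export
read_scaled_int_geotiff <- function(path, scale_factor = 1) {
  if (!is.numeric(scale_factor) || scale_factor <= 0)
    stop("scale_factor must be > 0")
  tf <- tiff_read(path)
  values <- tf$values
  if (is.null(tf$nodata)) {
    warning("no nodata tag in ", path, "; treating all cells as valid")
  } else if (tf$nodata == 0) {
    values[values == 0] <- NA_real_
  } else {
    # float32 storage perturbs the sentinel; match with a relative tolerance
    values[abs(values - tf$nodata) <= abs(tf$nodata) * 1e-6] <- NA_real_
  }
  values <- values * scale_factor
  if (is.null(tf$geo))
    stop("TIFF lacks georeferencing tags: ", path)
  g <- grid_spec(nrow(values), ncol(values), cell_size = tf$geo$cell_size,
                 xmin = tf$geo$xmin, ymax = tf$geo$ymax)
  layer(values, g)
}

# round half away from zero: the encoding rule for integer products
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Write a layer as a scaled int16 GeoTIFF
#'
#' Encodes `round(value / scale_factor)` (rounding half away from zero) as
#' 16-bit signed integers with the nodata sentinel -32768. Values that do not
#' fit the int16 range after scaling abort the write with a count of the
#' offending cells.
#'
#' @param lyr A numeric [layer()].
#' @param path Output path.
#' @param scale_factor Positive scale; stored integer is
#'   `value / scale_factor` rounded.
#' @param nodata Integer sentinel written for `NA` cells (default -32768).
#' @return The path, invisibly.
#' @export
write_scaled_int_geotiff <- function(lyr, path, scale_factor = 0.1,
                                     nodata = -32768L) {
  stopifnot(is_layer(lyr), is.numeric(lyr$values))
  if (!is.numeric(scale_factor) || scale_factor <= 0)
    stop("scale_factor must be > 0")
  # pre-round to 9 decimals so binary representation error cannot push a
  # decimal halfway case (e.g. 42.15 / 0.1) to the wrong side
  ints <- round_half_away(round(lyr$values / scale_factor, 9))
  over <- !is.na(ints) & (ints > 32767 | ints < -32767)
  if (any(over))
    stop(sum(over), " cell(s) overflow the int16 range at scale ",
         scale_factor)
  ints[is.na(ints)] <- nodata
  g <- lyr$grid
  tiff_write(path, ints, cell_size = g$cell_size, xmin = g$xmin,
             ymax = g$ymax, type = "int16", nodata = nodata)
  invisible(path)
}

#' Write a layer as a float32 GeoTIFF (intermediate products)
#'
#' @inheritParams write_scaled_int_geotiff
#' @param nodata Numeric sentinel for `NA` cells (default -3.4e38).
#' @return The path, invisibly.
#' @export
write_float_geotiff <- function(lyr, path, nodata = -3.4e38) {
  stopifnot(is_layer(lyr), is.numeric(lyr$values))
  vals <- lyr$values
  vals[is.na(vals)] <- nodata
  g <- lyr$grid
  tiff_write(path, vals, cell_size = g$cell_size, xmin = g$xmin,
             ymax = g$ymax, type = "float32", nodata = nodata)
  invisible(path)
}
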
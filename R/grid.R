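#' Geographic grid specification
#'
#' Defines a regular geographic (lon/lat) grid by its dimensions, cell size in
#' degrees and the coordinates of the upper-left corner. Cell-center
#' registration is used throughout: row 1 is the northernmost row and the
#' center of cell (r, c) is at
#' `(xmin + (c - 0.5) * cell_size, ymax - (r - 0.5) * cell_size)`.
#'
#' Two layers may only be combined when their grid specs are identical; all
#' raster algebra in this package checks this invariant.
#'
#' @param n_rows,n_cols Grid dimensions (positive integers).
#' @param cell_size Cell edge length in degrees (> 0).
#' @param xmin Longitude of the left edge of the grid (degrees).
#' @param ymax Latitude of the top edge of the grid (degrees).
#' @param crs_id Identifier of the coordinate reference system. Only
#'   geographic WGS84 is supported; the default is `"EPSG:4326"`.
#' @return An object of class `grid_spec`.
#' @examples
#' g <- grid_spec(10, 20, cell_size = 0.25, xmin = 10, ymax = 66)
#' row_latitudes(g)[1:3]
#' @export
grid_spec <- function(n_rows, n_cols, cell_size, xmin = 0, ymax = 0,
                      crs_id = "EPSG:4326") {
  stopifnot(length(n_rows) == 1, length(n_cols) == 1, length(cell_size) == 1)
  n_rows <- as.integer(n_rows)
  n_cols <- as.integer(n_cols)
  if (is.na(n_rows) || is.na(n_cols) || n_rows < 1L || n_cols < 1L)
    stop("grid dimensions must be >= 1")
  if (!is.finite(cell_size) || cell_size <= 0)
    stop("cell_size must be > 0")
  structure(
    list(n_rows = n_rows, n_cols = n_cols,
         cell_size = as.numeric(cell_size),
         xmin = as.numeric(xmin), ymax = as.numeric(ymax),
         crs_id = crs_id),
    class = "grid_spec")
}

#' @export
format.grid_spec <- function(x, ...) {
  sprintf("<grid_spec %d x %d @ %g deg, UL (%g, %g), %s>",
          x$n_rows, x$n_cols, x$cell_size, x$xmin, x$ymax, x$crs_id)
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' @rdname grid_spec
#' @param a,b Grid specs to compare.
#' @export
same_grid <- function(a, b) {
  stopifnot(inherits(a, "grid_spec"), inherits(b, "grid_spec"))
  a$n_rows == b$n_rows && a$n_cols == b$n_cols &&
    isTRUE(all.equal(a$cell_size, b$cell_size)) &&
    isTRUE(all.equal(a$xmin, b$xmin)) &&
    isTRUE(all.equal(a$ymax, b$ymax)) &&
    identical(a$crs_id, b$crs_id)
}

#' @rdname grid_spec
#' @param grid A `grid_spec`.
#' @return `row_latitudes()`: numeric vector of cell-center latitudes, one per
#'   row, north to south. `col_longitudes()`: cell-center longitudes.
#' @export
row_latitudes <- function(grid) {
  grid$ymax - (seq_len(grid$n_rows) - 0.5) * grid$cell_size
}

#' @rdname grid_spec
#' @export
col_longitudes <- function(grid) {
  grid$xmin + (seq_len(grid$n_cols) - 0.5) * grid$cell_size
}

stop_if_grid_mismatch <- function(a, b, what = "layers") {
  if (!same_grid(a, b))
    stop("grid mismatch: ", what, " must share an identical grid_spec")
  invisible(TRUE)
}

#' Single-band raster layer
#'
#' A layer couples a values matrix to a [grid_spec()]. Missing cells are
#' represented by `NA` in the matrix (the idiomatic R equivalent of a nodata
#' mask). Values must be finite wherever not `NA`; character matrices are
#' permitted for thematic (label) layers.
#'
#' @param values Matrix with `grid$n_rows` rows and `grid$n_cols` columns.
#'   A scalar is recycled to a constant layer.
#' @param grid A [grid_spec()].
#' @return An object of class `carb_layer` with elements `grid` and `values`.
#' @examples
#' g <- grid_spec(2, 2, 1, 0, 2)
#' layer(matrix(1:4, 2, 2), g)
#' @export
layer <- function(values, grid) {
  stopifnot(inherits(grid, "grid_spec"))
  if (length(values) == 1L)
    values <- matrix(values, grid$n_rows, grid$n_cols)
  if (!is.matrix(values))
    stop("values must be a matrix")
  if (nrow(values) != grid$n_rows || ncol(values) != grid$n_cols)
    stop(sprintf("values shape %d x %d does not match grid %d x %d",
                 nrow(values), ncol(values), grid$n_rows, grid$n_cols))
  if (is.numeric(values) && any(!is.finite(values) & !is.na(values)))
    stop("values must be finite wherever not NA")
  structure(list(grid = grid, values = values), class = "carb_layer")
}

#' @export
print.carb_layer <- function(x, ...) {
  cat("<carb_layer>", format(x$grid), "\n")
  n_na <- sum(is.na(x$values))
  if (is.numeric(x$values)) {
    rng <- if (all(is.na(x$values))) c(NA, NA) else range(x$values, na.rm = TRUE)
    cat(sprintf("  range [%g, %g], %d nodata cells\n", rng[1], rng[2], n_na))
  } else {
    cat(sprintf("  thematic, %d nodata cells\n", n_na))
  }
  invisible(x)
}

#' @rdname layer
#' @param x Object to test.
#' @export
is_layer <- function(x) inherits(x, "carb_layer")

#' Layer of (mean, standard error) pairs
#'
#' The central container for uncertain rasters: a mean layer and a standard
#' error layer on the same grid. The SE layer must be non-negative wherever
#' valid, and the nodata patterns are unified (a cell missing in either
#' component is missing in both).
#'
#' @param mean A [layer()] of means, or a numeric matrix.
#' @param se A [layer()] of standard errors (same grid), a matrix, or a
#'   scalar (recycled).
#' @param grid Grid spec, required when `mean` is given as a bare matrix.
#' @return An object of class `uncertain_layer` with elements `mean` and `se`
#'   (both `carb_layer`).
#' @examples
#' g <- grid_spec(2, 2, 1, 0, 2)
#' uncertain_layer(matrix(1:4, 2, 2), 0.5, grid = g)
#' @export
uncertain_layer <- function(mean, se = 0, grid = NULL) {
  if (!is_layer(mean)) {
    stopifnot(!is.null(grid))
    mean <- layer(mean, grid)
  }
  if (!is_layer(se)) se <- layer(se, mean$grid)
  stop_if_grid_mismatch(mean$grid, se$grid, "mean and se")
  if (any(se$values < 0, na.rm = TRUE))
    stop("standard errors must be >= 0")
  miss <- is.na(mean$values) | is.na(se$values)
  mean$values[miss] <- NA_real_
  se$values[miss] <- NA_real_
  structure(list(mean = mean, se = se), class = "uncertain_layer")
}

#' @export
print.uncertain_layer <- function(x, ...) {
  cat("<uncertain_layer>", format(x$mean$grid), "\n")
  invisible(x)
}

#' @rdname uncertain_layer
#' @param x Object to test.
#' @export
is_uncertain_layer <- function(x) inherits(x, "uncertain_layer")

#' Scalar or vector (mean, standard error) pair
#'
#' Lightweight value-with-uncertainty container used by the closed-form
#' propagation functions. Fields are vectorized so the same algebra applies
#' to scalars and to whole unwound rasters.
#'
#' @param mean Numeric vector of means.
#' @param se Numeric vector of standard errors (recycled; must be >= 0).
#' @return An object of class `uval` (a list with `mean` and `se`).
#' @examples
#' uval(100, 10)
#' @export
uval <- function(mean, se = 0) {
  se <- rep_len(se, length(mean))
  if (any(se < 0, na.rm = TRUE)) stop("se must be >= 0")
  structure(list(mean = as.numeric(mean), se = as.numeric(se)), class = "uval")
}

#' @export
print.uval <- function(x, ...) {
  cat("<uval> mean:", format(utils::head(x$mean, 5)),
      " se:", format(utils::head(x$se, 5)), "\n")
  invisible(x)
}
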
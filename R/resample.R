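# Aggregation and resampling on geographic grids. Cell areas on an
# equirectangular grid shrink with cos(latitude); all "area weighted"
# operations here use the cosine of the fine cell-center latitude as the
# weight, the standard proxy short of true ellipsoidal cell geometry.

# pad a matrix with NA on the bottom/right so block divides both dimensions
pad_to_block <- function(values, block) {
  nr <- ceiling(nrow(values) / block) * block
  nc <- ceiling(ncol(values) / block) * block
  if (nr == nrow(values) && nc == ncol(values)) return(values)
  out <- matrix(values[1][NA], nr, nc)
  out[seq_len(nrow(values)), seq_len(ncol(values))] <- values
  out
}

block_aggregate <- function(lyr, block, cell_fun) {
  stopifnot(is_layer(lyr), is.numeric(lyr$values))
  block <- as.integer(block)
  if (is.na(block) || block < 1L) stop("block must be a positive integer")
  if (block == 1L) return(lyr)
  g <- lyr$grid
  vals <- pad_to_block(lyr$values, block)
  lat <- g$ymax - (seq_len(nrow(vals)) - 0.5) * g$cell_size
  w_row <- cos(lat * pi / 180)
  nr_out <- nrow(vals) %/% block
  nc_out <- ncol(vals) %/% block
  out <- matrix(NA_real_, nr_out, nc_out)
  for (i in seq_len(nr_out)) {
    rows <- ((i - 1) * block + 1):(i * block)
    wr <- w_row[rows]
    for (j in seq_len(nc_out)) {
      cols <- ((j - 1) * block + 1):(j * block)
      v <- vals[rows, cols]
      w <- matrix(wr, block, block)[!is.na(v)]
      v <- v[!is.na(v)]
      if (length(v)) out[i, j] <- cell_fun(v, w)
    }
  }
  g_out <- grid_spec(nr_out, nc_out, cell_size = g$cell_size * block,
                     xmin = g$xmin, ymax = g$ymax, crs_id = g$crs_id)
  layer(out, g_out)
}

#' Area-weighted block aggregation of a layer
#'
#' Coarsens a layer by an integer factor. Each coarse cell is the
#' cos(latitude)-weighted mean of the valid fine cells it contains; blocks
#' with no valid cell become nodata. Grids whose dimensions are not a
#' multiple of `block` are padded with nodata at the south/east edges, so
#' partial edge blocks aggregate over their available cells with renormalised
#' weights.
#'
#' @param lyr A numeric [layer()].
#' @param block Integer aggregation factor (>= 1).
#' @return A [layer()] on the coarsened grid (cell size multiplied by
#'   `block`, same upper-left origin).
#' @seealso [aggregate_rms()] for the matching standard-error aggregation.
#' @export
aggregate_area_weighted_mean <- function(lyr, block) {
  block_aggregate(lyr, block, function(v, w) sum(w * v) / sum(w))
}

#' Root-mean-square aggregation of a standard-error layer
#'
#' Coarsens an SE layer by the quadrature-consistent rule: the coarse SE is
#' the square root of the area-weighted mean of the fine squared SEs,
#' `sqrt(sum(w * se^2) / sum(w))`. This equals mean-aggregating `se^2` and
#' taking the square root, which keeps aggregated uncertainty consistent with
#' summation in quadrature.
#'
#' @inheritParams aggregate_area_weighted_mean
#' @return A [layer()] on the coarsened grid.
#' @export
aggregate_rms <- function(lyr, block) {
  if (any(lyr$values < 0, na.rm = TRUE))
    stop("negative standard errors in input layer")
  block_aggregate(lyr, block, function(v, w) sqrt(sum(w * v^2) / sum(w)))
}

#' Bilinear resampling onto a target grid
#'
#' Interpolates between the four nearest source cell centers for each target
#' cell center. Nodata neighbours are excluded and the remaining weights
#' renormalised; target cells with no valid neighbour become nodata. Target
#' centers outside the source cell-center hull are clamped to the border
#' (constant extrapolation by at most half a source cell).
#'
#' @param lyr A numeric [layer()].
#' @param target A [grid_spec()] overlapping the source extent.
#' @return A [layer()] on `target`.
#' @export
resample_bilinear <- function(lyr, target) {
  stopifnot(is_layer(lyr), inherits(target, "grid_spec"))
  g <- lyr$grid
  if (same_grid(g, target)) return(layer(lyr$values, target))
  src_xmax <- g$xmin + g$n_cols * g$cell_size
  src_ymin <- g$ymax - g$n_rows * g$cell_size
  tgt_xmax <- target$xmin + target$n_cols * target$cell_size
  tgt_ymin <- target$ymax - target$n_rows * target$cell_size
  if (target$xmin >= src_xmax || tgt_xmax <= g$xmin ||
      target$ymax <= src_ymin || tgt_ymin >= g$ymax)
    stop("target grid does not overlap the source extent")

  # fractional row/col position of target centers in source index space
  tx <- (col_longitudes(target) - g$xmin) / g$cell_size + 0.5
  ty <- (g$ymax - row_latitudes(target)) / g$cell_size + 0.5
  clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)
  tx <- clamp(tx, 1, g$n_cols)
  ty <- clamp(ty, 1, g$n_rows)
  x0 <- floor(tx); x1 <- pmin(x0 + 1, g$n_cols); fx <- tx - x0
  y0 <- floor(ty); y1 <- pmin(y0 + 1, g$n_rows); fy <- ty - y0

  v <- lyr$values
  out <- matrix(NA_real_, target$n_rows, target$n_cols)
  for (i in seq_len(target$n_rows)) {
    r0 <- y0[i]; r1 <- y1[i]; wy <- fy[i]
    vv <- rbind(v[r0, ], v[r1, ])
    for (j in seq_len(target$n_cols)) {
      c0 <- x0[j]; c1 <- x1[j]; wx <- fx[j]
      nb <- c(vv[1, c0], vv[1, c1], vv[2, c0], vv[2, c1])
      w <- c((1 - wy) * (1 - wx), (1 - wy) * wx, wy * (1 - wx), wy * wx)
      ok <- !is.na(nb)
      sw <- sum(w[ok])
      if (any(ok) && sw > 0)
        out[i, j] <- sum(w[ok] * nb[ok]) / sw
    }
  }
  layer(out, target)
}
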
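# Cropland biomass carbon from crop yields and morphological parameters,
# harvested-area weighting with a harvest-frequency correction, and the
# robust (Theil-Sen) productivity-trend correction from the yield epoch to
# the map epoch, with bootstrap uncertainty.

#' Crop parameter set
#'
#' Per-crop morphological parameters: `omega`, the dry-matter fraction of
#' harvested biomass; `h`, the harvest index (fraction of total aboveground
#' biomass collected at harvest); `c`, the carbon fraction of harvested dry
#' mass; `r`, the root-to-shoot ratio. The published constants 0.451 and
#' 1.025 inside the conversion formulas already embed a 2.5%
#' field-to-farmgate harvest loss and a 44% carbon content of residues and
#' roots; no separate parameters exist for those.
#'
#' @param crop_id Crop identifier.
#' @param omega,h,c Fractions in `(0, 1]`.
#' @param r Root-to-shoot ratio (> 0).
#' @return A one-row data frame of class `crop_parameters`.
#' @export
crop_parameters <- function(crop_id, omega, h, c, r) {
  if (any(c(omega, h, c) <= 0 | c(omega, h, c) > 1))
    stop("omega, h and c must be in (0, 1]")
  if (r <= 0) stop("r must be > 0")
  structure(data.frame(crop_id = crop_id, omega = omega, h = h, c = c, r = r,
                       stringsAsFactors = FALSE),
            class = c("crop_parameters", "data.frame"))
}

#' Aboveground crop biomass carbon from yield
#'
#' `AGBC = y * omega * (0.451 / h + 1.025 * c - 0.451)` in MgC ha^-1, the
#' simplified yield-to-carbon conversion (maximum standing biomass inferred
#' from annual aboveground productivity).
#'
#' @param y Crop yield, Mg ha^-1 (vectorized).
#' @param params A [crop_parameters()] row (or anything with `omega`, `h`,
#'   `c`).
#' @return AGBC, MgC ha^-1.
#' @export
crop_agbc <- function(y, params) {
  if (params$h <= 0) stop("harvest index h must be > 0")
  y * params$omega * (0.451 / params$h + 1.025 * params$c - 0.451)
}

#' Belowground crop biomass carbon from yield
#'
#' `BGBC = 0.451 * y * r / h` in MgC ha^-1.
#'
#' @param y Crop yield, Mg ha^-1 (vectorized).
#' @param params A [crop_parameters()] row (or anything with `r`, `h`).
#' @return BGBC, MgC ha^-1.
#' @export
crop_bgbc <- function(y, params) {
  if (params$h <= 0) stop("harvest index h must be > 0")
  0.451 * y * params$r / params$h
}

#' Per-crop yield and harvested-area stack
#'
#' @param yields Named list of yield [layer()]s (Mg ha^-1), one per crop.
#' @param areas Named list of harvested-area [layer()]s (ha), same names.
#' @param extent Cropland-extent [layer()] (ha per cell).
#' @param parameters Data frame of [crop_parameters()] rows covering every
#'   crop name.
#' @return An object of class `crop_stack`.
#' @export
crop_stack <- function(yields, areas, extent, parameters) {
  stopifnot(is_layer(extent), length(yields) == length(areas),
            all(names(yields) == names(areas)))
  g <- extent$grid
  for (l in c(yields, areas)) {
    stopifnot(is_layer(l))
    stop_if_grid_mismatch(g, l$grid)
    if (any(l$values < 0, na.rm = TRUE))
      stop("yields and areas must be >= 0")
  }
  miss <- setdiff(names(yields), parameters$crop_id)
  if (length(miss)) stop("no parameters for crop(s): ",
                         paste(miss, collapse = ", "))
  structure(list(yields = yields, areas = areas, extent = extent,
                 parameters = parameters),
            class = "crop_stack")
}

#' Cell-level crop carbon totals and harvest frequency
#'
#' Computes the harvested-area-weighted average of per-crop AGBC and BGBC in
#' each cell, plus the harvest frequency `f` (total harvested area over
#' cropland extent). Where `f > 1`, multiple harvests are assumed and both
#' AGBC and BGBC are divided by `f` so estimates do not exceed maximum
#' standing biomass; `f <= 1` leaves values unchanged. Cells with harvested
#' area but zero extent become nodata with a warning.
#'
#' @param stack A [crop_stack()].
#' @return List of three [layer()]s: `agbc`, `bgbc` (MgC ha^-1) and `f`.
#' @export
cell_crop_totals <- function(stack) {
  stopifnot(inherits(stack, "crop_stack"))
  g <- stack$extent$grid
  area_sum <- matrix(0, g$n_rows, g$n_cols)
  agbc_sum <- matrix(0, g$n_rows, g$n_cols)
  bgbc_sum <- matrix(0, g$n_rows, g$n_cols)
  for (crop in names(stack$yields)) {
    p <- stack$parameters[stack$parameters$crop_id == crop, ]
    y <- stack$yields[[crop]]$values
    a <- stack$areas[[crop]]$values
    ok <- !is.na(y) & !is.na(a)
    area_sum[ok] <- area_sum[ok] + a[ok]
    agbc_sum[ok] <- agbc_sum[ok] + a[ok] * crop_agbc(y[ok], p)
    bgbc_sum[ok] <- bgbc_sum[ok] + a[ok] * crop_bgbc(y[ok], p)
  }
  agbc <- ifelse(area_sum > 0, agbc_sum / area_sum, 0)
  bgbc <- ifelse(area_sum > 0, bgbc_sum / area_sum, 0)
  ext <- stack$extent$values
  f <- matrix(NA_real_, g$n_rows, g$n_cols)
  has_ext <- !is.na(ext) & ext > 0
  f[has_ext] <- area_sum[has_ext] / ext[has_ext]
  f[!is.na(ext) & ext == 0 & area_sum == 0] <- 0
  bad <- !is.na(ext) & ext == 0 & area_sum > 0
  if (any(bad)) {
    warning(sum(bad), " cell(s) report harvested area on zero cropland ",
            "extent -> nodata")
    agbc[bad] <- NA_real_
    bgbc[bad] <- NA_real_
  }
  over <- !is.na(f) & f > 1
  agbc[over] <- agbc[over] / f[over]
  bgbc[over] <- bgbc[over] / f[over]
  agbc[is.na(ext)] <- NA_real_
  bgbc[is.na(ext)] <- NA_real_
  list(agbc = layer(agbc, g), bgbc = layer(bgbc, g), f = layer(f, g))
}

#' Theil-Sen slope of a time series
#'
#' The median of all pairwise slopes `(v_j - v_i) / (t_j - t_i)` over pairs
#' with distinct time points; for an even number of pairwise slopes, the
#' mean of the two middle order statistics. Robust to outliers (breakdown
#' point about 29%).
#'
#' @param years Numeric vector of time points (>= 2 distinct).
#' @param values Numeric vector of the same length.
#' @return The slope, in value units per year.
#' @examples
#' theil_sen_slope(0:2, c(0, 1, 10))  # median of {1, 5, 9} = 5
#' @export
theil_sen_slope <- function(years, values) {
  ok <- !is.na(years) & !is.na(values)
  years <- years[ok]
  values <- values[ok]
  if (length(unique(years)) < 2) stop("need >= 2 distinct years")
  n <- length(years)
  ij <- utils::combn(n, 2)
  dt <- years[ij[2, ]] - years[ij[1, ]]
  keep <- dt != 0
  stats::median((values[ij[2, ]] - values[ij[1, ]])[keep] / dt[keep])
}

#' Bootstrap standard error of the Theil-Sen slope
#'
#' Standard deviation of Theil-Sen slopes over `n_reps` replicates, each of
#' which omits a random subset of years: every year is dropped independently
#' with probability `drop_fraction`, redrawing if fewer than 3 years would
#' remain. The random stream is seeded and isolated, so results are
#' reproducible and the caller's RNG state is untouched.
#'
#' @inheritParams theil_sen_slope
#' @param n_reps Number of bootstrap replicates (default 1000).
#' @param drop_fraction Per-year omission probability (default 0.2).
#' @param seed Integer seed.
#' @return Standard deviation of the replicate slopes (value units per
#'   year).
#' @export
bootstrap_slope_se <- function(years, values, n_reps = 1000,
                               drop_fraction = 0.2, seed = 1) {
  if (length(unique(years)) < 3)
    stop("need >= 3 distinct years to bootstrap")
  slopes <- with_local_seed(seed, {
    vapply(seq_len(n_reps), function(i) {
      repeat {
        keep <- stats::runif(length(years)) >= drop_fraction
        if (sum(keep) >= 3) break
      }
      theil_sen_slope(years[keep], values[keep])
    }, numeric(1))
  })
  stats::sd(slopes)
}

# evaluate expr under a private RNG stream without disturbing the caller's
with_local_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Productivity-trend correction of crop carbon maps
#'
#' Moves epoch-2000-style crop AGBC/BGBC maps to a later epoch using the
#' per-cell Theil-Sen slope of an annual net-primary-productivity (ANPP)
#' series. The total carbon change is `years_elapsed * slope`; it is
#' allocated to the above- and belowground pools in proportion to their
#' shares `AGBC / (AGBC + BGBC)` and `BGBC / (AGBC + BGBC)`, and corrected
#' values are floored at zero. The per-cell standard error is the bootstrap
#' SE of the slope scaled by `years_elapsed` and split by the same shares
#' (the corrected maps' error is based exclusively on this trend
#' correction). Cells with zero total carbon are passed through unchanged.
#'
#' @param agbc2000,bgbc2000 [uncertain_layer()]s of the uncorrected maps.
#' @param anpp_series Named list of [layer()]s, one per year; names are the
#'   years (coerced with `as.numeric`).
#' @param years_elapsed Number of years the correction spans (default 10).
#' @param n_reps Bootstrap replicates per cell (default 1000).
#' @param seed Integer seed for the bootstrap.
#' @return List of two [uncertain_layer()]s: `agbc` and `bgbc`.
#' @export
anpp_correction <- function(agbc2000, bgbc2000, anpp_series,
                            years_elapsed = 10, n_reps = 1000, seed = 1) {
  stopifnot(is_uncertain_layer(agbc2000), is_uncertain_layer(bgbc2000),
            length(anpp_series) >= 3)
  g <- agbc2000$mean$grid
  stop_if_grid_mismatch(g, bgbc2000$mean$grid)
  for (l in anpp_series) stop_if_grid_mismatch(g, l$grid)
  years <- as.numeric(names(anpp_series))
  if (any(is.na(years))) stop("anpp_series must be named by year")

  stack <- vapply(anpp_series, function(l) l$values,
                  matrix(0, g$n_rows, g$n_cols))
  dim(stack) <- c(g$n_rows * g$n_cols, length(years))
  if (all(is.na(stack))) stop("all-nodata ANPP series")

  a0 <- agbc2000$mean$values
  b0 <- bgbc2000$mean$values
  total <- a0 + b0
  correct <- !is.na(total) & total > 0
  cells <- which(correct & rowSums(!is.na(stack)) >= 2)

  slope <- matrix(0, g$n_rows, g$n_cols)
  slope_se <- matrix(0, g$n_rows, g$n_cols)
  for (i in cells) {
    v <- stack[i, ]
    slope[i] <- theil_sen_slope(years, v)
    ok <- !is.na(v)
    if (sum(ok) >= 3)
      slope_se[i] <- bootstrap_slope_se(years[ok], v[ok], n_reps = n_reps,
                                        seed = seed + i)
  }

  share_a <- ifelse(correct, a0 / total, 0)
  share_b <- ifelse(correct, b0 / total, 0)
  delta <- years_elapsed * slope
  a1 <- pmax(a0 + share_a * delta, 0)
  b1 <- pmax(b0 + share_b * delta, 0)
  se_total <- years_elapsed * slope_se
  list(agbc = uncertain_layer(layer(a1, g), layer(share_a * se_total, g)),
       bgbc = uncertain_layer(layer(b1, g), layer(share_b * se_total, g)))
}
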
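# Tundra and grassland aboveground carbon from NDVI composites through
# pluggable calibrations and regressions, multi-composite averaging with
# root-mean-square error combination, and the matching belowground carbon
# from a MAT-dependent root-to-shoot model (tundra) or climate-stratified
# static ratios (grassland).

#' NDVI cross-sensor calibration
#'
#' Linear calibration `calibrated = gain * ndvi + offset` translating one
#' sensor's NDVI to the sensor a biomass regression was trained on, with
#' standard errors on both coefficients.
#'
#' @param gain,offset Calibration coefficients.
#' @param gain_se,offset_se Their standard errors (>= 0).
#' @param sensor Label of the target sensor (documentation only).
#' @return An object of class `ndvi_calibration`.
#' @export
ndvi_calibration <- function(gain = 1, offset = 0, gain_se = 0,
                             offset_se = 0, sensor = "unspecified") {
  if (gain_se < 0 || offset_se < 0) stop("calibration SEs must be >= 0")
  structure(list(gain = gain, offset = offset, gain_se = gain_se,
                 offset_se = offset_se, sensor = sensor),
            class = "ndvi_calibration")
}

#' Apply an NDVI calibration to a layer
#'
#' The calibrated value is `gain * ndvi + offset`; its standard error is the
#' quadrature combination `sqrt((ndvi * gain_se)^2 + offset_se^2)` of the
#' coefficient uncertainties.
#'
#' @param ndvi [layer()] of NDVI in `[-1, 1]`.
#' @param cal An [ndvi_calibration()].
#' @return [uncertain_layer()] of calibrated NDVI.
#' @export
calibrate_ndvi <- function(ndvi, cal) {
  stopifnot(is_layer(ndvi), inherits(cal, "ndvi_calibration"))
  m <- cal$gain * ndvi$values + cal$offset
  s <- sqrt((ndvi$values * cal$gain_se)^2 + cal$offset_se^2)
  uncertain_layer(layer(m, ndvi$grid), layer(s, ndvi$grid))
}

#' Per-cell percentile composite of an NDVI series
#'
#' Computes, for each cell, the given percentile of the valid observations
#' across the series (linear interpolation between closest order statistics;
#' `pct = 100` gives the per-cell maximum). Cells with no valid observation
#' become nodata.
#'
#' @param series List of numeric [layer()]s on a common grid.
#' @param pct Percentile in `[0, 100]` (default 80, the high-latitude
#'   compositing convention; use 100 for a maximum-value composite).
#' @return A [layer()].
#' @export
percentile_composite <- function(series, pct = 80) {
  if (!length(series)) stop("empty series")
  stopifnot(all(vapply(series, is_layer, logical(1))))
  g <- series[[1]]$grid
  for (l in series) stop_if_grid_mismatch(g, l$grid)
  if (pct < 0 || pct > 100) stop("pct must be in [0, 100]")
  stack <- vapply(series, function(l) l$values,
                  matrix(0, g$n_rows, g$n_cols))
  dim(stack) <- c(g$n_rows * g$n_cols, length(series))
  out <- apply(stack, 1, function(v) {
    v <- v[!is.na(v)]
    if (!length(v)) NA_real_ else stats::quantile(v, pct / 100, type = 7,
                                                  names = FALSE)
  })
  layer(matrix(out, g$n_rows, g$n_cols), g)
}

#' Pluggable NDVI-to-AGBC regression
#'
#' A nonlinear regression predicting aboveground biomass carbon from NDVI.
#' Supported forms (all monotone non-decreasing on `[0, 1]` for positive
#' scale coefficients):
#' * `"power"`: `AGBC = a * ndvi^b`, coefficients `a`, `b`;
#' * `"exponential"`: `AGBC = a * (exp(b * ndvi) - 1)`, coefficients `a`,
#'   `b`.
#'
#' Predictions are capped at `cap` (the model's stated maximum, e.g. its
#' NDVI = 1 prediction) and NDVI outside `[0, 1]` is clamped with a logged
#' count. `rel_rmse` adds a relative residual error term in quadrature with
#' the coefficient contributions.
#'
#' @param coef,coef_se Named coefficient vector and standard errors.
#' @param form Functional form id.
#' @param cap Prediction cap in MgC ha^-1 (`Inf` to disable).
#' @param rel_rmse Relative RMSE of the regression (0 to disable).
#' @return An object of class `agbc_regression`.
#' @export
agbc_regression <- function(coef, coef_se = 0 * coef,
                            form = c("power", "exponential"),
                            cap = Inf, rel_rmse = 0) {
  form <- match.arg(form)
  miss <- setdiff(c("a", "b"), names(coef))
  if (length(miss)) stop("missing coefficients: ", paste(miss, collapse = ", "))
  if (any(coef_se < 0)) stop("coefficient SEs must be >= 0")
  structure(list(form = form, coef = coef, coef_se = coef_se[names(coef)],
                 cap = cap, rel_rmse = rel_rmse),
            class = "agbc_regression")
}

eval_agbc_model <- function(coef, form, ndvi) {
  switch(form,
         power = coef[["a"]] * ndvi^coef[["b"]],
         exponential = coef[["a"]] * (exp(coef[["b"]] * ndvi) - 1))
}

#' Predict AGBC from an NDVI layer
#'
#' Evaluates an [agbc_regression()] per cell. The standard error combines,
#' in quadrature: central finite-difference contributions of each
#' coefficient scaled by its SE, the propagated NDVI standard error, and the
#' model's relative RMSE times the prediction.
#'
#' @param ndvi [uncertain_layer()] of (calibrated) NDVI.
#' @param model An [agbc_regression()].
#' @return [uncertain_layer()] of AGBC (MgC ha^-1).
#' @export
apply_agbc_model <- function(ndvi, model) {
  stopifnot(is_uncertain_layer(ndvi), inherits(model, "agbc_regression"))
  g <- ndvi$mean$grid
  x <- ndvi$mean$values
  out_of_domain <- !is.na(x) & (x < 0 | x > 1)
  if (any(out_of_domain)) {
    message(sum(out_of_domain), " NDVI cell(s) outside [0, 1] clamped")
    x <- pmin(pmax(x, 0), 1)
  }
  valid <- !is.na(x)
  xv <- x[valid]
  f0 <- eval_agbc_model(model$coef, model$form, xv)

  se2 <- (model$rel_rmse * f0)^2
  for (k in names(model$coef)) {
    se_k <- model$coef_se[[k]]
    if (se_k == 0) next
    h <- 1e-6 * max(abs(model$coef[[k]]), 1)
    cp <- cm <- model$coef
    cp[[k]] <- cp[[k]] + h
    cm[[k]] <- cm[[k]] - h
    d <- (eval_agbc_model(cp, model$form, xv) -
            eval_agbc_model(cm, model$form, xv)) / (2 * h)
    se2 <- se2 + (d * se_k)^2
  }
  h_x <- 1e-6
  dx <- (eval_agbc_model(model$coef, model$form, pmin(xv + h_x, 1)) -
           eval_agbc_model(model$coef, model$form, pmax(xv - h_x, 0))) /
    (pmin(xv + h_x, 1) - pmax(xv - h_x, 0))
  se2 <- se2 + (dx * ndvi$se$values[valid])^2

  capped <- pmin(f0, model$cap)
  m <- matrix(NA_real_, g$n_rows, g$n_cols)
  s <- matrix(NA_real_, g$n_rows, g$n_cols)
  m[valid] <- capped
  s[valid] <- sqrt(se2)
  uncertain_layer(layer(m, g), layer(s, g))
}

#' Combine composite members into a single estimate
#'
#' The combined mean is the per-cell arithmetic mean of the member means;
#' the combined standard error is the per-cell root mean square of the
#' member SEs (`sqrt(mean(se^2))`), the quadrature-consistent average.
#'
#' @param members List of [uncertain_layer()]s on a common grid.
#' @return [uncertain_layer()].
#' @export
combine_composites <- function(members) {
  if (!length(members)) stop("empty member list")
  stopifnot(all(vapply(members, is_uncertain_layer, logical(1))))
  g <- members[[1]]$mean$grid
  for (m in members) stop_if_grid_mismatch(g, m$mean$grid)
  n <- length(members)
  msum <- 0
  s2sum <- 0
  for (m in members) {
    msum <- msum + m$mean$values
    s2sum <- s2sum + m$se$values^2
  }
  uncertain_layer(layer(msum / n, g), layer(sqrt(s2sum / n), g))
}

#' Convert tundra biomass to biomass carbon
#'
#' Multiplies tundra AGB by the herbaceous/shrub biomass carbon fraction
#' 0.492 (SE 0.008) with product-rule error propagation.
#'
#' @param agb [uncertain_layer()] of tundra AGB (Mg ha^-1).
#' @return [uncertain_layer()] of AGBC (MgC ha^-1).
#' @export
tundra_c_fraction <- function(agb) {
  stopifnot(is_uncertain_layer(agb))
  g <- agb$mean$grid
  prod <- se_of_product(uval(agb$mean$values, agb$se$values),
                        uval(0.492, 0.008))
  uncertain_layer(layer(matrix(prod$mean, g$n_rows, g$n_cols), g),
                  layer(matrix(prod$se, g$n_rows, g$n_cols), g))
}

#' MAT-dependent tundra root-to-shoot model
#'
#' Univariate model predicting the tundra root-to-shoot ratio from mean
#' annual temperature: `ratio = a + b * MAT` (form `"linear"`) or
#' `ratio = exp(a + b * MAT)` (form `"log_linear"`), floored at
#' `min_ratio`. Coefficients are configuration: the default is a documented
#' *synthetic* stand-in with plausible magnitudes (colder MAT, larger root
#' fraction).
#'
#' @param coef,coef_se Named coefficients `a`, `b` and standard errors.
#' @param form `"linear"` or `"log_linear"`.
#' @param min_ratio Lower floor for the predicted ratio.
#' @return An object of class `wang_model`.
#' @export
wang_model <- function(coef, coef_se = 0 * coef,
                       form = c("linear", "log_linear"), min_ratio = 0.1) {
  form <- match.arg(form)
  miss <- setdiff(c("a", "b"), names(coef))
  if (length(miss)) stop("missing coefficients: ", paste(miss, collapse = ", "))
  if (any(coef_se < 0)) stop("coefficient SEs must be >= 0")
  structure(list(form = form, coef = coef, coef_se = coef_se[names(coef)],
                 min_ratio = min_ratio),
            class = "wang_model")
}

#' @rdname wang_model
#' @export
default_wang_model <- function() {
  wang_model(coef = c(a = 3.2, b = -0.12), coef_se = c(a = 0.2, b = 0.02),
             form = "linear", min_ratio = 0.2)
}

eval_wang_ratio <- function(coef, form, mat, min_ratio) {
  r <- switch(form,
              linear = coef[["a"]] + coef[["b"]] * mat,
              log_linear = exp(coef[["a"]] + coef[["b"]] * mat))
  pmax(r, min_ratio)
}

#' Tundra belowground biomass carbon
#'
#' Cells with tundra AGB at or below 25 Mg ha^-1 use the MAT-dependent
#' root-to-shoot model: `BGBC = AGBC * ratio(MAT)`, with SE combining (in
#' quadrature) the AGBC error, the MAT error through the ratio's slope, and
#' the model coefficient errors. Where AGB exceeds 25 Mg ha^-1 the
#' vegetation is considered to include trees and the woody regression path
#' ([regression_bgbc()]) is used instead.
#'
#' @param agbc [uncertain_layer()] of tundra AGBC (MgC ha^-1).
#' @param agb [uncertain_layer()] of tundra AGB (Mg ha^-1), used only for
#'   the 25 Mg ha^-1 switch.
#' @param mat [uncertain_layer()] of MAT (deg C).
#' @param model A [wang_model()].
#' @param reich_args List of arguments for the woody path:
#'   `phylogeny_fraction`, `origin`, `model`, and optionally `phylo_ua`,
#'   passed to [regression_bgbc()] for the above-threshold cells. `NULL`
#'   errors if any cell exceeds the threshold.
#' @return [uncertain_layer()] of BGBC.
#' @export
tundra_bgbc <- function(agbc, agb, mat, model = default_wang_model(),
                        reich_args = NULL) {
  stopifnot(is_uncertain_layer(agbc), is_uncertain_layer(agb),
            is_uncertain_layer(mat), inherits(model, "wang_model"))
  g <- agbc$mean$grid
  stop_if_grid_mismatch(g, agb$mean$grid)
  stop_if_grid_mismatch(g, mat$mean$grid)

  a <- agbc$mean$values
  tv <- mat$mean$values
  valid <- !is.na(a) & !is.na(tv)
  woody_cells <- valid & !is.na(agb$mean$values) & agb$mean$values > 25

  ratio <- eval_wang_ratio(model$coef, model$form, tv[valid], model$min_ratio)
  f0 <- a[valid] * ratio
  se2 <- (ratio * agbc$se$values[valid])^2
  for (k in names(model$coef)) {
    se_k <- model$coef_se[[k]]
    if (se_k == 0) next
    h <- 1e-6 * max(abs(model$coef[[k]]), 1)
    cp <- cm <- model$coef
    cp[[k]] <- cp[[k]] + h
    cm[[k]] <- cm[[k]] - h
    d <- a[valid] *
      (eval_wang_ratio(cp, model$form, tv[valid], model$min_ratio) -
         eval_wang_ratio(cm, model$form, tv[valid], model$min_ratio)) / (2 * h)
    se2 <- se2 + (d * se_k)^2
  }
  h_t <- 1e-4
  d_t <- a[valid] *
    (eval_wang_ratio(model$coef, model$form, tv[valid] + h_t, model$min_ratio) -
       eval_wang_ratio(model$coef, model$form, tv[valid] - h_t,
                       model$min_ratio)) / (2 * h_t)
  se2 <- se2 + (d_t * mat$se$values[valid])^2

  m <- matrix(NA_real_, g$n_rows, g$n_cols)
  s <- matrix(NA_real_, g$n_rows, g$n_cols)
  m[valid] <- f0
  s[valid] <- sqrt(se2)

  if (any(woody_cells)) {
    if (is.null(reich_args))
      stop("cells with AGB > 25 Mg ha^-1 need the woody regression ",
           "(supply reich_args)")
    woody <- do.call(regression_bgbc, c(
      list(agbc = agbc, mat = mat), reich_args))
    m[woody_cells] <- woody$mean$values[woody_cells]
    s[woody_cells] <- woody$se$values[woody_cells]
  }
  uncertain_layer(layer(m, g), layer(s, g))
}

#' Grassland belowground biomass carbon
#'
#' Looks up the grassland climate class of each cell's Koppen-Geiger code,
#' prefixes it to match the `Grassland-*` strata of the ratio table and
#' applies [static_ratio_bgbc()].
#'
#' @param agbc [uncertain_layer()] of grassland AGBC.
#' @param kg [layer()] of Koppen-Geiger codes.
#' @param ratios Ratio table (default [root_shoot_table()]).
#' @return [uncertain_layer()] of BGBC.
#' @export
grassland_bgbc <- function(agbc, kg, ratios = root_shoot_table()) {
  stopifnot(is_uncertain_layer(agbc), is_layer(kg))
  g <- agbc$mean$grid
  stop_if_grid_mismatch(g, kg$grid)
  strata <- matrix(NA_character_, g$n_rows, g$n_cols)
  ok <- !is.na(kg$values)
  strata[ok] <- paste0("Grassland-", koppen_strata(kg$values[ok])$grassland_class)
  static_ratio_bgbc(agbc, layer(strata, g), ratios = ratios)
}
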
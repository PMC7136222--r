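# Woody biomass carbon: merging of the global and regional (dryland-Africa
# analogue) aboveground maps, conversion of dry biomass to carbon with
# climate/phylogeny stratified fractions, and belowground carbon from either
# a pluggable root regression (with planted/natural origin weighting) or
# static root-to-shoot ratios for savannah and shrubland.

#' Analytic standard error of the regional woody biomass map
#'
#' The regional dryland map ships without an uncertainty layer; its authors'
#' cubic polynomial gives the standard error of prediction as a function of
#' estimated aboveground biomass:
#' `SE = 1.0551*AGB - 0.007*AGB^2 - 0.0000273*AGB^3`, valid on
#' `0 <= AGB <= 85` Mg ha^-1 (the saturation threshold of the L-band
#' SAR-biomass relationship behind the map).
#'
#' @param agb Aboveground biomass density, Mg ha^-1 (vectorized).
#' @return Standard error, Mg ha^-1.
#' @examples
#' bouvet_se(50)
#' @export
bouvet_se <- function(agb) {
  if (any(agb < 0 | agb > 85, na.rm = TRUE))
    stop("AGB outside the model domain [0, 85] Mg ha^-1")
  1.0551 * agb - 0.007 * agb^2 - 0.0000273 * agb^3
}

#' Merge global and regional woody biomass maps
#'
#' Within the regional map's footprint (its valid cells), the regional
#' estimate and its SE replace the global one — except where the landcover
#' is a closed or flooded forest type, which lies outside the regional
#' model's dryland domain and keeps the global estimate. No blending occurs:
#' every output cell equals exactly one of the two inputs.
#'
#' @param global_agb,regional_agb [uncertain_layer()]s on the common grid.
#' @param landcover [layer()] of landcover codes on the same grid.
#' @param closed_flooded Named mapping (code to `"1"`/`"0"`) from
#'   [scheme_mapping()] flagging closed/flooded forest codes.
#' @return An [uncertain_layer()].
#' @export
merge_woody_maps <- function(global_agb, regional_agb, landcover,
                             closed_flooded) {
  stopifnot(is_uncertain_layer(global_agb), is_uncertain_layer(regional_agb),
            is_layer(landcover))
  stop_if_grid_mismatch(global_agb$mean$grid, regional_agb$mean$grid)
  stop_if_grid_mismatch(global_agb$mean$grid, landcover$grid)
  closed <- matrix(closed_flooded[as.character(landcover$values)] == "1",
                   landcover$grid$n_rows, landcover$grid$n_cols)
  closed[is.na(closed)] <- FALSE
  use_regional <- !is.na(regional_agb$mean$values) & !closed
  m <- global_agb$mean$values
  s <- global_agb$se$values
  m[use_regional] <- regional_agb$mean$values[use_regional]
  s[use_regional] <- regional_agb$se$values[use_regional]
  uncertain_layer(layer(m, global_agb$mean$grid),
                  layer(s, global_agb$mean$grid))
}

#' Convert woody biomass to biomass carbon
#'
#' Multiplies aboveground biomass by the climate- and phylogeny-specific
#' carbon fraction looked up from the Koppen-derived carbon domain and the
#' landcover-derived phylogeny label, propagating both the biomass SE and
#' the fraction SE with the product rule. Cells whose stratum cannot be
#' resolved (unknown phylogeny such as bare or urban cover) become nodata;
#' their count is reported in a message.
#'
#' @param agb [uncertain_layer()] of AGB (Mg ha^-1).
#' @param kg [layer()] of Koppen-Geiger codes.
#' @param phylogeny Thematic [layer()] of phylogeny labels (`"angiosperm"`,
#'   `"gymnosperm"`, `"mixed"`; anything else is unresolvable).
#' @param fractions Carbon-fraction table
#'   (default [carbon_fraction_table()]).
#' @return [uncertain_layer()] of AGBC (MgC ha^-1).
#' @export
agb_to_agbc <- function(agb, kg, phylogeny,
                        fractions = carbon_fraction_table()) {
  stopifnot(is_uncertain_layer(agb), is_layer(kg), is_layer(phylogeny))
  g <- agb$mean$grid
  stop_if_grid_mismatch(g, kg$grid)
  stop_if_grid_mismatch(g, phylogeny$grid)
  phylo <- as.character(phylogeny$values)
  valid <- !is.na(agb$mean$values) & !is.na(kg$values) &
    phylo %in% c("angiosperm", "gymnosperm", "mixed")
  n_unresolved <- sum(!is.na(agb$mean$values) & !valid)
  if (n_unresolved > 0)
    message(n_unresolved, " cell(s) with unresolvable carbon stratum -> nodata")
  m <- matrix(NA_real_, g$n_rows, g$n_cols)
  s <- matrix(NA_real_, g$n_rows, g$n_cols)
  if (any(valid)) {
    domain <- koppen_strata(kg$values[valid])$carbon_domain
    frac <- c_fraction(domain, phylo[valid], table = fractions)
    prod <- se_of_product(uval(agb$mean$values[valid], agb$se$values[valid]),
                          frac)
    m[valid] <- prod$mean
    s[valid] <- prod$se
  }
  uncertain_layer(layer(m, g), layer(s, g))
}

#' Country table of forest origin evidence
#'
#' Validates a per-country table of reported and mapped natural/planted
#' forest areas used for origin weighting: FRA-style natural and planted
#' areas, FAOSTAT-style tree-crop area, and the areas covered by the intact
#' forest (IFL) and planted-trees (SDPT) maps within the country.
#'
#' @param df Data frame with columns `country_id`, `fra_natural_ha`,
#'   `fra_planted_ha`, `faostat_treecrop_ha`, `ifl_mapped_ha`,
#'   `sdpt_mapped_ha`.
#' @return The validated data frame (class `country_forest_table`).
#' @export
country_forest_table <- function(df) {
  need <- c("country_id", "fra_natural_ha", "fra_planted_ha",
            "faostat_treecrop_ha", "ifl_mapped_ha", "sdpt_mapped_ha")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  areas <- df[, setdiff(need, "country_id")]
  if (any(as.matrix(areas) < 0, na.rm = TRUE)) stop("areas must be >= 0")
  if (anyDuplicated(df$country_id)) stop("duplicate country ids")
  class(df) <- c("country_forest_table", "data.frame")
  df
}

#' Per-cell planted/natural origin weights
#'
#' Assigns each cell a probability pair `(w_planted, w_natural)` summing
#' to 1:
#' * intact-forest (IFL) cells are natural: `(0, 1)`;
#' * planted-database (SDPT) cells are planted, down-weighted to
#'   `w_planted = min(1, planted_total / sdpt_mapped_ha)` when the mapped
#'   plantation area exceeds the country's reported planted total;
#' * remaining cells get the country's residual split
#'   `(D_p, D_n) / (D_p + D_n)` where `D_p`/`D_n` are the reported planted
#'   and natural totals minus the mapped SDPT/IFL areas, floored at zero.
#'
#' The reported planted total is `fra_planted + max(0, faostat - fra_planted)`
#' (tree crops beyond the FRA planted area are added). Countries whose
#' residuals are both zero but still have unknown-origin cells fall back to
#' `(0.5, 0.5)` with a warning.
#'
#' @param country_table A [country_forest_table()].
#' @param country_id [layer()] of country ids.
#' @param ifl_mask,sdpt_mask Logical (0/1) [layer()]s flagging intact and
#'   planted-database cells.
#' @return An object of class `origin_weights`: list of two [layer()]s,
#'   `planted` and `natural`.
#' @export
origin_weights <- function(country_table, country_id, ifl_mask, sdpt_mask) {
  stopifnot(inherits(country_table, "country_forest_table"),
            is_layer(country_id), is_layer(ifl_mask), is_layer(sdpt_mask))
  g <- country_id$grid
  stop_if_grid_mismatch(g, ifl_mask$grid)
  stop_if_grid_mismatch(g, sdpt_mask$grid)

  planted_total <- country_table$fra_planted_ha +
    pmax(0, country_table$faostat_treecrop_ha - country_table$fra_planted_ha)
  d_p <- pmax(0, planted_total - country_table$sdpt_mapped_ha)
  d_n <- pmax(0, country_table$fra_natural_ha - country_table$ifl_mapped_ha)
  omega_p <- ifelse(country_table$sdpt_mapped_ha > 0,
                    pmin(1, planted_total / country_table$sdpt_mapped_ha), 1)
  resid_p <- ifelse(d_p + d_n > 0, d_p / (d_p + d_n), NA_real_)

  idx <- match(country_id$values, country_table$country_id)
  unmatched <- !is.na(country_id$values) & is.na(idx)
  if (any(unmatched))
    stop(sum(unmatched), " cell(s) with country id missing from the table")

  wp <- matrix(NA_real_, g$n_rows, g$n_cols)
  ifl <- !is.na(ifl_mask$values) & ifl_mask$values > 0
  sdpt <- !is.na(sdpt_mask$values) & sdpt_mask$values > 0 & !ifl
  known <- !is.na(idx)
  wp[known] <- resid_p[idx[known]]
  degenerate <- known & is.na(wp) & !ifl & !sdpt
  if (any(degenerate)) {
    warning(sum(degenerate),
            " unknown-origin cell(s) in countries with zero residual areas; ",
            "using weights (0.5, 0.5)")
    wp[degenerate] <- 0.5
  }
  wp[known & sdpt] <- omega_p[idx[known & sdpt]]
  wp[known & ifl] <- 0
  structure(list(planted = layer(wp, g),
                 natural = layer(1 - wp, g)),
            class = "origin_weights")
}

#' Pluggable root (belowground-from-aboveground) regression model
#'
#' The multiple regression predicting belowground biomass carbon from
#' aboveground carbon, mean annual temperature, phylogeny and regenerative
#' origin is supplied as a configuration object, since its published
#' coefficients are external to this package. Two functional forms are
#' supported:
#' * `"log_linear"`:
#'   `BGBC = exp(b0 + b1*log(AGBC) + b2*MAT + b3*angio + b4*planted)` with
#'   coefficients named `intercept`, `log_agbc`, `mat`, `angiosperm`,
#'   `planted`;
#' * `"ratio"`: `BGBC = r * AGBC` with a single coefficient named `ratio`
#'   (a deliberately simple stand-in for parameter-recovery testing).
#'
#' @param coef Named numeric vector of coefficients.
#' @param coef_se Named numeric vector of their standard errors (>= 0; same
#'   names).
#' @param form `"log_linear"` or `"ratio"`.
#' @return An object of class `root_regression_model`.
#' @export
root_regression_model <- function(coef, coef_se = 0 * coef,
                                  form = c("log_linear", "ratio")) {
  form <- match.arg(form)
  need <- switch(form,
                 log_linear = c("intercept", "log_agbc", "mat", "angiosperm",
                                "planted"),
                 ratio = "ratio")
  miss <- setdiff(need, names(coef))
  if (length(miss)) stop("missing coefficients: ", paste(miss, collapse = ", "))
  if (any(coef_se < 0)) stop("coefficient SEs must be >= 0")
  coef_se <- coef_se[names(coef)]
  structure(list(form = form, coef = coef, coef_se = coef_se),
            class = "root_regression_model")
}

#' @rdname root_regression_model
#' @details `default_root_model()` returns a documented *synthetic* default
#'   (plausible magnitudes, not fitted to any dataset) used by the test
#'   suite; real analyses must supply published coefficients.
#' @export
default_root_model <- function() {
  root_regression_model(
    coef = c(intercept = -1.39, log_agbc = 0.98, mat = -0.012,
             angiosperm = 0.05, planted = -0.10),
    coef_se = c(intercept = 0.05, log_agbc = 0.01, mat = 0.001,
                angiosperm = 0.02, planted = 0.03),
    form = "log_linear")
}

# Evaluate a root model for vectors of inputs; planted is 0/1 (or a weight
# when evaluating the origin-weighted prediction directly).
eval_root_model <- function(coef, form, agbc, mat, angio, planted) {
  switch(form,
         log_linear = ifelse(agbc > 0,
                             exp(coef[["intercept"]] +
                                   coef[["log_agbc"]] * log(agbc) +
                                   coef[["mat"]] * mat +
                                   coef[["angiosperm"]] * angio +
                                   coef[["planted"]] * planted),
                             0),
         ratio = coef[["ratio"]] * agbc)
}

#' Regression-based woody belowground biomass carbon
#'
#' Evaluates the root regression under fully planted and fully natural
#' origin and combines the two predictions with the per-cell origin
#' weights (`BGBC_u = w_p * BGBC_p + w_n * BGBC_n`). The standard error is a
#' summation in quadrature over finite-difference contributions of every
#' model coefficient (scaled by its SE), the AGBC standard error, the MAT
#' standard error, and the Bernoulli standard deviation of the phylogeny
#' classification's user's accuracy.
#'
#' @param agbc [uncertain_layer()] of woody AGBC (MgC ha^-1).
#' @param mat [uncertain_layer()] of mean annual temperature (deg C); see
#'   [mat_uncertain()] for the conventional 27% relative error.
#' @param phylogeny_fraction [layer()] of angiosperm share in `[0, 1]`
#'   (mixed/ambiguous cells are 0.5).
#' @param origin [origin_weights()] layers.
#' @param model A [root_regression_model()].
#' @param phylo_ua User's accuracy of the phylogeny classification used for
#'   the Bernoulli error term (default: accuracy-weighted mean of the
#'   published phylogeny confusion matrix diagonal is not assumed; supply
#'   the class-specific value, default 0.99 for the dominant mixed class).
#' @return [uncertain_layer()] of BGBC (MgC ha^-1).
#' @export
regression_bgbc <- function(agbc, mat, phylogeny_fraction, origin, model,
                            phylo_ua = 0.99) {
  stopifnot(is_uncertain_layer(agbc), is_uncertain_layer(mat),
            is_layer(phylogeny_fraction),
            inherits(origin, "origin_weights"),
            inherits(model, "root_regression_model"))
  g <- agbc$mean$grid
  stop_if_grid_mismatch(g, mat$mean$grid)
  stop_if_grid_mismatch(g, phylogeny_fraction$grid)
  stop_if_grid_mismatch(g, origin$planted$grid)

  a <- agbc$mean$values
  tmat <- mat$mean$values
  angio <- phylogeny_fraction$values
  wp <- origin$planted$values
  valid <- !is.na(a) & !is.na(tmat) & !is.na(angio) & !is.na(wp)

  predict_u <- function(coef, a, tmat, angio, wp) {
    wp * eval_root_model(coef, model$form, a, tmat, angio, 1) +
      (1 - wp) * eval_root_model(coef, model$form, a, tmat, angio, 0)
  }

  av <- a[valid]; tv <- tmat[valid]; pv <- angio[valid]; wv <- wp[valid]
  f0 <- predict_u(model$coef, av, tv, pv, wv)

  # central finite differences for each uncertain input and coefficient
  fd <- function(plus, minus, h) (plus - minus) / (2 * h)
  contribs <- list()
  for (k in names(model$coef)) {
    se_k <- model$coef_se[[k]]
    if (se_k == 0) next
    h <- 1e-6 * max(abs(model$coef[[k]]), 1)
    cp <- cm <- model$coef
    cp[[k]] <- cp[[k]] + h
    cm[[k]] <- cm[[k]] - h
    contribs[[k]] <- fd(predict_u(cp, av, tv, pv, wv),
                        predict_u(cm, av, tv, pv, wv), h) * se_k
  }
  h_a <- pmax(1e-6 * abs(av), 1e-9)
  contribs$agbc <- fd(predict_u(model$coef, av + h_a, tv, pv, wv),
                      predict_u(model$coef, pmax(av - h_a, 0), tv, pv, wv),
                      h_a) * agbc$se$values[valid]
  h_t <- 1e-4
  contribs$mat <- fd(predict_u(model$coef, av, tv + h_t, pv, wv),
                     predict_u(model$coef, av, tv - h_t, pv, wv),
                     h_t) * mat$se$values[valid]
  h_p <- 1e-6
  delta <- bernoulli_sd(phylo_ua)
  contribs$phylo <- fd(predict_u(model$coef, av, tv, pv + h_p, wv),
                       predict_u(model$coef, av, tv, pv - h_p, wv),
                       h_p) * delta

  se2 <- 0
  for (ctb in contribs) se2 <- se2 + ctb^2
  m <- matrix(NA_real_, g$n_rows, g$n_cols)
  s <- matrix(NA_real_, g$n_rows, g$n_cols)
  m[valid] <- f0
  s[valid] <- sqrt(se2)
  uncertain_layer(layer(m, g), layer(s, g))
}

#' Conventional MAT uncertainty layer
#'
#' Wraps a mean annual temperature layer with the conventional 27% relative
#' standard error used when propagating MAT uncertainty into root models.
#'
#' @param mat_layer [layer()] of MAT (deg C).
#' @param relative Relative error (default 0.27).
#' @return [uncertain_layer()].
#' @export
mat_uncertain <- function(mat_layer, relative = 0.27) {
  stopifnot(is_layer(mat_layer))
  uncertain_layer(mat_layer,
                  layer(abs(mat_layer$values) * relative, mat_layer$grid))
}

#' Belowground carbon from static root-to-shoot ratios
#'
#' `BGBC = AGBC * ratio` per stratum, with the product-rule SE combining the
#' AGBC standard error and the ratio's. Cells with a stratum not present in
#' the ratio table become nodata.
#'
#' @param agbc [uncertain_layer()] of AGBC.
#' @param stratum Thematic [layer()] of stratum labels matching
#'   `ratios$stratum`.
#' @param ratios Ratio table (default [root_shoot_table()]).
#' @return [uncertain_layer()] of BGBC.
#' @export
static_ratio_bgbc <- function(agbc, stratum, ratios = root_shoot_table()) {
  stopifnot(is_uncertain_layer(agbc), is_layer(stratum))
  g <- agbc$mean$grid
  stop_if_grid_mismatch(g, stratum$grid)
  idx <- match(as.character(stratum$values), ratios$stratum)
  valid <- !is.na(agbc$mean$values) & !is.na(idx)
  m <- matrix(NA_real_, g$n_rows, g$n_cols)
  s <- matrix(NA_real_, g$n_rows, g$n_cols)
  if (any(valid)) {
    prod <- se_of_product(
      uval(agbc$mean$values[valid], agbc$se$values[valid]),
      uval(ratios$mean[idx[valid]], ratios$se[idx[valid]]))
    m[valid] <- prod$mean
    s[valid] <- prod$se
  }
  uncertain_layer(layer(m, g), layer(s, g))
}
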
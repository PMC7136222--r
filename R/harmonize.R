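# The harmonization decision tree: tree-cover-proportional allocation of
# herbaceous carbon on top of the woody layer, tundra/boreal override rules,
# distance-weighted blending across the 60 degrees N methodological seam,
# and water masking. AGBC and BGBC are harmonized with the same schema, and
# the override decision derived from the AGBC layers also governs BGBC so a
# cell never takes different branches in the two pools.

#' Stretch saturating percent tree cover to a fraction
#'
#' Optical percent-tree-cover products saturate around 80%; values are
#' linearly stretched so that 80% counts as complete cover:
#' `q = min(q_pct / 80, 1)`. The reported standard deviation is stretched by
#' the same 1/0.8 factor (it is not clamped).
#'
#' @param q_pct Percent tree cover in `[0, 100]` (vectorized).
#' @param sd_pct Standard deviation of the percent estimate.
#' @return List with `q` (fraction in `[0, 1]`) and `sigma_q` (fraction).
#' @export
stretch_treecover <- function(q_pct, sd_pct = 0) {
  if (any(q_pct < 0, na.rm = TRUE)) stop("percent tree cover must be >= 0")
  if (any(sd_pct < 0, na.rm = TRUE)) stop("sd must be >= 0")
  list(q = pmin(q_pct / 80, 1), sigma_q = sd_pct / 80)
}

#' Most-probable herbaceous estimate of a cell
#'
#' Mixes the grass and crop estimates according to the most probable
#' herbaceous class and the probability `p_i` that the classification is
#' correct (the class's user's accuracy), via [mix_two_classes()].
#'
#' @param grass,crop [uval()] estimates of the two herbaceous classes
#'   (vectorized).
#' @param most_probable Character vector: `"grass"` or `"crop"` per cell.
#' @param p_i Classification probability of the most probable class.
#' @return A [uval()].
#' @export
herbaceous_estimate <- function(grass, crop, most_probable, p_i) {
  stopifnot(inherits(grass, "uval"), inherits(crop, "uval"))
  bad <- !most_probable %in% c("grass", "crop") & !is.na(most_probable)
  if (any(bad))
    stop("unknown herbaceous label(s): ",
         paste(unique(most_probable[bad]), collapse = ", "))
  is_crop <- most_probable == "crop"
  mu_i <- uval(ifelse(is_crop, crop$mean, grass$mean),
               ifelse(is_crop, crop$se, grass$se))
  mu_j <- uval(ifelse(is_crop, grass$mean, crop$mean),
               ifelse(is_crop, grass$se, crop$se))
  mix_two_classes(mu_i, mu_j, p_i)
}

#' Tree-cover-proportional total allocation
#'
#' Total carbon of a cell: the woody estimate plus the herbaceous estimate
#' in the proportion complementary to fractional tree cover,
#' `mu_T = mu_w + mu_h * (1 - q)`. The published uncertainty form is
#' `sigma_T = sqrt(sigma_w^2 + q^2 * sigma_h^2 + mu_h^2 * sigma_q^2)`
#' (`form = "printed"`), which scales the herbaceous error by `q` rather
#' than by the complement `(1 - q)` actually applied to the mean;
#' `form = "complement"` substitutes `(1 - q)` for textbook consistency.
#' The printed form is the default for fidelity with the published maps.
#'
#' @param woody,herb [uval()]s (vectorized).
#' @param q Stretched tree-cover fraction in `[0, 1]`.
#' @param sigma_q Its standard error (fraction).
#' @param form `"printed"` or `"complement"`.
#' @return A [uval()].
#' @export
allocate_total <- function(woody, herb, q, sigma_q = 0,
                           form = c("printed", "complement")) {
  stopifnot(inherits(woody, "uval"), inherits(herb, "uval"))
  form <- match.arg(form)
  if (any(q < 0 | q > 1, na.rm = TRUE)) stop("q must be in [0, 1]")
  qs <- if (form == "printed") q else 1 - q
  uval(woody$mean + herb$mean * (1 - q),
       sqrt(woody$se^2 + (qs * herb$se)^2 + (herb$mean * sigma_q)^2))
}

#' Tundra/boreal override decision for one or more cells
#'
#' In the tundra and boreal biomes the woody and tundra-vegetation maps
#' overlap thematically and a separate rule set decides each cell's source:
#' * sparse landcover: the tundra estimate alone (`"tundra_only"`);
#' * north of 60 degrees with under 10% (unstretched) tree cover, or where
#'   the tundra AGBC estimate exceeds the woody AGBC: `"tundra_only"`;
#' * north of 60 degrees otherwise: woody plus the grass contribution
#'   (`"woody_plus_grass"`);
#' * at or south of 60 degrees (non-sparse): the `"standard"` allocation.
#' Ties (tundra equal to woody) take the woody branch. Cells outside these
#' biomes are always `"standard"`.
#'
#' @param biome Character vector: `"tundra"`, `"boreal"` or `"other"`.
#' @param sparse Logical vector: sparse-landcover flag.
#' @param latitude Cell-center latitude, degrees.
#' @param treecover_pct Unstretched percent tree cover.
#' @param tundra_agbc,woody_agbc Mean AGBC of the two candidate sources.
#' @return Character vector of decisions: `"tundra_only"`,
#'   `"woody_plus_grass"` or `"standard"`.
#' @export
tundra_override <- function(biome, sparse, latitude, treecover_pct,
                            tundra_agbc, woody_agbc) {
  in_biome <- biome %in% c("tundra", "boreal")
  north <- latitude > 60
  tundra_wins <- !is.na(tundra_agbc) &
    (is.na(woody_agbc) | tundra_agbc > woody_agbc)
  decision <- rep("standard", length(biome))
  decision[in_biome & north] <- "woody_plus_grass"
  decision[in_biome & north & (treecover_pct < 10 | tundra_wins)] <-
    "tundra_only"
  decision[in_biome & sparse] <- "tundra_only"
  decision
}

#' Blend two uncertain layers across the 60 degrees N seam
#'
#' Linear distance weighting within 1 degree of 60 degrees N:
#' `w(lat) = clamp((lat - 59) / 2, 0, 1)`; the result is
#' `w * north + (1 - w) * south` with SE
#' `sqrt((w * se_n)^2 + ((1 - w) * se_s)^2)`. At or above 61 degrees the
#' northern layer passes through untouched, at or below 59 degrees the
#' southern one, and exactly at 60 degrees the arithmetic average.
#'
#' @param north,south [uncertain_layer()]s on a common grid.
#' @return [uncertain_layer()].
#' @export
blend_60n <- function(north, south) {
  stopifnot(is_uncertain_layer(north), is_uncertain_layer(south))
  g <- north$mean$grid
  stop_if_grid_mismatch(g, south$mean$grid)
  w <- pmin(pmax((row_latitudes(g) - 59) / 2, 0), 1)
  wm <- matrix(w, g$n_rows, g$n_cols)
  m <- wm * north$mean$values + (1 - wm) * south$mean$values
  s <- sqrt((wm * north$se$values)^2 + ((1 - wm) * south$se$values)^2)
  # outside the band, pass the pure side through even if the other is NA
  pure_n <- wm == 1
  pure_s <- wm == 0
  m[pure_n] <- north$mean$values[pure_n]
  s[pure_n] <- north$se$values[pure_n]
  m[pure_s] <- south$mean$values[pure_s]
  s[pure_s] <- south$se$values[pure_s]
  uncertain_layer(layer(m, g), layer(s, g))
}

#' Mask water cells
#'
#' Cells whose landcover is the water class (code 210) become nodata in
#' both the mean and SE layers.
#'
#' @param ul [uncertain_layer()].
#' @param landcover [layer()] of landcover codes.
#' @param water_code Water class code (default 210).
#' @return [uncertain_layer()].
#' @export
mask_water <- function(ul, landcover, water_code = 210) {
  stopifnot(is_uncertain_layer(ul), is_layer(landcover))
  stop_if_grid_mismatch(ul$mean$grid, landcover$grid)
  water <- !is.na(landcover$values) & landcover$values == water_code
  m <- ul$mean$values
  s <- ul$se$values
  m[water] <- NA_real_
  s[water] <- NA_real_
  uncertain_layer(layer(m, ul$mean$grid), layer(s, ul$mean$grid))
}

#' Bundle of aligned inputs for harmonization
#'
#' Validates and bundles everything [run_harmonization()] needs. All layers
#' must share one grid. `herb_ua` gives the user's accuracy of each likely
#' herbaceous class; the default uses the published area-weighted confusion
#' matrix.
#'
#' @param woody,grass,crop,tundra [uncertain_layer()]s of the four
#'   landcover-specific carbon maps for one pool (all MgC ha^-1).
#' @param treecover [uncertain_layer()] of percent tree cover (mean percent,
#'   SD percent), unstretched.
#' @param herbaceous_class Thematic [layer()]: `"crop"` or `"grass"`.
#' @param landcover [layer()] of landcover codes (used for water masking).
#' @param sparse_mask,water_mask Logical (0/1) [layer()]s. `water_mask` may
#'   be `NULL` to derive it from `landcover` code 210.
#' @param biome Thematic [layer()]: `"tundra"`, `"boreal"` or `"other"`.
#' @param herb_ua Named probabilities `c(crop = ..., grass = ...)`.
#' @param uncertainty_form Passed to [allocate_total()].
#' @return An object of class `allocation_inputs`.
#' @export
allocation_inputs <- function(woody, grass, crop, tundra, treecover,
                              herbaceous_class, landcover, sparse_mask,
                              biome, water_mask = NULL,
                              herb_ua = default_herb_ua(),
                              uncertainty_form = "printed") {
  uls <- list(woody = woody, grass = grass, crop = crop, tundra = tundra,
              treecover = treecover)
  for (nm in names(uls)) {
    if (!is_uncertain_layer(uls[[nm]]))
      stop("missing or invalid layer: ", nm)
  }
  lys <- list(herbaceous_class = herbaceous_class, landcover = landcover,
              sparse_mask = sparse_mask, biome = biome)
  for (nm in names(lys)) {
    if (!is_layer(lys[[nm]])) stop("missing or invalid layer: ", nm)
  }
  g <- woody$mean$grid
  for (ul in uls) stop_if_grid_mismatch(g, ul$mean$grid)
  for (ly in lys) stop_if_grid_mismatch(g, ly$grid)
  if (is.null(water_mask)) {
    water_mask <- layer((!is.na(landcover$values) &
                           landcover$values == 210) * 1, g)
  } else {
    stop_if_grid_mismatch(g, water_mask$grid)
  }
  if (!all(c("crop", "grass") %in% names(herb_ua)))
    stop("herb_ua must name 'crop' and 'grass' probabilities")
  structure(c(uls, lys, list(water_mask = water_mask, herb_ua = herb_ua,
                             uncertainty_form = uncertainty_form)),
            class = "allocation_inputs")
}

#' Default herbaceous-class user's accuracies
#'
#' User's accuracies of the likely-herbaceous classes from the published
#' area-weighted confusion matrix (crop about 0.79, non-crop/grass about
#' 0.96).
#'
#' @return Named numeric vector `c(crop = ..., grass = ...)`.
#' @export
default_herb_ua <- function() {
  ua <- accuracy_metrics(confusion_fixture("herbaceous"))$users
  c(crop = unname(ua["crop"]), grass = unname(ua["noncrop"]))
}

# standard fractional-allocation value for every cell (vectorized over the
# unwound grid); returns list(mean, se)
standard_path <- function(inputs, pool_layers, q, sigma_q) {
  hcls <- as.character(inputs$herbaceous_class$values)
  p_i <- ifelse(hcls == "crop", inputs$herb_ua[["crop"]],
                inputs$herb_ua[["grass"]])
  grass <- uval(as.vector(pool_layers$grass$mean$values),
                as.vector(pool_layers$grass$se$values))
  crop <- uval(as.vector(pool_layers$crop$mean$values),
               as.vector(pool_layers$crop$se$values))
  herb <- herbaceous_estimate(grass, crop, hcls, p_i)
  woody <- uval(as.vector(pool_layers$woody$mean$values),
                as.vector(pool_layers$woody$se$values))
  allocate_total(woody, herb, q, sigma_q, form = inputs$uncertainty_form)
}

# woody + grass (grass forced as the herbaceous class)
woody_grass_path <- function(inputs, pool_layers, q, sigma_q) {
  n <- length(q)
  grass <- uval(as.vector(pool_layers$grass$mean$values),
                as.vector(pool_layers$grass$se$values))
  crop <- uval(as.vector(pool_layers$crop$mean$values),
               as.vector(pool_layers$crop$se$values))
  herb <- herbaceous_estimate(grass, crop, rep("grass", n),
                              rep(inputs$herb_ua[["grass"]], n))
  woody <- uval(as.vector(pool_layers$woody$mean$values),
                as.vector(pool_layers$woody$se$values))
  allocate_total(woody, herb, q, sigma_q, form = inputs$uncertainty_form)
}

#' Run the harmonization decision tree
#'
#' Produces the harmonized map for one pool from aligned landcover-specific
#' layers. Per cell: the tundra/boreal override rules pick between the
#' tundra estimate alone, woody plus grass, or the standard fractional
#' allocation; the northern and southern methodologies are blended with
#' distance weights across 59-61 degrees N; finally water cells are masked.
#' The branch decision is computed from the AGBC layers and, for pool
#' `"bgbc"`, reapplied unchanged to the belowground layers, so both pools
#' allocate every cell identically.
#'
#' @param inputs An [allocation_inputs()] built from the AGBC layers.
#' @param pool `"agbc"` (default) to harmonize the layers in `inputs`, or
#'   `"bgbc"` together with `bgb_layers`.
#' @param bgb_layers For `pool = "bgbc"`: named list of
#'   [uncertain_layer()]s `woody`, `grass`, `crop`, `tundra` holding the
#'   belowground maps.
#' @param verbose Emit a message with branch and masked-cell counts.
#' @return [uncertain_layer()] of harmonized carbon density (MgC ha^-1).
#' @export
run_harmonization <- function(inputs, pool = c("agbc", "bgbc"),
                              bgb_layers = NULL, verbose = FALSE) {
  stopifnot(inherits(inputs, "allocation_inputs"))
  pool <- match.arg(pool)
  g <- inputs$woody$mean$grid
  pool_layers <- if (pool == "agbc") {
    inputs[c("woody", "grass", "crop", "tundra")]
  } else {
    if (is.null(bgb_layers))
      stop("pool 'bgbc' requires bgb_layers")
    need <- c("woody", "grass", "crop", "tundra")
    miss <- setdiff(need, names(bgb_layers))
    if (length(miss)) stop("bgb_layers missing: ", paste(miss, collapse = ", "))
    for (nm in need) stop_if_grid_mismatch(g, bgb_layers[[nm]]$mean$grid)
    bgb_layers[need]
  }

  lat <- matrix(row_latitudes(g), g$n_rows, g$n_cols)
  sq <- stretch_treecover(as.vector(inputs$treecover$mean$values),
                          as.vector(inputs$treecover$se$values))
  q <- sq$q
  sigma_q <- sq$sigma_q
  biome <- as.character(inputs$biome$values)
  sparse <- !is.na(inputs$sparse_mask$values) & inputs$sparse_mask$values > 0
  in_biome <- biome %in% c("tundra", "boreal")

  # decision layers always derive from the AGBC means
  tundra_agbc <- as.vector(inputs$tundra$mean$values)
  woody_agbc <- as.vector(inputs$woody$mean$values)
  tc_pct <- as.vector(inputs$treecover$mean$values)

  std <- standard_path(inputs, pool_layers, q, sigma_q)
  wg <- woody_grass_path(inputs, pool_layers, q, sigma_q)
  tun_m <- as.vector(pool_layers$tundra$mean$values)
  tun_s <- as.vector(pool_layers$tundra$se$values)

  # southern methodology: sparse override in the focal biomes, else standard
  south_m <- std$mean
  south_s <- std$se
  s_tun <- in_biome & as.vector(sparse)
  south_m[s_tun] <- tun_m[s_tun]
  south_s[s_tun] <- tun_s[s_tun]

  # northern methodology: full override rule set (as applied above 60 N)
  north_decision <- tundra_override(
    biome = biome, sparse = as.vector(sparse),
    latitude = rep(61, length(biome)),  # force the northern branch rules
    treecover_pct = tc_pct, tundra_agbc = tundra_agbc,
    woody_agbc = woody_agbc)
  north_m <- std$mean
  north_s <- std$se
  n_tun <- north_decision == "tundra_only"
  n_wg <- north_decision == "woody_plus_grass"
  north_m[n_tun] <- tun_m[n_tun]
  north_s[n_tun] <- tun_s[n_tun]
  north_m[n_wg] <- wg$mean[n_wg]
  north_s[n_wg] <- wg$se[n_wg]

  to_ul <- function(m, s) {
    uncertain_layer(layer(matrix(m, g$n_rows, g$n_cols), g),
                    layer(matrix(pmax(s, 0), g$n_rows, g$n_cols), g))
  }
  blended <- blend_60n(to_ul(north_m, north_s), to_ul(south_m, south_s))
  out <- mask_water(blended, inputs$landcover)

  if (verbose) {
    eff <- tundra_override(biome, as.vector(sparse), as.vector(lat),
                           tc_pct, tundra_agbc, woody_agbc)
    message(sprintf(
      "branches: standard %d, tundra_only %d, woody_plus_grass %d; water-masked %d",
      sum(eff == "standard"), sum(eff == "tundra_only"),
      sum(eff == "woody_plus_grass"),
      sum(!is.na(inputs$landcover$values) & inputs$landcover$values == 210)))
  }
  out
}
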
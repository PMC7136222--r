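# Seeded generator of a complete miniature input world: a high-latitude
# 64 x 64 grid spanning the 59-61 N blend band, with landcover, biomes,
# tree cover, the four landcover-specific carbon maps for both pools, crop
# yield stacks, country origin-evidence tables and ancillary climate
# layers. Everything is deterministic under the configured seed so tests
# and the end-to-end reference comparison are exactly reproducible.

#' Configuration of the synthetic input world
#'
#' Defaults describe the stated test world: a 64 x 64 grid of 0.25 degree
#' cells whose rows run from 66 N down to 50 N, crossing the tundra (> 63 N),
#' boreal (58-63 N) and temperate zones, and straddling the 59-61 N blend
#' band. Noise levels and biomass ranges are chosen to resemble the real
#' products' magnitudes (woody carbon up to ~60 MgC ha^-1 with ~20% relative
#' error, grassland carbon capped near 2.3 MgC ha^-1, tundra carbon a few
#' MgC ha^-1, crops up to ~8 MgC ha^-1).
#'
#' @param n Grid edge length (default 64).
#' @param seed Integer seed controlling every random field.
#' @param cell_size Cell size, degrees (default 0.25).
#' @param ymax Latitude of the grid's top edge (default 66).
#' @param xmin Longitude of the left edge (default 20).
#' @param water_fraction Share of cells set to water code 210
#'   (default 0.03).
#' @param herb_zero If `TRUE`, grass/crop/tundra biomass is zeroed (for
#'   degenerate-world checks).
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(n = 64, seed = 42, cell_size = 0.25, ymax = 66,
                         xmin = 20, water_fraction = 0.03,
                         herb_zero = FALSE) {
  stopifnot(n >= 8, water_fraction >= 0, water_fraction < 1)
  structure(list(n = as.integer(n), seed = as.integer(seed),
                 cell_size = cell_size, ymax = ymax, xmin = xmin,
                 water_fraction = water_fraction, herb_zero = herb_zero),
            class = "synth_config")
}

# white noise smoothed by a few 3x3 moving-average passes
smooth_noise <- function(nr, nc, sd = 1, passes = 2) {
  m <- matrix(stats::rnorm(nr * nc, 0, sd), nr, nc)
  for (p in seq_len(passes)) {
    padded <- m[c(1, seq_len(nr), nr), c(1, seq_len(nc), nc)]
    acc <- matrix(0, nr, nc)
    for (di in 0:2) for (dj in 0:2)
      acc <- acc + padded[di + seq_len(nr), dj + seq_len(nc)]
    m <- acc / 9
  }
  m
}

#' Generate the full synthetic input stack
#'
#' Builds every input the pipeline and harmonization need, with known
#' structure: an [allocation_inputs()] bundle (AGBC layers), the matching
#' belowground layers, a [crop_stack()], a [country_forest_table()] with
#' consistent per-country mapped areas, and ancillary layers (Koppen codes,
#' MAT, country ids, intact/planted masks, an NDVI composite series and an
#' ANPP series). When `dir` is given, the rasters are also written as
#' GeoTIFFs and the tables as CSVs so file-based entry points can be
#' exercised.
#'
#' @param cfg A [synth_config()].
#' @param dir Optional directory to write GeoTIFF/CSV copies into.
#' @return A list with elements `inputs` (class `allocation_inputs`),
#'   `bgb_layers`, `crops` (class `crop_stack`), `country_table`,
#'   `ancillary` (list of layers and series) and `grid`.
#' @export
generate_stack <- function(cfg = synth_config(), dir = NULL) {
  stopifnot(inherits(cfg, "synth_config"))
  with_local_seed(cfg$seed, generate_stack_impl(cfg, dir))
}

generate_stack_impl <- function(cfg, dir) {
  n <- cfg$n
  g <- grid_spec(n, n, cell_size = cfg$cell_size, xmin = cfg$xmin,
                 ymax = cfg$ymax)
  lat <- matrix(row_latitudes(g), n, n)
  lon <- matrix(col_longitudes(g), n, n, byrow = TRUE)

  # biome bands with a wavy boundary
  wob <- smooth_noise(n, n, 0.6, passes = 3)
  biome <- ifelse(lat + wob > 63, "tundra",
                  ifelse(lat + wob > 58, "boreal", "other"))

  # Koppen codes consistent with the biome bands
  kg <- ifelse(biome == "tundra", 31L,
               ifelse(biome == "boreal", 20L,
                      ifelse(lat > 54, 19L, 10L)))

  # mean annual temperature: cold north, warm south
  mat <- 12 - (lat - 50) * 1.2 + smooth_noise(n, n, 0.8)

  # landcover: forests dominate mid-latitudes, crops/savannah the south,
  # shrub/grass/sparse the north
  u <- matrix(stats::runif(n * n), n, n)
  code <- matrix(130L, n, n)
  north <- biome == "tundra"
  mid <- biome == "boreal"
  south <- biome == "other"
  code[north] <- ifelse(u[north] < 0.45, 150L,
                        ifelse(u[north] < 0.75, 120L, 130L))
  code[mid] <- ifelse(u[mid] < 0.35, 70L,
                      ifelse(u[mid] < 0.5, 90L,
                             ifelse(u[mid] < 0.6, 150L,
                                    ifelse(u[mid] < 0.8, 130L, 60L))))
  code[south] <- ifelse(u[south] < 0.3, 10L,
                        ifelse(u[south] < 0.45, 122L,
                               ifelse(u[south] < 0.6, 50L,
                                      ifelse(u[south] < 0.85, 130L, 60L))))
  water <- matrix(stats::runif(n * n) < cfg$water_fraction, n, n)
  code[water] <- 210L
  landcover <- layer(code, g)

  scheme <- read_class_scheme()
  herb_label <- aggregate_classes(landcover, scheme_mapping(scheme, "herbaceous"))
  sparse_map <- aggregate_classes(landcover, scheme_mapping(scheme, "sparse"))
  sparse_mask <- layer((sparse_map$values == "1") * 1, g)

  # tree cover (percent): peaks in the boreal/temperate forest belt
  tc <- 55 * exp(-((lat - 56) / 6)^2) + 8 * smooth_noise(n, n, 1)
  tc <- pmin(pmax(tc, 0), 95)
  tc[water] <- 0
  tc_sd <- pmin(3 + 0.08 * tc, 15)
  treecover <- uncertain_layer(layer(tc, g), layer(tc_sd, g))

  # woody AGBC: scales with tree cover, ~20% relative SE
  woody_m <- pmax(tc / 80 * (35 + 6 * smooth_noise(n, n, 1)), 0)
  woody_s <- 0.2 * woody_m
  woody <- uncertain_layer(layer(woody_m, g), layer(woody_s, g))

  # herbaceous pools (zeroed in the degenerate world)
  zmul <- if (cfg$herb_zero) 0 else 1
  grass_m <- zmul * pmin(pmax(1.2 + 0.5 * smooth_noise(n, n, 1), 0), 2.3)
  grass <- uncertain_layer(layer(grass_m, g), layer(0.15 * grass_m, g))
  is_crop_cell <- matrix(code %in% c(10L, 20L, 30L), n, n)
  crop_m <- zmul * ifelse(is_crop_cell,
                          pmax(4 + 1.5 * smooth_noise(n, n, 1), 0), 0)
  crop_ul <- uncertain_layer(layer(crop_m, g), layer(0.1 * crop_m, g))
  tundra_m <- zmul * pmax((lat - 56) / 10 * (4 + smooth_noise(n, n, 0.8)), 0)
  tundra <- uncertain_layer(layer(tundra_m, g), layer(0.25 * tundra_m, g))

  # belowground counterparts via plausible (not package-derived) ratios
  bgb_layers <- list(
    woody = uncertain_layer(layer(0.27 * woody_m, g),
                            layer(0.3 * 0.27 * woody_m, g)),
    grass = uncertain_layer(layer(4.2 * grass_m, g),
                            layer(0.25 * 4.2 * grass_m, g)),
    crop = uncertain_layer(layer(0.12 * crop_m, g),
                           layer(0.15 * 0.12 * crop_m, g)),
    tundra = uncertain_layer(layer(3.5 * tundra_m, g),
                             layer(0.35 * 3.5 * tundra_m, g)))

  inputs <- allocation_inputs(
    woody = woody, grass = grass, crop = crop_ul, tundra = tundra,
    treecover = treecover, herbaceous_class = herb_label,
    landcover = landcover, sparse_mask = sparse_mask,
    biome = layer(biome, g))

  # countries: a west/east split with origin evidence
  country <- layer(matrix(ifelse(lon < cfg$xmin + n * cfg$cell_size / 2,
                                 1L, 2L), n, n), g)
  ifl_mask <- layer(((country$values == 1L) & (lat > 62) & !water) * 1, g)
  sdpt_mask <- layer(((country$values == 2L) & (lat < 54) &
                        (u < 0.25) & !water) * 1, g)
  cell_ha <- 1000  # nominal area per cell for the synthetic country ledger
  ifl_ha <- c(sum(ifl_mask$values[country$values == 1L]),
              sum(ifl_mask$values[country$values == 2L])) * cell_ha
  sdpt_ha <- c(sum(sdpt_mask$values[country$values == 1L]),
               sum(sdpt_mask$values[country$values == 2L])) * cell_ha
  country_table <- country_forest_table(data.frame(
    country_id = c(1L, 2L),
    fra_natural_ha = ifl_ha + c(8e5, 6e5),
    fra_planted_ha = sdpt_ha + c(1e5, 2e5),
    faostat_treecrop_ha = c(5e4, 3e5),
    ifl_mapped_ha = ifl_ha,
    sdpt_mapped_ha = sdpt_ha))

  # crop stack on the same grid: three crops with parameter rows
  params <- rbind(crop_parameters("wheat", 0.87, 0.39, 0.45, 0.20),
                  crop_parameters("maize", 0.86, 0.53, 0.45, 0.18),
                  crop_parameters("soy", 0.91, 0.42, 0.54, 0.19))
  mk_yield <- function(base) {
    layer(ifelse(is_crop_cell,
                 pmax(base + smooth_noise(n, n, 0.6), 0.1), 0), g)
  }
  extent_ha <- layer(ifelse(is_crop_cell, cell_ha * 0.8, 0), g)
  mk_area <- function(share) {
    layer(ifelse(is_crop_cell, cell_ha * 0.8 * share, 0), g)
  }
  crops <- crop_stack(
    yields = list(wheat = mk_yield(3), maize = mk_yield(5),
                  soy = mk_yield(2.5)),
    areas = list(wheat = mk_area(0.4), maize = mk_area(0.35),
                 soy = mk_area(0.25)),
    extent = extent_ha, parameters = params)

  # ANPP series 2000-2015: regional trend plus noise
  trend <- 0.05 * (lat < 58) - 0.02 * (lat >= 63)
  anpp_series <- stats::setNames(lapply(0:15, function(t) {
    layer(pmax(4 + trend * t + 0.3 * smooth_noise(n, n, 1), 0), g)
  }), 2000:2015)

  # six NDVI composites around a smooth seasonal surface
  ndvi_base <- pmin(pmax(0.35 + 0.25 * exp(-((lat - 56) / 6)^2) +
                           0.05 * smooth_noise(n, n, 1), 0), 0.95)
  ndvi_series <- lapply(1:6, function(i) {
    layer(pmin(pmax(ndvi_base + stats::rnorm(1, 0, 0.02) +
                      0.03 * smooth_noise(n, n, 1), -1), 1), g)
  })

  ancillary <- list(kg = layer(kg, g), mat = layer(mat, g),
                    country_id = country, ifl_mask = ifl_mask,
                    sdpt_mask = sdpt_mask, anpp_series = anpp_series,
                    ndvi_series = ndvi_series, scheme = scheme)

  stack <- list(inputs = inputs, bgb_layers = bgb_layers, crops = crops,
                country_table = country_table, ancillary = ancillary,
                grid = g)
  if (!is.null(dir)) write_stack(stack, dir)
  stack
}

# write the stack's rasters/tables to a directory (float32 intermediates)
write_stack <- function(stack, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(l, name) write_float_geotiff(l, file.path(dir, paste0(name, ".tif")))
  inp <- stack$inputs
  for (nm in c("woody", "grass", "crop", "tundra", "treecover")) {
    wr(inp[[nm]]$mean, nm)
    wr(inp[[nm]]$se, paste0(nm, "_se"))
  }
  for (nm in names(stack$bgb_layers)) {
    wr(stack$bgb_layers[[nm]]$mean, paste0("bgb_", nm))
    wr(stack$bgb_layers[[nm]]$se, paste0("bgb_", nm, "_se"))
  }
  num_landcover <- layer(stack$inputs$landcover$values + 0, stack$grid)
  wr(num_landcover, "landcover")
  wr(stack$inputs$sparse_mask, "sparse_mask")
  biome_code <- matrix(match(stack$inputs$biome$values,
                             c("other", "boreal", "tundra")) - 1,
                       stack$grid$n_rows, stack$grid$n_cols)
  wr(layer(biome_code, stack$grid), "biome_code")
  wr(stack$ancillary$kg, "kg")
  wr(stack$ancillary$mat, "mat")
  utils::write.csv(stack$country_table,
                   file.path(dir, "country_forest_table.csv"),
                   row.names = FALSE)
  utils::write.csv(stack$crops$parameters,
                   file.path(dir, "crop_parameters.csv"), row.names = FALSE)
  invisible(dir)
}
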
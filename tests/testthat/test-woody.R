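test_that("regional-map SE polynomial matches direct evaluation over its domain", {
  expect_equal(bouvet_se(0), 0)
  expect_equal(bouvet_se(50), 1.0551 * 50 - 0.007 * 2500 - 0.0000273 * 125000)
  expect_equal(bouvet_se(85), oracle_bouvet(85))
  expect_error(bouvet_se(86), "domain")
  expect_error(bouvet_se(-1), "domain")
  set.seed(71)
  agb <- runif(100, 0, 85)
  expect_equal(bouvet_se(agb), oracle_bouvet(agb))
  # non-negative over the domain, with an interior maximum
  grid_scan <- bouvet_se(seq(0, 85, by = 0.1))
  expect_true(all(grid_scan >= 0))
  peak <- which.max(grid_scan)
  expect_gt(peak, 1)
  expect_lt(peak, length(grid_scan))
})

test_that("map merging prioritises the regional map except in closed/flooded forest", {
  g <- grid_spec(2, 2, 1, 0, 2)
  global <- uncertain_layer(matrix(c(10, 20, 30, 40), 2, 2), 1, grid = g)
  reg_m <- matrix(c(50, NA, 60, 70), 2, 2)
  regional <- uncertain_layer(layer(reg_m, g),
                              layer(reg_m * 0.1, g))
  # [1,1] savannah, [2,1] outside footprint, [1,2] closed forest, [2,2] crop
  lc <- layer(matrix(c(122L, 130L, 50L, 10L), 2, 2), g)
  scheme <- read_class_scheme()
  merged <- merge_woody_maps(global, regional, lc,
                             scheme_mapping(scheme, "closed_flooded"))
  expect_equal(merged$mean$values, matrix(c(50, 20, 30, 70), 2, 2))
  expect_equal(merged$se$values[1, 1], 5)
  expect_equal(merged$se$values[1, 2], 1)  # closed forest keeps global SE
  # output equals one of the two inputs cell-wise (no blending)
  one_of <- merged$mean$values == global$mean$values |
    (!is.na(reg_m) & merged$mean$values == reg_m)
  expect_true(all(one_of))
  expect_error(
    merge_woody_maps(global, uncertain_layer(matrix(1, 3, 3), 0,
                                             grid = grid_spec(3, 3, 1)),
                     lc, scheme_mapping(scheme, "closed_flooded")),
    "grid mismatch")
})

test_that("biomass-to-carbon conversion applies stratified fractions with product SE", {
  g <- grid_spec(1, 3, 1, 0, 1)
  agb <- uncertain_layer(layer(matrix(c(100, 0, 100), 1, 3), g),
                         layer(matrix(c(0, 0, 10), 1, 3), g))
  kg <- layer(matrix(c(1L, 1L, 20L), 1, 3), g)
  phylo <- layer(matrix(c("angiosperm", "angiosperm", "gymnosperm"), 1, 3), g)
  out <- agb_to_agbc(agb, kg, phylo)
  expect_equal(out$mean$values[1, 1], 45.4)           # 100 * 0.454 (Tropical)
  expect_equal(out$se$values[1, 1], 100 * 0.003)
  expect_equal(out$mean$values[1, 2], 0)
  expect_equal(out$se$values[1, 2], 0)
  expect_equal(out$mean$values[1, 3], 100 * 0.476)    # Boreal gymnosperm
  expect_equal(out$se$values[1, 3],
               oracle_product_se(100, 10, 0.476, 0.009))
  # unresolvable stratum -> nodata with a message
  phylo2 <- layer(matrix(c("angiosperm", "none", "gymnosperm"), 1, 3), g)
  expect_message(out2 <- agb_to_agbc(agb, kg, phylo2), "unresolvable")
  expect_true(is.na(out2$mean$values[1, 2]))
})

test_that("origin weights honour masks, down-weighting and residual splits", {
  g <- grid_spec(1, 5, 1, 0, 1)
  country <- layer(matrix(c(1L, 1L, 1L, 2L, 2L), 1, 5), g)
  ifl <- layer(matrix(c(1, 0, 0, 0, 0), 1, 5), g)
  sdpt <- layer(matrix(c(0, 1, 0, 1, 0), 1, 5), g)
  tab <- country_forest_table(data.frame(
    country_id = c(1L, 2L),
    fra_natural_ha = c(1000, 500),
    fra_planted_ha = c(300, 100),
    faostat_treecrop_ha = c(0, 400),   # tree crops exceed planted in country 2
    ifl_mapped_ha = c(200, 0),
    sdpt_mapped_ha = c(100, 800)))     # SDPT exceeds planted total in country 2
  w <- origin_weights(tab, country, ifl, sdpt)
  expect_equal(w$planted$values[1, 1], 0)      # IFL -> natural
  expect_equal(w$natural$values[1, 1], 1)
  expect_equal(w$planted$values[1, 2], 1)      # SDPT within planted total
  # country 1 residual: D_p = 300-100 = 200, D_n = 1000-200 = 800
  expect_equal(w$planted$values[1, 3], 200 / 1000)
  # country 2 SDPT down-weighted: planted_total = 100 + 300 = 400; 400/800
  expect_equal(w$planted$values[1, 4], 0.5)
  # country 2 residual: D_p = max(0, 400-800) = 0, D_n = 500
  expect_equal(w$planted$values[1, 5], 0)
  # weights always sum to one
  expect_equal(w$planted$values + w$natural$values, matrix(1, 1, 5))

  # equal residuals give a 50/50 split
  tab2 <- country_forest_table(data.frame(
    country_id = 1L, fra_natural_ha = 400, fra_planted_ha = 400,
    faostat_treecrop_ha = 0, ifl_mapped_ha = 0, sdpt_mapped_ha = 0))
  g1 <- grid_spec(1, 1, 1, 0, 1)
  w2 <- origin_weights(tab2, layer(matrix(1L, 1, 1), g1),
                       layer(matrix(0, 1, 1), g1), layer(matrix(0, 1, 1), g1))
  expect_equal(w2$planted$values[1, 1], 0.5)

  # zero residuals with unknown-origin cells -> (0.5, 0.5) and a warning
  tab3 <- country_forest_table(data.frame(
    country_id = 1L, fra_natural_ha = 100, fra_planted_ha = 50,
    faostat_treecrop_ha = 0, ifl_mapped_ha = 100, sdpt_mapped_ha = 50))
  expect_warning(
    w3 <- origin_weights(tab3, layer(matrix(1L, 1, 1), g1),
                         layer(matrix(0, 1, 1), g1),
                         layer(matrix(0, 1, 1), g1)),
    "0.5")
  expect_equal(w3$planted$values[1, 1], 0.5)
})

test_that("regression belowground carbon: degenerate origins, zero SEs and ratio recovery", {
  g <- grid_spec(4, 4, 0.5, 0, 60)
  set.seed(81)
  agbc_m <- matrix(runif(16, 5, 80), 4, 4)
  agbc <- uncertain_layer(layer(agbc_m, g), layer(0 * agbc_m, g))
  mat <- uncertain_layer(layer(matrix(2, 4, 4), g), layer(matrix(0, 4, 4), g))
  angio <- layer(matrix(0.5, 4, 4), g)
  natural <- structure(list(planted = layer(matrix(0, 4, 4), g),
                            natural = layer(matrix(1, 4, 4), g)),
                       class = "origin_weights")

  # ratio-form model: exact linear recovery, zero SE when everything is exact
  m_ratio <- root_regression_model(c(ratio = 0.285), form = "ratio")
  out <- regression_bgbc(agbc, mat, angio, natural, m_ratio, phylo_ua = 1)
  expect_equal(out$mean$values, 0.285 * agbc_m)
  expect_equal(max(out$se$values), 0)

  # w_natural = 1 makes the weighted prediction the natural one exactly
  m_log <- default_root_model()
  out_n <- regression_bgbc(agbc, mat, angio, natural, m_log, phylo_ua = 1)
  direct <- exp(m_log$coef[["intercept"]] +
                  m_log$coef[["log_agbc"]] * log(agbc_m) +
                  m_log$coef[["mat"]] * 2 + m_log$coef[["angiosperm"]] * 0.5)
  expect_equal(out_n$mean$values, direct, tolerance = 1e-12)

  # fully planted shifts by the planted coefficient
  planted <- structure(list(planted = layer(matrix(1, 4, 4), g),
                            natural = layer(matrix(0, 4, 4), g)),
                       class = "origin_weights")
  out_p <- regression_bgbc(agbc, mat, angio, planted, m_log, phylo_ua = 1)
  expect_equal(out_p$mean$values / out_n$mean$values,
               matrix(exp(m_log$coef[["planted"]]), 4, 4))

  # SE responds to AGBC uncertainty through the finite-difference partial
  agbc_u <- uncertain_layer(layer(agbc_m, g), layer(0.1 * agbc_m, g))
  out_u <- regression_bgbc(agbc_u, mat, angio, natural, m_ratio, phylo_ua = 1)
  expect_equal(out_u$se$values, 0.285 * 0.1 * agbc_m, tolerance = 1e-6)
  expect_error(regression_bgbc(agbc, mat, angio, natural,
                               list(form = "log_linear")),
               "root_regression_model")
})

test_that("static-ratio belowground carbon uses the printed ratios with product SE", {
  g <- grid_spec(1, 3, 1, 0, 1)
  agbc <- uncertain_layer(layer(matrix(c(10, 10, 0), 1, 3), g),
                          layer(matrix(0, 1, 3), g))
  stratum <- layer(matrix(c("Savannah", "Shrub", "Savannah"), 1, 3), g)
  out <- static_ratio_bgbc(agbc, stratum)
  expect_equal(out$mean$values[1, ], c(6.42, 18.37, 0))
  expect_equal(out$se$values[1, 1], 10 * 0.111)  # 1.11
  expect_equal(out$se$values[1, 3], 0)
  # linear in the AGBC mean
  agbc2 <- uncertain_layer(layer(matrix(c(20, 20, 0), 1, 3), g),
                           layer(matrix(0, 1, 3), g))
  expect_equal(static_ratio_bgbc(agbc2, stratum)$mean$values,
               2 * out$mean$values)
  # unknown stratum -> nodata
  bad <- layer(matrix(c("Savannah", "Asteroid", "Shrub"), 1, 3), g)
  expect_true(is.na(static_ratio_bgbc(agbc, bad)$mean$values[1, 2]))
  # printed table fidelity
  expected <- read.csv(test_path("fixtures", "root_shoot_expected.csv"),
                       stringsAsFactors = FALSE)
  expect_equal(root_shoot_table()$stratum, expected$stratum)
  expect_equal(root_shoot_table()$mean, expected$mean)
  expect_equal(root_shoot_table()$se, expected$se)
})
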
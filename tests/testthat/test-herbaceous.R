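test_that("NDVI calibration is linear with quadrature SE", {
  g <- grid_spec(1, 2, 1, 0, 1)
  ndvi <- layer(matrix(c(0.6, 0.2), 1, 2), g)
  ident <- calibrate_ndvi(ndvi, ndvi_calibration())
  expect_equal(ident$mean$values, ndvi$values)
  expect_equal(max(ident$se$values), 0)

  cal <- ndvi_calibration(gain = 1.05, offset = -0.02,
                          gain_se = 0.01, offset_se = 0.005)
  out <- calibrate_ndvi(ndvi, cal)
  expect_equal(out$mean$values[1, 1], 1.05 * 0.6 - 0.02)
  expect_equal(out$se$values[1, 1], sqrt((0.6 * 0.01)^2 + 0.005^2))
})

test_that("percentile composite interpolates order statistics per cell", {
  g <- grid_spec(1, 1, 1, 0, 1)
  mk <- function(x) layer(matrix(x, 1, 1), g)
  series <- lapply(c(0.2, 0.4, 0.6, 0.8, 1.0), mk)
  expect_equal(percentile_composite(series, 80)$values[1, 1], 0.84)
  expect_equal(percentile_composite(series, 100)$values[1, 1], 1.0)
  expect_equal(percentile_composite(lapply(rep(0.5, 4), mk), 37)$values[1, 1],
               0.5)
  # order invariance
  set.seed(91)
  vals <- runif(7)
  expect_equal(percentile_composite(lapply(vals, mk), 80)$values,
               percentile_composite(lapply(sample(vals), mk), 80)$values)
  # nodata handling: cells with no valid observation stay nodata
  series_na <- list(mk(NA_real_), mk(NA_real_))
  expect_true(is.na(percentile_composite(series_na, 80)$values[1, 1]))
  expect_error(percentile_composite(list(), 80), "empty")
})

test_that("NDVI-to-AGBC models evaluate, clamp, cap and propagate coefficient SEs", {
  g <- grid_spec(1, 3, 1, 0, 1)
  ndvi <- uncertain_layer(layer(matrix(c(0.25, 0.5, 1), 1, 3), g),
                          layer(matrix(0, 1, 3), g))
  # synthetic power-law model against closed-form evaluation
  m <- agbc_regression(c(a = 2.3, b = 1.7), form = "power")
  out <- apply_agbc_model(ndvi, m)
  expect_equal(out$mean$values[1, ], 2.3 * c(0.25, 0.5, 1)^1.7)
  expect_equal(max(out$se$values), 0)
  # the cap bounds predictions (the published grassland cap is 2.3 at NDVI 1)
  m_cap <- agbc_regression(c(a = 5, b = 1), form = "power", cap = 2.3)
  expect_equal(apply_agbc_model(ndvi, m_cap)$mean$values[1, 3], 2.3)
  # monotone model preserves NDVI ordering
  ord <- order(out$mean$values[1, ])
  expect_equal(ord, order(ndvi$mean$values[1, ]))
  # out-of-domain NDVI clamps with a message
  ndvi_bad <- uncertain_layer(layer(matrix(c(-0.2, 0.5, 1.2), 1, 3), g),
                              layer(matrix(0, 1, 3), g))
  expect_message(out_bad <- apply_agbc_model(ndvi_bad, m), "clamped")
  expect_equal(out_bad$mean$values[1, 1], 0)
  # coefficient SE propagation matches a finite-difference hand computation
  m_se <- agbc_regression(c(a = 2, b = 1.5), coef_se = c(a = 0.1, b = 0),
                          form = "power")
  out_se <- apply_agbc_model(ndvi, m_se)
  expect_equal(out_se$se$values[1, 2], 0.5^1.5 * 0.1, tolerance = 1e-6)
  # relative RMSE enters in quadrature
  m_rmse <- agbc_regression(c(a = 2, b = 1.5), form = "power", rel_rmse = 0.2)
  out_r <- apply_agbc_model(ndvi, m_rmse)
  expect_equal(out_r$se$values[1, 2], 0.2 * 2 * 0.5^1.5, tolerance = 1e-9)
})

test_that("composite combination averages means and RMS-averages errors", {
  g <- grid_spec(1, 1, 1, 0, 1)
  mk <- function(m, s) uncertain_layer(layer(matrix(m, 1, 1), g),
                                       layer(matrix(s, 1, 1), g))
  one <- mk(3.5, 0.4)
  expect_equal(combine_composites(list(one)), one)
  two <- combine_composites(list(mk(2, 3), mk(4, 4)))
  expect_equal(two$mean$values[1, 1], 3)
  expect_equal(two$se$values[1, 1], sqrt(12.5))
  same <- combine_composites(rep(list(one), 5))
  expect_equal(same$mean$values, one$mean$values)
  expect_equal(same$se$values, one$se$values)
  expect_error(combine_composites(list()), "empty")
})

test_that("tundra carbon fraction multiplies by 0.492 with SE 0.008", {
  g <- grid_spec(1, 2, 1, 0, 1)
  agb <- uncertain_layer(layer(matrix(c(10, 0), 1, 2), g),
                         layer(matrix(c(0, 0), 1, 2), g))
  out <- tundra_c_fraction(agb)
  expect_equal(out$mean$values[1, ], c(4.92, 0))
  expect_equal(out$se$values[1, ], c(0.08, 0))
  agb_u <- uncertain_layer(layer(matrix(10, 1, 1), grid_spec(1, 1, 1)),
                           layer(matrix(1, 1, 1), grid_spec(1, 1, 1)))
  expect_equal(tundra_c_fraction(agb_u)$se$values[1, 1],
               sqrt((0.492 * 1)^2 + (10 * 0.008)^2))
})

test_that("tundra belowground switches between the MAT model and the woody path at 25 Mg/ha", {
  g <- grid_spec(1, 3, 1, 0, 61)
  # AGB 25 exactly stays on the MAT-ratio path; 26 goes to the woody path
  agb <- uncertain_layer(layer(matrix(c(10, 25, 26), 1, 3), g),
                         layer(matrix(0, 1, 3), g))
  agbc <- uncertain_layer(layer(0.492 * agb$mean$values, g),
                          layer(matrix(0, 1, 3), g))
  mat <- uncertain_layer(layer(matrix(-5, 1, 3), g), layer(matrix(0, 1, 3), g))
  wm <- wang_model(c(a = 3.2, b = -0.12), form = "linear", min_ratio = 0.2)
  reich <- list(phylogeny_fraction = layer(matrix(0.5, 1, 3), g),
                origin = structure(list(planted = layer(matrix(0, 1, 3), g),
                                        natural = layer(matrix(1, 1, 3), g)),
                                   class = "origin_weights"),
                model = root_regression_model(c(ratio = 0.3), form = "ratio"),
                phylo_ua = 1)
  out <- tundra_bgbc(agbc, agb, mat, wm, reich)
  ratio <- 3.2 - 0.12 * (-5)
  expect_equal(out$mean$values[1, 1], 0.492 * 10 * ratio)
  expect_equal(out$mean$values[1, 2], 0.492 * 25 * ratio)   # threshold inclusive
  expect_equal(out$mean$values[1, 3], 0.3 * 0.492 * 26)     # woody path
  # constant-ratio stand-in: BGBC / AGBC constant across MAT
  wm_const <- wang_model(c(a = 2, b = 0), form = "linear")
  mat2 <- uncertain_layer(layer(matrix(c(-10, 0, 5), 1, 3), g),
                          layer(matrix(0, 1, 3), g))
  agb_small <- uncertain_layer(layer(matrix(10, 1, 3), g),
                               layer(matrix(0, 1, 3), g))
  agbc_small <- uncertain_layer(layer(matrix(4.92, 1, 3), g),
                                layer(matrix(0, 1, 3), g))
  out2 <- tundra_bgbc(agbc_small, agb_small, mat2, wm_const)
  expect_equal(out2$mean$values / agbc_small$mean$values, matrix(2, 1, 3))
  # needing the woody path without configuration is an error
  expect_error(tundra_bgbc(agbc, agb, mat, wm), "reich_args")
})

test_that("grassland belowground applies climate-specific printed ratios", {
  g <- grid_spec(1, 3, 1, 0, 1)
  agbc <- uncertain_layer(layer(matrix(1, 1, 3), g), layer(matrix(0, 1, 3), g))
  kg <- layer(matrix(c(1L, 10L, 31L), 1, 3), g)
  out <- grassland_bgbc(agbc, kg)
  expect_equal(out$mean$values[1, ], c(1.887, 4.224, 4.804))
  # ratio is exactly the table value in every zero-SE cell
  agbc2 <- uncertain_layer(layer(matrix(2.5, 1, 3), g),
                           layer(matrix(0, 1, 3), g))
  out2 <- grassland_bgbc(agbc2, kg)
  expect_equal(out2$mean$values / 2.5, out$mean$values)
  expect_error(grassland_bgbc(agbc, layer(matrix(50L, 1, 3), g)), "unknown")
})
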
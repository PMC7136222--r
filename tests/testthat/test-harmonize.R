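test_that("tree-cover stretch treats 80% as complete cover", {
  expect_equal(stretch_treecover(80)$q, 1)
  expect_equal(stretch_treecover(0)$q, 0)
  expect_equal(stretch_treecover(40)$q, 0.5)
  expect_equal(stretch_treecover(95)$q, 1)  # clamped above saturation
  expect_equal(stretch_treecover(40, 8)$sigma_q, 0.1)
  expect_error(stretch_treecover(-5), ">= 0")
})

test_that("herbaceous estimate mixes classes by user's accuracy", {
  got <- herbaceous_estimate(uval(2, 0), uval(10, 0), "crop", 0.79)
  expect_equal(got$mean, 10 * 0.79 + 2 * 0.21)  # 8.32
  exact <- herbaceous_estimate(uval(2, 0.3), uval(10, 1), "crop", 1)
  expect_equal(exact$mean, 10)
  expect_equal(exact$se, 1)
  same <- herbaceous_estimate(uval(4, 0), uval(4, 0), "grass", 0.6)
  expect_equal(same$mean, 4)
  expect_error(herbaceous_estimate(uval(1, 0), uval(1, 0), "kelp", 0.5),
               "unknown")
})

test_that("allocate_total follows the printed uncertainty form and its collapses", {
  expect_equal(allocate_total(uval(40, 0), uval(2, 0), 0, 0)$mean, 42)
  q1 <- allocate_total(uval(40, 4), uval(2, 0), 1, 0)
  expect_equal(q1$mean, 40)
  expect_equal(q1$se, 4)
  got <- allocate_total(uval(40, 4), uval(2, 0.5), 0.5, 0.1)
  expect_equal(got$mean, 41)
  expect_equal(got$se, sqrt(16 + 0.0625 + 0.04))
  set.seed(121)
  for (i in 1:100) {
    mw <- runif(1, 0, 80); sw <- runif(1, 0, 8)
    mh <- runif(1, 0.1, 5); sh <- runif(1, 0.01, 1)
    q <- runif(1, 0.05, 1); sq <- runif(1, 0, 0.1)
    got <- allocate_total(uval(mw, sw), uval(mh, sh), q, sq)
    expect_equal(got$mean, oracle_alloc_mean(mw, mh, q))
    expect_equal(got$se, oracle_alloc_se(sw, mh, sh, q, sq))
  }
  # collapse: zero herbaceous and tree-cover errors leave the woody SE
  col <- allocate_total(uval(30, 3), uval(2, 0), 0.4, 0)
  expect_equal(col$se, 3)
  # the complement form swaps q for (1 - q) in the herbaceous error term
  comp <- allocate_total(uval(0, 0), uval(10, 1), 0.25, 0,
                         form = "complement")
  expect_equal(comp$se, 0.75)
  expect_error(allocate_total(uval(1, 0), uval(1, 0), 1.5, 0), "\\[0, 1\\]")
})

test_that("tundra/boreal override decisions cover every branch", {
  # sparse cell in a focal biome -> tundra regardless of latitude
  expect_equal(tundra_override("boreal", TRUE, 55, 50, 1, 10), "tundra_only")
  # north with low tree cover -> tundra
  expect_equal(tundra_override("tundra", FALSE, 65, 5, 1, 10), "tundra_only")
  # north, tundra exceeds woody -> tundra
  expect_equal(tundra_override("boreal", FALSE, 65, 50, 12, 10), "tundra_only")
  # north otherwise -> woody plus grass (ties keep the woody branch)
  expect_equal(tundra_override("boreal", FALSE, 65, 50, 10, 10),
               "woody_plus_grass")
  # south of 60 in the focal biomes, non-sparse -> standard
  expect_equal(tundra_override("boreal", FALSE, 59, 5, 12, 10), "standard")
  # outside the focal biomes always standard
  expect_equal(tundra_override("other", TRUE, 65, 0, 99, 0), "standard")
  # vectorized: every cell is assigned exactly one branch
  set.seed(131)
  n <- 500
  dec <- tundra_override(sample(c("tundra", "boreal", "other"), n, TRUE),
                         sample(c(TRUE, FALSE), n, TRUE),
                         runif(n, 50, 70), runif(n, 0, 100),
                         runif(n, 0, 20), runif(n, 0, 20))
  expect_true(all(dec %in% c("tundra_only", "woody_plus_grass", "standard")))
  expect_equal(length(dec), n)
})

test_that("60N blending weights by linear proximity with exact endpoints", {
  g <- grid_spec(6, 1, 1, 0, 62)  # centers 61.5, 60.5, ..., 56.5
  lats <- row_latitudes(g)  # 61.5 60.5 59.5 58.5 ...
  north <- uncertain_layer(layer(matrix(10, 6, 1), g),
                           layer(matrix(2, 6, 1), g))
  south <- uncertain_layer(layer(matrix(20, 6, 1), g),
                           layer(matrix(4, 6, 1), g))
  out <- blend_60n(north, south)
  w <- pmin(pmax((lats - 59) / 2, 0), 1)
  expect_equal(out$mean$values[, 1], w * 10 + (1 - w) * 20)
  expect_equal(out$se$values[, 1], sqrt((w * 2)^2 + ((1 - w) * 4)^2))
  # exact endpoints at 60 (average), 61 (north), 59 (south): half-degree rows
  g2 <- grid_spec(5, 1, 0.5, 0, 61.25)  # centers 61, 60.5, 60, 59.5, 59
  n2 <- uncertain_layer(layer(matrix(10, 5, 1), g2), layer(matrix(0, 5, 1), g2))
  s2 <- uncertain_layer(layer(matrix(20, 5, 1), g2), layer(matrix(0, 5, 1), g2))
  out2 <- blend_60n(n2, s2)
  expect_equal(out2$mean$values[, 1], c(10, 12.5, 15, 17.5, 20))
  # a pure side passes through even when the other side is nodata
  s_na <- uncertain_layer(layer(matrix(NA_real_, 5, 1), g2),
                          layer(matrix(NA_real_, 5, 1), g2))
  out3 <- blend_60n(n2, s_na)
  expect_equal(out3$mean$values[1, 1], 10)
  expect_true(is.na(out3$mean$values[3, 1]))
})

test_that("water masking hits exactly the water-coded cells", {
  g <- grid_spec(4, 4, 1, 0, 4)
  checker <- matrix(rep(c(210L, 130L), 8), 4, 4)
  ul <- uncertain_layer(layer(matrix(5, 4, 4), g), layer(matrix(1, 4, 4), g))
  out <- mask_water(ul, layer(checker, g))
  expect_equal(sum(is.na(out$mean$values)), 8)
  expect_equal(is.na(out$mean$values), checker == 210L)
  none <- mask_water(ul, layer(matrix(130L, 4, 4), g))
  expect_equal(none$mean$values, ul$mean$values)
  all_w <- mask_water(ul, layer(matrix(210L, 4, 4), g))
  expect_true(all(is.na(all_w$mean$values)))
})

test_that("run_harmonization collapses to the woody layer in a zero-herbaceous world", {
  st <- generate_stack(synth_config(n = 24, seed = 9, herb_zero = TRUE))
  out <- run_harmonization(st$inputs)
  inp <- st$inputs
  lat <- matrix(row_latitudes(st$grid), st$grid$n_rows, st$grid$n_cols)
  water <- inp$landcover$values == 210L
  # wherever no override fires and not water, total equals woody exactly
  dec <- matrix(tundra_override(as.character(inp$biome$values),
                                inp$sparse_mask$values > 0,
                                as.vector(lat),
                                as.vector(inp$treecover$mean$values),
                                as.vector(inp$tundra$mean$values),
                                as.vector(inp$woody$mean$values)),
                st$grid$n_rows, st$grid$n_cols)
  plain <- dec != "tundra_only" & !water & lat >= 61
  expect_equal(out$mean$values[plain & dec == "woody_plus_grass"],
               inp$woody$mean$values[plain & dec == "woody_plus_grass"])
  south_plain <- !water & lat <= 59 & !(inp$sparse_mask$values > 0 &
                                          inp$biome$values != "other")
  expect_equal(out$mean$values[south_plain],
               inp$woody$mean$values[south_plain])
  expect_true(all(is.na(out$mean$values[water])))
})

test_that("run_harmonization is continuous across the 59-61N band for smooth inputs", {
  # one column, rows every 0.01 degrees from 61.5 to 58.5; constant fields
  nr <- 301
  g <- grid_spec(nr, 1, 0.01, 0, 61.505)
  const_ul <- function(m, s) uncertain_layer(layer(matrix(m, nr, 1), g),
                                             layer(matrix(s, nr, 1), g))
  inputs <- allocation_inputs(
    woody = const_ul(30, 3), grass = const_ul(1.5, 0.2),
    crop = const_ul(5, 0.5), tundra = const_ul(8, 1),
    treecover = const_ul(40, 5),
    herbaceous_class = layer(matrix("crop", nr, 1), g),
    landcover = layer(matrix(10L, nr, 1), g),
    sparse_mask = layer(matrix(0, nr, 1), g),
    biome = layer(matrix("boreal", nr, 1), g))
  out <- run_harmonization(inputs)
  vals <- out$mean$values[, 1]
  steps <- abs(diff(vals))
  # north and south methodologies differ here (crop vs forced grass), yet
  # each 0.01-degree step moves the blend by at most w-step * |north-south|
  expect_true(all(is.finite(vals)))
  expect_gt(max(vals) - min(vals), 0)  # the two methodologies do differ
  expect_lt(max(steps), (max(vals) - min(vals)) * 0.01)
})

test_that("decision layers from AGBC govern the BGBC allocation identically", {
  st <- generate_stack(synth_config(n = 24, seed = 10))
  agbc <- run_harmonization(st$inputs)
  bgbc <- run_harmonization(st$inputs, pool = "bgbc",
                            bgb_layers = st$bgb_layers)
  expect_true(same_grid(agbc$mean$grid, bgbc$mean$grid))
  # nodata patterns coincide: the same branch/mask decisions applied
  expect_equal(is.na(agbc$mean$values), is.na(bgbc$mean$values))
  expect_error(run_harmonization(st$inputs, pool = "bgbc"), "bgb_layers")
})
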
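---
title: "Harmonizing landcover-specific biomass carbon maps: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Harmonizing landcover-specific biomass carbon maps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(carbharm)
```

## The problem

Remotely sensed biomass maps are landcover-specific: woody aboveground
biomass (AGB) products cover trees, grassland and tundra products cover
herbaceous and shrub vegetation, and cropland carbon is inferred from yield
statistics. No single product reports carbon in *all* living biomass, and
belowground biomass (BGB) — roots — cannot be observed from space at all.
`carbharm` implements an **overlay and allocate** harmonization: the
landcover-specific maps are overlaid on a common geographic grid and each
grid cell's total carbon is apportioned between its woody and herbaceous
components using percent tree cover, a thematic landcover map, and a
rule-based decision tree, separately for aboveground biomass carbon (AGBC)
and belowground biomass carbon (BGBC), with per-cell standard errors
propagated throughout.

## The model

### Allocation

For a cell with woody carbon estimate $\mu_w$, herbaceous estimate
$\mu_h$ and stretched fractional tree cover $q$, the total is

$$\mu_T = \mu_w + \mu_h\,(1 - q).$$

The woody term is kept in full regardless of landcover, because the woody
input maps already retain estimates wherever sub-pixel tree cover was
detected. Optical tree-cover products saturate near 80%, so percent cover
is stretched linearly with `stretch_treecover()`: 80% counts as complete
cover ($q = \min(q_{\%}/80, 1)$), and the reported standard deviation is
scaled by the same factor. Whether the SD should also be stretched is not
settled; we stretch it by default so that $q$ and $\sigma_q$ remain on one
scale, and document the choice here.

The herbaceous estimate itself mixes the grass and crop candidates by the
probability $p_i$ (the class's area-weighted user's accuracy) that the
most probable herbaceous class $i$ is correctly mapped:

$$\mu_h = \mu_i\,p_i + \mu_j\,(1 - p_i).$$

### Uncertainty

All errors are treated as independent and combined by summation in
quadrature ($\sigma_f = \sqrt{\sum_k (\partial f/\partial x_k\,
\sigma_k)^2}$). Two published forms are reproduced *literally* even where
a textbook derivation would differ, because the aim is fidelity to the
published maps rather than re-derivation:

* The total-allocation error is
  $\sigma_T = \sqrt{\sigma_w^2 + q^2\sigma_h^2 + \mu_h^2\sigma_q^2}$ — note
  the factor $q$, not the complement $(1-q)$ that multiplies $\mu_h$ in the
  mean. `allocate_total(form = "complement")` provides the textbook
  variant; `"printed"` is the default.
* The probability-weighted carbon-fraction error
  (`weighted_c_fraction_se()`) carries both a $2\sigma_m^2$ term and a
  $(p_m \sigma_m)^2$ term, i.e. it counts the leading class's error twice
  relative to linear propagation of the mean formula. It is implemented as
  printed, not "repaired".

Classification uncertainty enters as the Bernoulli standard deviation
$\delta = \sqrt{p(1-p)}$ of the user's accuracy. The class-mixing error
(`mix_two_classes()`) is evaluated in its expanded absolute form
$\sqrt{(p_i\sigma_i)^2 + (\mu_i\delta_i)^2 + ((1-p_i)\sigma_j)^2 +
(\mu_j(1-p_i)\delta_i/p_i)^2}$, which is algebraically identical to the
published relative form for nonzero means but avoids 0/0 when an estimate
is zero; at $p_i = 0$ the $\delta_i/p_i$ term is taken as 0 by continuity.

### Decision tree and the 60°N seam

In the tundra and boreal biomes the woody and tundra-vegetation maps
overlap thematically, so a separate rule set applies
(`tundra_override()`): sparse-landcover cells take the tundra estimate
alone; north of 60° latitude, cells with under 10% (unstretched) tree
cover or where tundra AGBC exceeds woody AGBC also take the tundra
estimate, and the rest take the woody value plus the grass contribution.
Ties go to the woody branch (the rule requires strict excess). Because the
northern and southern methodologies differ, values within 1° of 60°N are
blended linearly (`blend_60n()`): pure north at ≥ 61°N, pure south at
≤ 59°N, the arithmetic average at exactly 60°N. Water cells (landcover
code 210) are masked last.

Two consistency choices the published description leaves open, decided
here: (i) the override decision is computed once from the *AGBC* layers
and reapplied unchanged to the BGBC allocation, so a cell never takes
different branches in the two pools; (ii) "north of 60°" is evaluated at
the cell-center latitude. The "woody plus grass" branch runs the same
allocation machinery with grass forced as the most probable herbaceous
class (at the grass class's user's accuracy), rather than bypassing the
accuracy weighting, so its uncertainty stays comparable with the standard
branch.

## Component maps

**Woody.** A global AGB map (with SE layer) is merged with a regional
dryland map whose SE comes from a published cubic polynomial
(`bouvet_se()`, valid on 0–85 Mg ha⁻¹); the regional estimate wins inside
its footprint except on closed/flooded forest classes. AGB converts to
AGBC through carbon fractions stratified by climate domain (from a 32-row
Köppen–Geiger reclassification) and phylogeny, probability-weighted by the
phylogeny classification's user's accuracy. Woody BGBC comes from a
pluggable root regression over AGBC, mean annual temperature (MAT),
phylogeny and regenerative origin; savannah and shrubland instead use
static root-to-shoot ratios. Origin (planted vs natural) weights combine
intact-forest and planted-trees maps with national reported areas
(`origin_weights()`); residual differences are floored at zero so weights
stay in [0, 1] even when mapped areas exceed reported totals.

**Tundra and grassland.** NDVI composites (80th-percentile for the
tundra convention, maximum-value for grassland — the generator and tests
use `pct = 80` and `pct = 100` respectively) are calibrated across sensors
(`calibrate_ndvi()`), pushed through pluggable nonlinear regressions
(`apply_agbc_model()`), and averaged across composites with RMS error
combination (`combine_composites()`). Tundra AGB converts to carbon with
the fraction 0.492 (SE 0.008). Tundra BGBC uses a MAT-dependent
root-to-shoot model below 25 Mg ha⁻¹ AGB and the woody regression above it
(threshold *exclusive*: exactly 25 stays on the MAT path). Grassland BGBC
applies climate-stratified static ratios.

**Cropland.** Per-crop AGBC $= y\,\omega\,(0.451 h^{-1} + 1.025 c -
0.451)$ and BGBC $= 0.451\,y\,r\,h^{-1}$; the constants embed a 2.5%
field-to-farmgate loss and a 44% carbon content of residues and roots, so
no separate parameters exist for those. Cell totals are harvested-area
weighted; if total harvested area exceeds the cropland extent (harvest
frequency $f > 1$), both pools divide by $f$. The epoch correction uses
the per-cell Theil–Sen slope of an annual-productivity series, allocated
between pools by their carbon shares and floored at zero; its error is the
bootstrap SD of the slope. The bootstrap's omission rule is
under-specified in the source description, so it is parameterized: each
replicate drops each year independently with probability 0.2 (redrawing if
fewer than 3 years would survive), under an isolated, seeded RNG stream.

## Pluggable regressions

The root regression, the MAT-ratio model and the NDVI regressions are
published externally and their coefficients are not re-derived here; each
is a configuration object (`root_regression_model()`, `wang_model()`,
`agbc_regression()`) with a documented **synthetic** default of plausible
magnitude used by the test suite. `default_root_model()`, for instance, is
log-linear in AGBC with additive MAT, phylogeny and origin offsets —
useful for parameter-recovery tests, not fitted to any data. Real analyses
must supply the published coefficients. The grassland model's published
cap (2.3 MgC ha⁻¹ at NDVI = 1) is supported as a configuration sanity
check via the `cap` argument.

Likewise, the landcover class-aggregation scheme shipped under
`extdata/synthetic_landcover_scheme.csv` is a synthetic stand-in (the real
product's aggregation table is not printed in the source material); users
of real landcover data supply their own CSV with the same columns.

## Numerical choices

* **Area weights.** "Area weighted" aggregation uses cos(latitude of the
  fine cell center) — the standard equirectangular proxy; exact
  ellipsoidal cell geometry is out of scope. SE layers aggregate by the
  root of the weighted mean of squares, which equals mean-aggregating
  $\sigma^2$ then taking the square root.
* **Integer encoding.** Products store int16 at scale 0.1 with nodata
  −32768, rounding half away from zero; the quotient is pre-rounded to 9
  decimals so binary representation error cannot flip a decimal halfway
  case. A write/read cycle therefore changes no value by more than half a
  quantum (0.05 MgC ha⁻¹).
* **Grid registration.** Cell-center registration, row 1 northernmost,
  geographic WGS84. The product description's projection wording is
  ambiguous (it names a Mercator projection while matching a plate-carrée
  landcover grid); this package assumes the geographic lat/lon grid that
  the landcover product actually uses.
* **Percentiles.** Linear interpolation between closest order statistics
  (R's default quantile type 7).
* **Finite differences.** Coefficient-error propagation uses central
  differences with step `1e-6 × max(|coef|, 1)`.
* **Degenerate inputs.** Zero AGBC cells predict zero BGBC with zero SE;
  countries with zero residual origin areas but unknown-origin cells fall
  back to (0.5, 0.5) weights with a warning; empty composite lists,
  mismatched grids and out-of-range probabilities are hard errors.

## What the synthetic world does and does not establish

`generate_stack()` builds a deterministic 64 × 64, 0.25° world spanning
50–66°N so that the 59–61°N blend band, the tundra/boreal override rules
and both hemispheres of the decision tree are all exercised, with water,
sparse, cropland and forest classes present. Biomass magnitudes and noise
levels imitate the real products (woody carbon to ~60 MgC ha⁻¹ at ~20%
relative error, grassland ≤ 2.3 MgC ha⁻¹, crops to ~8 MgC ha⁻¹). The
end-to-end test compares `run_harmonization()` against an intentionally
naive per-cell scalar reference implementation kept in the test tree.

A green suite therefore establishes that the allocation algebra, decision
tree, blending, masking and encoding behave exactly as specified on inputs
of realistic shape. It does **not** establish fidelity to the real global
products: the published global totals (287 PgC AGBC, 122 PgC BGBC) require
the real input rasters and cannot be reproduced at desk scale, the
synthetic landcover scheme and regression defaults are stand-ins, and the
generator does not emulate sensor physics, cloud masking or the spatial
autocorrelation structure of real imagery.

## Known limitations

* Understory carbon beyond the $(1-q)$ complement is not represented; in
  densely forested cells the herbaceous contribution is likely
  underestimated by construction.
* All error propagation assumes independence; no covariance terms are
  carried, and Monte-Carlo propagation is used only as a test oracle.
* Reprojection between coordinate systems, tiled/compressed GeoTIFFs and
  litter/soil carbon pools are out of scope.

## A worked example

```{r example, eval = FALSE}
st <- generate_stack(synth_config(n = 64, seed = 2025))
agbc <- run_harmonization(st$inputs, verbose = TRUE)
bgbc <- run_harmonization(st$inputs, pool = "bgbc",
                          bgb_layers = st$bgb_layers)
summary(as.vector(agbc$mean$values))
write_scaled_int_geotiff(agbc$mean, "agbc.tif", scale_factor = 0.1)
```
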
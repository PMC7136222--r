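# carbharm

Harmonized above- and belowground biomass carbon density mapping in R.

## What this is for

Satellite-derived biomass maps are landcover-specific: woody aboveground
biomass (AGB) products cover trees, grassland/tundra products cover
herbaceous and shrub vegetation, and cropland carbon is inferred from crop
yields. Researchers doing carbon accounting, greenhouse-gas inventories or
biogeographical analysis need a *single* wall-to-wall map of aboveground
biomass carbon (AGBC) and its belowground counterpart (BGBC), with
quantified per-pixel uncertainty. `carbharm` implements the **overlay and
allocate** harmonization method for exactly that: overlay the
landcover-specific carbon maps on one geographic grid and apportion each
cell's total by fractional tree cover, thematic landcover class
probabilities and a rule-based decision tree.

## The method in brief

Per grid cell, the harmonized total is

```
mu_T = mu_w + mu_h * (1 - q)
mu_h = mu_i * p_i + mu_j * (1 - p_i)
```

where `mu_w` is the woody carbon estimate, `q` the fractional tree cover
(linearly stretched so that 80% counts as saturated full cover), `mu_i`
the estimate of the most probable herbaceous class (grass or crop) and
`p_i` that class's area-weighted user's accuracy. Standard errors combine
by summation in quadrature,

```
sigma_T = sqrt(sigma_w^2 + q^2 sigma_h^2 + mu_h^2 sigma_q^2)
```

with classification uncertainty entering as the Bernoulli standard
deviation `sqrt(p(1-p))`. Tundra/boreal cells follow override rules
(sparse cover, <10% tree cover north of 60°N, or tundra exceeding woody
carbon take the tundra estimate alone), the northern and southern
methodologies are blended across 59–61°N, and water is masked. Belowground
maps come from a pluggable root regression (AGBC, mean annual temperature,
phylogeny, planted/natural origin) or climate-stratified static
root-to-shoot ratios; cropland carbon comes from yields
(`AGBC = y·ω·(0.451/h + 1.025·c − 0.451)`, `BGBC = 0.451·y·r/h`) with a
Theil–Sen productivity-trend epoch correction and bootstrap uncertainty.
See the vignette in `vignettes/` for the full model, the design decisions
and their rationale.

## Worked example

```r
library(carbharm)

## published area-weighted confusion matrix for the likely-herbaceous classes
herb <- accuracy_metrics(confusion_fixture("herbaceous"))
round(herb$users, 4)
#>    crop noncrop
#>  0.7949  0.9642
round(herb$overall, 4)
#> [1] 0.9575

## deterministic synthetic world: 64 x 64 cells, 50-66N, seed fixed
st <- generate_stack(synth_config(n = 64, seed = 2025))
agbc <- run_harmonization(st$inputs, verbose = TRUE)
#> branches: standard 2501, tundra_only 837, woody_plus_grass 758; water-masked 155
summary(as.vector(agbc$mean$values))
#>    Min. 1st Qu.  Median    Mean 3rd Qu.    Max.    NA's
#>  0.7571  8.4283 15.8434 14.7799 21.5161 28.8050     155

## the matching belowground map uses the same per-cell branch decisions
bgbc <- run_harmonization(st$inputs, pool = "bgbc",
                          bgb_layers = st$bgb_layers)

## write the product exactly as the data records specify:
## int16, scale factor 0.1 (one decimal of MgC/ha), nodata -32768
write_scaled_int_geotiff(agbc$mean, "agbc.tif", scale_factor = 0.1)
```

The branch counts say how the decision tree classified the world: 2501
cells took the standard tree-cover allocation, 837 the tundra-only
override, 758 woody-plus-grass (north of 60°N with real tree cover), and
155 water cells were masked. Harmonized AGBC in this synthetic world spans
0.76–28.8 MgC ha⁻¹ — herbaceous carbon (≤ 2.3 MgC ha⁻¹ for grass) riding
on top of the woody field wherever tree cover is partial.

Single equations are exposed directly, e.g.:

```r
bouvet_se(50)                          # SE of the regional dryland AGB map
#> [1] 31.8425
c_fraction("Tropical", "angiosperm")   # carbon fraction (mean 0.454, SE 0.003)
theil_sen_slope(c(0, 1, 2), c(0, 1, 10))
#> [1] 5
```

## Command-line use

```sh
Rscript -e 'carbharm::harmonize_cli()' --config config.json --pool agbc --out agbc.tif
```

where `config.json` names the input rasters (see `?harmonize_cli`;
`generate_stack(cfg, dir = ...)` writes a complete example input
directory).

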
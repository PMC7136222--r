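Package: carbharm
Title: Harmonized Above- and Belowground Biomass Carbon Density Mapping
Version: 0.1.0
Authors@R:
    person("Carbon", "Mapping Project", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for merging landcover-specific above- and belowground
    biomass carbon density rasters into single harmonized maps with per-pixel
    propagated uncertainty. Implements an "overlay and allocate" schema:
    woody, grassland, cropland and tundra carbon layers are overlaid and each
    grid cell's total is apportioned by fractional tree cover and thematic
    landcover class probabilities, with standard errors combined by summation
    in quadrature. Includes scaled-integer GeoTIFF input/output, area-weighted
    aggregation, climate and phylogeny stratified carbon-fraction conversion,
    root-to-shoot belowground models, crop yield based carbon accounting with
    Theil-Sen trend correction, area-weighted confusion-matrix accuracy
    metrics, and a seeded synthetic-data generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
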
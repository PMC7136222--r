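# Built-in lookup tables: the Koppen-Geiger reclassification into grassland
# climate classes and carbon-fraction domains, the probability-weighted
# climate x phylogeny biomass carbon fractions, the root-to-shoot ratio
# table, and the two published area-weighted confusion matrices used as
# default classification-accuracy fixtures.

#' Koppen-Geiger reclassification table
#'
#' Maps each of the 32 Koppen-Geiger climate codes to (i) the grassland
#' climate class used to stratify root-to-shoot ratios and (ii) the carbon
#' domain used to stratify biomass carbon fractions.
#'
#' @return A data frame with columns `kg_code` (1-32), `kg_class`,
#'   `grassland_class` and `carbon_domain`.
#' @seealso [koppen_strata()] for single-code lookup.
#' @export
koppen_table <- function() {
  data.frame(
    kg_code = 1:32,
    kg_class = c("Af", "Am", "As", "Aw", "BSh", "BSk", "BWh", "BWk",
                 "Cfa", "Cfb", "Cfc", "Csa", "Csb", "Csc", "Cwa", "Cwb",
                 "Cwc", "Dfa", "Dfb", "Dfc", "Dfd", "Dsa", "Dsb", "Dsc",
                 "Dsd", "Dwa", "Dwb", "Dwc", "Dwd", "EF", "ET", "Ocean"),
    grassland_class = c(
      "Tropical/Subtropical", "Tropical/Subtropical", "Tropical/Subtropical",
      "Tropical/Subtropical", "Temperate", "Temperate", "Temperate",
      "Temperate", "Temperate", "Temperate", "Temperate", "Temperate",
      "Temperate", "Temperate", "Temperate", "Temperate", "Temperate",
      "Cool Temperate", "Cool Temperate", "Tundra", "Tundra",
      "Cool Temperate", "Cool Temperate", "Cool Temperate", "Cool Temperate",
      "Cool Temperate", "Cool Temperate", "Tundra", "Tundra", "Tundra",
      "Tundra", "Tropical/Subtropical"),
    carbon_domain = c(
      "Tropical", "Tropical", "Tropical", "Tropical",
      "Subtropical/Mediterranean", "Temperate", "Subtropical/Mediterranean",
      "Temperate", "Subtropical/Mediterranean", "Temperate", "Temperate",
      "Subtropical/Mediterranean", "Temperate", "Temperate",
      "Subtropical/Mediterranean", "Subtropical/Mediterranean", "Temperate",
      "Temperate", "Temperate", "Boreal", "Boreal", "Temperate", "Temperate",
      "Boreal", "Boreal", "Temperate", "Temperate", "Boreal", "Boreal",
      "Boreal", "Boreal", "Global"),
    stringsAsFactors = FALSE)
}

#' Climate- and phylogeny-specific biomass carbon fractions
#'
#' Default probability-weighted carbon fractions (dimensionless, with
#' standard errors) for converting dry biomass density to carbon density,
#' stratified by carbon domain and forest phylogeny. These defaults already
#' incorporate the weighting of [weighted_c_fraction()] by the phylogeny
#' classification's user's accuracy; users with their own source fractions
#' and confusion matrix can regenerate a table via that function.
#'
#' @return A data frame with columns `carbon_domain`, `phylogeny`
#'   (`"angiosperm"`, `"mixed"`, `"gymnosperm"`), `mean` and `se`.
#' @seealso [c_fraction()]
#' @export
carbon_fraction_table <- function() {
  data.frame(
    carbon_domain = rep(c("Tropical", "Subtropical/Mediterranean",
                          "Temperate", "Boreal", "Global"), each = 3),
    phylogeny = rep(c("angiosperm", "mixed", "gymnosperm"), 5),
    mean = c(0.454, 0.452, 0.450,
             0.465, 0.478, 0.484,
             0.472, 0.483, 0.489,
             0.488, 0.480, 0.476,
             0.471, 0.476, 0.479),
    se = c(0.003, 0.004, 0.008,
           0.006, 0.008, 0.009,
           0.005, 0.006, 0.006,
           0.013, 0.011, 0.009,
           0.011, 0.016, 0.012),
    stringsAsFactors = FALSE)
}

#' Root-to-shoot ratio table
#'
#' Static root-to-shoot ratios (belowground / aboveground biomass, with
#' standard errors) for savannah, shrubland and the four grassland climate
#' classes. Grassland strata correspond to the `grassland_class` column of
#' [koppen_table()].
#'
#' @return A data frame with columns `stratum`, `mean` and `se`.
#' @export
root_shoot_table <- function() {
  data.frame(
    stratum = c("Savannah", "Shrub", "Grassland-Tropical/Subtropical",
                "Grassland-Temperate", "Grassland-Cool Temperate",
                "Grassland-Tundra"),
    mean = c(0.642, 1.837, 1.887, 4.224, 4.504, 4.804),
    se = c(0.111, 0.589, 0.304, 0.518, 1.337, 1.188),
    stringsAsFactors = FALSE)
}

#' Area-weighted confusion matrix
#'
#' Couples an ordered label set with a square matrix of area proportions
#' (map class in rows, reference class in columns) summing to 1.
#'
#' @param proportions Square numeric matrix of area proportions (>= 0,
#'   total within 1e-6 of 1).
#' @param labels Character vector of class names, one per row/column.
#' @return An object of class `confusion_matrix`.
#' @seealso [accuracy_metrics()], [confusion_fixture()]
#' @export
confusion_matrix <- function(proportions, labels = rownames(proportions)) {
  proportions <- as.matrix(proportions)
  if (nrow(proportions) != ncol(proportions))
    stop("confusion matrix must be square")
  if (is.null(labels) || length(labels) != nrow(proportions))
    stop("labels must name every class")
  if (any(proportions < 0))
    stop("confusion matrix entries must be >= 0")
  if (abs(sum(proportions) - 1) > 1e-6)
    stop("confusion matrix proportions must sum to 1")
  dimnames(proportions) <- list(labels, labels)
  structure(list(labels = labels, proportions = proportions),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat("<confusion_matrix>\n")
  print(x$proportions)
  invisible(x)
}

#' Published area-weighted confusion matrices
#'
#' Returns one of the two default confusion-matrix fixtures: the
#' "likely forest phylogeny" matrix (gymnosperm / mixed / angiosperm) or the
#' "likely herbaceous" matrix (crop / non-crop), both as area proportions.
#'
#' @param which `"phylogeny"` or `"herbaceous"`.
#' @return A [confusion_matrix()].
#' @export
confusion_fixture <- function(which = c("phylogeny", "herbaceous")) {
  which <- match.arg(which)
  if (which == "phylogeny") {
    m <- matrix(c(0.0180, 0.0124, 0.0024,
                  0.0020, 0.9241, 0.0086,
                  0.0006, 0.0076, 0.0243),
                nrow = 3, byrow = TRUE)
    confusion_matrix(m, labels = c("gymnosperm", "mixed", "angiosperm"))
  } else {
    m <- matrix(c(0.0314, 0.0081,
                  0.0344, 0.9261),
                nrow = 2, byrow = TRUE)
    confusion_matrix(m, labels = c("crop", "noncrop"))
  }
}
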
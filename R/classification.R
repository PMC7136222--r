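# Thematic machinery: confusion-matrix accuracy metrics, climate
# stratification lookups, carbon-fraction lookup and class-code aggregation.

#' Accuracy metrics of an area-weighted confusion matrix
#'
#' Computes per-class user's accuracy (diagonal over row sum: the probability
#' that a mapped cell of a class is truly that class), per-class producer's
#' accuracy (diagonal over column sum), and overall accuracy (trace over
#' total), all as proportions. Classes with a zero row or column sum get `NA`
#' for the undefined accuracy rather than 0.
#'
#' @param cm A [confusion_matrix()].
#' @return A list with elements `users` (named vector), `producers` (named
#'   vector) and `overall` (scalar).
#' @examples
#' accuracy_metrics(confusion_fixture("herbaceous"))
#' @export
accuracy_metrics <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  p <- cm$proportions
  rs <- rowSums(p)
  cs <- colSums(p)
  d <- diag(p)
  users <- ifelse(rs > 0, d / rs, NA_real_)
  producers <- ifelse(cs > 0, d / cs, NA_real_)
  names(users) <- names(producers) <- cm$labels
  list(users = users, producers = producers,
       overall = sum(d) / sum(p))
}

#' Climate strata for a Koppen-Geiger code
#'
#' Looks up the grassland climate class and carbon domain for one or more
#' Koppen-Geiger codes (1-32).
#'
#' @param kg_code Integer vector of codes in 1-32.
#' @return A data frame with columns `grassland_class` and `carbon_domain`
#'   (one row per input code).
#' @examples
#' koppen_strata(c(1, 20, 31))
#' @export
koppen_strata <- function(kg_code) {
  tab <- koppen_table()
  idx <- match(kg_code, tab$kg_code)
  if (any(is.na(idx) & !is.na(kg_code)))
    stop("unknown Koppen-Geiger code(s): ",
         paste(unique(kg_code[is.na(idx) & !is.na(kg_code)]), collapse = ", "))
  tab[idx, c("grassland_class", "carbon_domain"), drop = FALSE]
}

#' Carbon fraction lookup
#'
#' Retrieves the probability-weighted biomass carbon fraction (mean and SE)
#' for a carbon domain and phylogeny from [carbon_fraction_table()] (or a
#' user-supplied table of the same shape).
#'
#' @param domain Carbon domain label(s).
#' @param phylogeny Phylogeny label(s): `"angiosperm"`, `"mixed"` or
#'   `"gymnosperm"`.
#' @param table Fraction table (defaults to the built-in one).
#' @return A [uval()] (vectorized over inputs).
#' @examples
#' c_fraction("Tropical", "angiosperm")
#' @export
c_fraction <- function(domain, phylogeny, table = carbon_fraction_table()) {
  key <- paste(domain, phylogeny, sep = "|")
  tab_key <- paste(table$carbon_domain, table$phylogeny, sep = "|")
  idx <- match(key, tab_key)
  if (any(is.na(idx)))
    stop("no carbon fraction for: ",
         paste(unique(key[is.na(idx)]), collapse = ", "))
  uval(table$mean[idx], table$se[idx])
}

#' Landcover class-aggregation scheme
#'
#' A scheme maps every landcover code to one aggregated label per target
#' classification (forest phylogeny, likely-herbaceous class, sparse /
#' closed-forest / water flags, woody root-to-shoot stratum). The default
#' scheme shipped with the package is a documented *synthetic* stand-in
#' emulating an aggregation of CCI-style landcover codes; analyses of real
#' landcover products must supply their own table.
#'
#' @param path CSV file with columns `code`, `phylogeny`, `herbaceous`,
#'   `sparse`, `closed_flooded`, `water`, `ratio_stratum`. `NULL` loads the
#'   synthetic default shipped under `extdata/`.
#' @return A data frame of class `class_scheme`.
#' @export
read_class_scheme <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "synthetic_landcover_scheme.csv",
                        package = "carbharm", mustWork = TRUE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("code", "phylogeny", "herbaceous", "sparse", "closed_flooded",
            "water", "ratio_stratum")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop("scheme missing columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(tab$code)) stop("duplicate landcover codes in scheme")
  if (!210 %in% tab$code) stop("scheme must include water code 210")
  class(tab) <- c("class_scheme", "data.frame")
  tab
}

#' Extract one aggregation mapping from a scheme
#'
#' @param scheme A scheme from [read_class_scheme()].
#' @param target Which aggregated classification to extract: one of
#'   `"phylogeny"`, `"herbaceous"`, `"sparse"`, `"closed_flooded"`,
#'   `"water"`, `"ratio_stratum"`.
#' @return Named character vector: landcover code (as name) to label.
#' @export
scheme_mapping <- function(scheme, target = c("phylogeny", "herbaceous",
                                              "sparse", "closed_flooded",
                                              "water", "ratio_stratum")) {
  target <- match.arg(target)
  stats::setNames(as.character(scheme[[target]]), scheme$code)
}

#' Relabel a coded landcover layer
#'
#' Applies a code-to-label mapping cell-wise. Codes not covered by the
#' mapping are flagged with the label `"unknown"` (and counted in a message)
#' rather than erroring.
#'
#' @param landcover A [layer()] of integer class codes.
#' @param mapping Named character vector from [scheme_mapping()].
#' @return A thematic [layer()] of character labels.
#' @export
aggregate_classes <- function(landcover, mapping) {
  stopifnot(is_layer(landcover))
  codes <- as.character(landcover$values)
  labels <- unname(mapping[codes])
  unknown <- is.na(labels) & !is.na(codes)
  if (any(unknown)) {
    message(sum(unknown), " cell(s) with unmapped landcover codes -> 'unknown'")
    labels[unknown] <- "unknown"
  }
  layer(matrix(labels, landcover$grid$n_rows, landcover$grid$n_cols),
        landcover$grid)
}
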
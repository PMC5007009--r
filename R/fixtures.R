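#' Reconstructed metadata for the 29 Native American populations
#'
#' A versioned reconstruction of the population / region / language-family /
#' coordinate table for the 29 Native American populations of the published
#' 63-population microsatellite compilation. The nine-region labels and the
#' Ethnologue/Campbell-based family assignments were reconstructed from the
#' published descriptions; coordinates are approximate published locations.
#' Spelling is ASCII-normalised (e.g. "Surui", "Cabecar"); use the
#' `aliases` argument of \code{\link{read_population_metadata}} to map
#' diacritic variants onto these names.
#'
#' @return data.frame with columns `population`, `region`,
#'   `language_family`, `latitude`, `longitude` (29 rows, 9 regions).
#' @export
american_populations <- function() {
  read_population_metadata(
    system.file("extdata", "american_populations_reconstructed.csv",
                package = "admixcline", mustWork = TRUE))
}

#' Default alias table for population-name spelling variants
#'
#' Maps common diacritic or variant spellings onto the canonical names used
#' by \code{\link{american_populations}}.
#'
#' @return named character vector variant -> canonical.
#' @export
population_aliases <- function() {
  c("Suruí" = "Surui",
    "Cabécar" = "Cabecar",
    "Emberá" = "Embera",
    "Zenú" = "Zenu",
    "Wounaan" = "Waunana",
    "Aché" = "Ache",
    "Guaraní" = "Guarani")
}

#' Default waypoint route library
#'
#' Loads the packaged route library encoding coastal / riverine dispersal
#' paths from the Beringia-analog origin (see
#' \code{\link{read_route_library}} for the format).
#'
#' @return list with `origin` and `routes`.
#' @export
default_routes <- function() {
  read_route_library(
    system.file("extdata", "routes_default.yaml",
                package = "admixcline", mustWork = TRUE))
}

#' Language-family census of a metadata table
#'
#' Counts the well-attested language families in a population metadata
#' table: populations per family, the mean number of populations per family,
#' and how many families have more than two representatives. Populations
#' with `language_family` `"NA"` (outside the language analysis) are
#' excluded.
#'
#' @param meta data.frame with `population` and `language_family`; defaults
#'   to the packaged reconstruction.
#' @return list: `n_families`, `mean_populations_per_family`,
#'   `n_families_over_two`, `counts` (named integer vector per family).
#' @export
language_family_counts <- function(meta = american_populations()) {
  fam <- meta$language_family
  fam <- fam[!is.na(fam) & fam != "NA"]
  counts <- table(fam)
  list(n_families = length(counts),
       mean_populations_per_family = as.numeric(mean(counts)),
       n_families_over_two = sum(counts > 2),
       counts = stats::setNames(as.integer(counts), names(counts)))
}
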
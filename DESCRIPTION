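Package: admixcline
Title: Admixture-Aware Analysis of Geographic Gene-Diversity Clines
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for asking whether a geographic decline in microsatellite
    gene diversity reflects a serial founder effect or geographically
    patterned post-contact admixture. Provides STRUCTURE-format genotype
    input, maximum-likelihood admixture proportion estimation across a range
    of cluster numbers K with multi-run label alignment and the Evanno
    delta-K statistic, per-population gene diversity and genetic distances
    (Nei minimum, delta-mu-squared), waypoint-constrained great-circle
    distances from an origin, correlation and partial-correlation analysis
    of diversity versus distance with drop-one jackknife attribution,
    principal component and classical multidimensional scaling ordination,
    gene-language correspondence summaries, and a forward Wright-Fisher
    microsatellite simulator (serial founder chain, stepwise mutation,
    admixture pulses) with full truth records for method validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    geosphere,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
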
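# Scenario presets. Each preset fixes the generative conditions used by the
# package's validation studies; parameter choices are documented in the
# methods vignette and are deliberately not tuned per analysis.

#' Three well-separated populations (true K = 3)
#'
#' Three demes founded without bottlenecks and left to drift apart for long
#' inter-founding intervals, with no admixture and no outgroups: the
#' configuration under which the Evanno delta-K statistic should recover
#' K = 3.
#'
#' @param seed integer seed.
#' @param n_loci,sample_size scenario size knobs.
#' @return a \code{\link{sim_config}}.
#' @export
scenario_true_k3 <- function(seed, n_loci = 80L, sample_size = 15L) {
  sim_config(n_loci = n_loci, n_demes = 3, deme_size = 100,
             founder_size = 100, generations_between = 250,
             mu = 1e-3, outgroups = list(), admixture = NULL,
             admixture_generations_ago = 0L,
             sample_size = sample_size, seed = seed)
}

#' Admixture-fraction grid for EM recovery
#'
#' Six demes with manual per-deme European-analog admixture fractions
#' 0, 0.1, ..., 0.5; 200 loci and 50 individuals per deme. The chain is
#' founded without bottlenecks and with short inter-founding intervals so
#' that the demes share a single native genetic background: the scenario
#' isolates admixture-proportion estimation from the drift structure the
#' K = 2 admixture model does not represent.
#'
#' @param seed integer seed.
#' @return a \code{\link{sim_config}}.
#' @export
scenario_alpha_grid <- function(seed) {
  sim_config(n_loci = 200, n_demes = 6, deme_size = 100,
             founder_size = 100, founder_duration = 1,
             generations_between = 8,
             mu = 1e-3,
             outgroups = list(EUR = 800),
             admixture = list(EUR = list(profile = "manual",
                                         alpha = seq(0, 0.5, by = 0.1))),
             admixture_generations_ago = 5L,
             sample_size = 50, outgroup_sample_size = 50,
             seed = seed)
}

#' Admixture-only cline (no founder effect)
#'
#' Ten demes founded without bottlenecks, with European-analog admixture
#' decaying exponentially with distance from the origin. Gene diversity then
#' declines with distance purely because admixture does, reproducing the
#' situation in which a raw diversity-distance correlation is spurious and
#' the admixture-controlled partial correlation should vanish.
#'
#' @param seed integer seed.
#' @return a \code{\link{sim_config}}.
#' @export
scenario_admixture_only <- function(seed) {
  sim_config(n_loci = 120, n_demes = 10, deme_size = 100,
             founder_size = 100, generations_between = 30,
             mu = 1e-3,
             outgroups = list(EUR = 800),
             admixture = list(EUR = list(profile = "exponential",
                                         alpha0 = 0.35, lambda = 3e-4)),
             admixture_generations_ago = 12L,
             sample_size = 20, outgroup_sample_size = 20,
             seed = seed)
}

#' Founder-effect-only cline
#'
#' Ten demes founded through strong serial bottlenecks (12 founders into
#' demes of 100) with a small constant admixture fraction that carries no
#' geographic information: here the raw and admixture-controlled
#' correlations of diversity with distance should agree.
#'
#' @param seed integer seed.
#' @return a \code{\link{sim_config}}.
#' @export
scenario_founder_only <- function(seed) {
  sim_config(n_loci = 120, n_demes = 10, deme_size = 100,
             founder_size = 12, generations_between = 30,
             mu = 1e-3,
             outgroups = list(EUR = 800),
             admixture = list(EUR = list(profile = "constant", alpha = 0.05)),
             admixture_generations_ago = 12L,
             sample_size = 20, outgroup_sample_size = 20,
             seed = seed)
}

#' Planted low-diversity distant region
#'
#' Nine demes in three contiguous regions of three. The chain is founded
#' without bottlenecks except at deme 7, which passes through a severe
#' bottleneck (4 founders for the founding phase) whose diversity loss is
#' inherited by demes 8-9: the far region is planted as the sole driver of
#' the diversity-distance correlation, mirroring the role of an isolated
#' low-diversity region in a regional jackknife.
#'
#' @param seed integer seed.
#' @return list: `config` (a \code{\link{sim_config}}) and `regions`
#'   (named character vector deme -> region).
#' @export
scenario_planted_region <- function(seed) {
  cfg <- sim_config(n_loci = 200, n_demes = 9, deme_size = 100,
                    founder_size = c(rep(100L, 6), 4L, 100L, 100L),
                    generations_between = 20,
                    mu = 1e-3,
                    outgroups = list(EUR = 800),
                    admixture = list(EUR = list(profile = "constant",
                                                alpha = 0.03)),
                    admixture_generations_ago = 12L,
                    sample_size = 20, outgroup_sample_size = 20,
                    seed = seed)
  regions <- stats::setNames(rep(c("near", "mid", "far"), each = 3),
                             sprintf("deme%02d", 1:9))
  list(config = cfg, regions = regions)
}

#' Gradient-analysis inputs from a simulation
#'
#' Convenience extractor: per-deme gene diversity, the geotable implied by
#' the configured chain distances, the true non-native ancestry covariate
#' from the truth record, and the deme regions.
#'
#' @param sim an `admix_sim` from \code{\link{simulate_genotypes}}.
#' @return list: `diversity`, `geotable`, `covariate` (named vector),
#'   `regions` (named vector), `demes` (deme population names).
#' @export
sim_gradient_inputs <- function(sim) {
  demes <- sim$meta$population[!is.na(sim$meta$founding_order)]
  grouping <- populations(sim$genotypes)
  keep <- names(grouping)[grouping %in% demes]
  sub <- grouping[keep]
  freqs <- allele_frequencies(sim$genotypes)
  div <- gene_diversity(freqs)
  div <- div[div$population %in% demes, ]
  geo <- data.frame(population = demes,
                    distance_km = sim$meta$distance_km[
                      match(demes, sim$meta$population)])
  cov <- 1 - sim$truth$alpha_realized[demes, "native"]
  regions <- stats::setNames(
    sim$meta$region[match(demes, sim$meta$population)], demes)
  list(diversity = div, geotable = geo,
       covariate = stats::setNames(as.numeric(cov), demes),
       regions = regions, demes = demes)
}
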
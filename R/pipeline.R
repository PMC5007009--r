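#' Run the full analysis pipeline
#'
#' Orchestrates simulate (or load) -> ancestry -> diversity -> geo ->
#' gradient -> ordination with a single master seed, writing every stage's
#' tables as CSV plus a YAML run manifest with the derived seeds and file
#' checksums. Re-running with the same configuration reproduces all outputs
#' bit-identically.
#'
#' @param sim a \code{\link{sim_config}} to simulate from, or NULL to read
#'   `genotype_path` / `meta` instead.
#' @param genotype_path STRUCTURE-format genotype file (used when `sim` is
#'   NULL).
#' @param meta population metadata data.frame (required with
#'   `genotype_path`; for simulations the simulated metadata is used).
#' @param out_dir output directory (created if needed).
#' @param K_values contiguous K range for the ancestry series.
#' @param n_runs replicate EM runs per K.
#' @param n_starts EM multi-starts per run.
#' @param source_groups named list annotation -> population names treated as
#'   continental sources; for simulations defaults to the outgroup
#'   populations, each its own group.
#' @param routes optional named route list for \code{\link{build_geotable}};
#'   simulations use their configured chain distances.
#' @param origin origin coordinate for route distances.
#' @param seed master seed; every stochastic stage derives its seed from it.
#' @return (invisibly) list with the main stage results: `sim` or
#'   `genotypes`, `series`, `delta_k`, `diversity`, `geotable`, `gradient`,
#'   `pca`, `mds`, `language`, `out_dir`.
#' @export
run_pipeline <- function(sim = NULL, genotype_path = NULL, meta = NULL,
                         out_dir, K_values = 2:4, n_runs = 3L,
                         n_starts = 2L, source_groups = NULL,
                         routes = NULL, origin = c(66, -167), seed) {
  if (missing(seed)) stop("a master seed is mandatory")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  outfiles <- character(0)
  emit <- function(df, name) {
    p <- file.path(out_dir, name)
    utils::write.csv(df, p, row.names = FALSE)
    outfiles <<- c(outfiles, p)
  }

  # stage 1: data
  if (!is.null(sim)) {
    sim$seed <- seed + 1L
    simr <- simulate_genotypes(sim)
    g <- simr$genotypes; meta <- simr$meta
    native <- meta$population[!is.na(meta$founding_order)]
    if (is.null(source_groups)) {
      outs <- meta$population[is.na(meta$founding_order)]
      source_groups <- stats::setNames(as.list(outs), outs)
    }
  } else {
    if (is.null(genotype_path) || is.null(meta))
      stop("either `sim` or both `genotype_path` and `meta` are required")
    simr <- NULL
    g <- read_structure(genotype_path)
    native <- meta$population[!is.na(meta$latitude)]
    if (is.null(source_groups)) source_groups <- list()
  }
  grouping <- populations(g)

  # stage 2: ancestry across K
  series <- run_admixture_series(g, K_values, n_runs = n_runs,
                                 seed = seed + 100L, n_starts = n_starts)
  dk <- delta_k(series)
  emit(dk, "delta_k.csv")
  ll <- as.data.frame(series$loglik)
  ll$run <- seq_len(nrow(ll))
  emit(ll, "loglik.csv")
  K_best <- if (all(is.na(dk$delta_K))) max(K_values)
            else dk$K[which.max(dk$delta_K)]
  ki <- match(K_best, K_values)
  aligned <- align_runs(series$runs[[ki]])
  Qbar <- Reduce(`+`, lapply(aligned, `[[`, "Q")) / length(aligned)
  fit <- aligned[[1]]; fit$Q <- Qbar
  emit(data.frame(individual = rownames(Qbar),
                  population = grouping[rownames(Qbar)], Qbar),
       "q_matrix.csv")
  ann <- annotate_clusters(fit, grouping, source_groups)
  pop_q <- ancestry_by_population(fit, grouping)
  covariate <- non_native_ancestry(pop_q, ann)
  sens <- k_sensitivity(series, grouping, source_groups)
  emit(sens, "k_sensitivity.csv")

  # stage 3: diversity and distances
  freqs <- allele_frequencies(g)
  div <- gene_diversity(freqs)
  emit(div, "diversity.csv")
  nei <- nei_minimum_distance(freqs)
  dmu <- delta_mu_squared(freqs)
  emit(data.frame(population = rownames(nei$D), nei$D), "nei_distance.csv")
  emit(data.frame(population = rownames(dmu$D), dmu$D), "delta_mu_distance.csv")

  # stage 4: geography
  if (!is.null(simr)) {
    geo <- data.frame(population = native,
                      distance_km = meta$distance_km[
                        match(native, meta$population)],
                      route = "chain", n_waypoints = 0L)
  } else {
    geo <- build_geotable(meta[meta$population %in% native, ],
                          origin = origin, routes = routes)
  }
  emit(geo, "geotable.csv")

  # stage 5: gradient with jackknives
  regions <- stats::setNames(meta$region[match(native, meta$population)],
                             native)
  grad <- gradient_analysis(div[div$population %in% native, ], geo,
                            covariate = covariate[native], regions = regions)
  emit(data.frame(stat = c("r", "p", "r_partial", "p_partial", "n"),
                  value = c(grad$r, grad$p, grad$r_partial, grad$p_partial,
                            grad$n)),
       "gradient.csv")
  emit(grad$jackknife_population, "jackknife_population.csv")
  emit(grad$jackknife_region, "jackknife_region.csv")

  # stage 6: ordination and language
  pca <- pca_genotypes(g, n_axes = 6)
  emit(data.frame(individual = rownames(pca$scores),
                  population = grouping[rownames(pca$scores)], pca$scores),
       "pca_scores.csv")
  mds <- classical_mds(nei, n_axes = 2)
  emit(data.frame(population = rownames(mds$scores), mds$scores),
       "mds_scores.csv")
  lang <- NULL
  fams <- stats::setNames(meta$language_family, meta$population)
  fams <- fams[names(fams) %in% rownames(nei$D)]
  if (sum(!is.na(fams) & fams != "NA") >= 4) {
    lang <- gene_language_summary(nei, fams, n_perm = 999L,
                                  seed = seed + 300L)
    emit(lang$families, "language_families.csv")
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("admixcline")),
    master_seed = seed,
    derived_seeds = list(simulate = seed + 1L, ancestry = seed + 100L,
                         language = seed + 300L),
    K_values = K_values, K_selected = K_best,
    cluster_annotation = ann,
    outputs = as.list(stats::setNames(
      unname(tools::md5sum(outfiles)), basename(outfiles))))
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))

  invisible(list(sim = simr, genotypes = g, meta = meta, series = series,
                 delta_k = dk, K_selected = K_best, ancestry = fit,
                 annotation = ann, covariate = covariate,
                 diversity = div, geotable = geo, gradient = grad,
                 pca = pca, mds = mds, language = lang, out_dir = out_dir))
}
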
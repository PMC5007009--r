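#' Build a simulation scenario configuration
#'
#' Describes a forward Wright-Fisher microsatellite scenario: a burnt-in root
#' population spawns continental outgroup analogs (African / European / East
#' Asian by default) at their divergence times and a serial chain of demes
#' founded one from the next, each founding passing through a bottleneck of
#' `founder_size` diploids. Loci mutate under the symmetric single-step
#' (stepwise mutation) model. A single admixture pulse
#' `admixture_generations_ago` generations before the present replaces a
#' per-deme, per-source fraction of gene copies with draws from the source
#' gene pools; ancestry labels are tracked from the pulse onward. Language
#' family labels are assigned to contiguous blocks of demes and then
#' decoupled at random with probability `language_decouple_prob`, mimicking
#' the independent movement of genes and languages.
#'
#' Deme coordinates run south along a meridian from the origin with constant
#' `deme_spacing_km`, so the configured spacing is also the great-circle
#' distance between neighbours.
#'
#' @param n_loci number of unlinked microsatellite loci.
#' @param n_demes number of demes in the serial chain.
#' @param deme_spacing_km great-circle distance between successive demes.
#' @param deme_size diploid size `N` of every deme (and of the root).
#' @param founder_size diploid founder count `N_f` per founding; scalar or a
#'   vector of length `n_demes` (the first entry is the founding of deme 1
#'   from the root). Must not exceed `deme_size`.
#' @param founder_duration generations a newly founded deme stays at
#'   `founder_size` before expanding to `deme_size` (the founding draw is
#'   the first of them). Sustained small size is what makes serial
#'   bottlenecks bite: a single-generation bottleneck removes only
#'   `1/(2 N_f)` of the heterozygosity.
#' @param generations_between generations separating successive foundings;
#'   the last deme also lives this long before the present.
#' @param mu mutation rate per gene copy per generation, in `[0, 0.5)`.
#' @param outgroups named list `source -> divergence generations before the
#'   present` for the continental analogs.
#' @param admixture named list `source -> profile`; each profile is a list
#'   with `profile = "constant"` (field `alpha`), `"linear"` (`alpha0`,
#'   `slope` per km, floored at 0), `"exponential"` (`alpha0`, `lambda` per
#'   km: `alpha0 * exp(-lambda * dist)`), or `"manual"` (`alpha`, length
#'   `n_demes`). Use `admixture = NULL` for no admixture.
#' @param admixture_generations_ago when the single pulse occurs.
#' @param sample_size diploid individuals sampled per deme.
#' @param outgroup_sample_size diploid individuals sampled per outgroup.
#' @param language_block_size contiguous demes sharing a language family.
#' @param language_decouple_prob probability a deme's family label is
#'   reassigned uniformly at random.
#' @param origin `c(latitude, longitude)` of the chain origin (a Beringia
#'   analog by default).
#' @param seed mandatory integer seed.
#' @return a `sim_config` list, validated.
#' @export
sim_config <- function(n_loci = 150,
                       n_demes = 8,
                       deme_spacing_km = 1500,
                       deme_size = 100,
                       founder_size = 15,
                       founder_duration = 5,
                       generations_between = 30,
                       mu = 1e-3,
                       outgroups = list(AFR = 1500, EUR = 800, EAS = 600),
                       admixture = list(
                         EUR = list(profile = "exponential",
                                    alpha0 = 0.30, lambda = 2.5e-4),
                         AFR = list(profile = "constant", alpha = 0.01),
                         EAS = list(profile = "constant", alpha = 0.015)),
                       admixture_generations_ago = 15,
                       sample_size = 20,
                       outgroup_sample_size = 20,
                       language_block_size = 2,
                       language_decouple_prob = 0.25,
                       origin = c(66, -167),
                       seed) {
  if (missing(seed) || is.null(seed))
    stop("seed is mandatory: simulations must be reproducible")
  if (mu < 0 || mu >= 0.5) stop("mu must lie in [0, 0.5)")
  founder_size <- as.integer(rep_len(founder_size, n_demes))
  if (any(founder_size > deme_size)) stop("founder_size must not exceed deme_size")
  if (any(founder_size < 1)) stop("founder_size must be positive")
  if (founder_duration < 1 || founder_duration > generations_between)
    stop("founder_duration must lie in [1, generations_between]")
  cfg <- list(n_loci = as.integer(n_loci), n_demes = as.integer(n_demes),
              deme_spacing_km = deme_spacing_km,
              deme_size = as.integer(deme_size), founder_size = founder_size,
              founder_duration = as.integer(founder_duration),
              generations_between = as.integer(generations_between),
              mu = mu, outgroups = outgroups, admixture = admixture,
              admixture_generations_ago = as.integer(admixture_generations_ago),
              sample_size = as.integer(sample_size),
              outgroup_sample_size = as.integer(outgroup_sample_size),
              language_block_size = as.integer(language_block_size),
              language_decouple_prob = language_decouple_prob,
              origin = origin, seed = as.integer(seed))
  # distances from the origin along the chain, deme 1 sits at the origin
  cfg$deme_distance_km <- (seq_len(cfg$n_demes) - 1L) * deme_spacing_km
  bad <- setdiff(names(admixture), names(outgroups))
  if (length(bad))
    stop("admixture sources without an outgroup: ", paste(bad, collapse = ", "))
  alpha <- admixture_fractions(cfg)
  if (any(alpha < 0)) stop("admixture fractions must be non-negative")
  if (any(rowSums(alpha) > 1))
    stop("admixture fractions sum to > 1 for at least one deme")
  class(cfg) <- "sim_config"
  cfg
}

#' Per-deme admixture fractions implied by a configuration
#'
#' @param config a `sim_config`.
#' @return matrix `n_demes x n_sources` of fractions (0 columns if no
#'   admixture is configured).
#' @export
admixture_fractions <- function(config) {
  d <- config$deme_distance_km
  sources <- names(config$admixture)
  alpha <- matrix(0, config$n_demes, length(sources),
                  dimnames = list(NULL, sources))
  for (s in sources) {
    pr <- config$admixture[[s]]
    alpha[, s] <- switch(pr$profile,
      constant    = rep(pr$alpha, config$n_demes),
      linear      = pmax(0, pr$alpha0 + pr$slope * d),
      exponential = pr$alpha0 * exp(-pr$lambda * d),
      manual      = {
        if (length(pr$alpha) != config$n_demes)
          stop("manual profile needs one alpha per deme")
        pr$alpha
      },
      stop("unknown admixture profile: ", pr$profile))
  }
  alpha
}

#' Expected heterozygosity after a founder bottleneck
#'
#' Closed-form drift expectation used as an oracle for the simulator at
#' `mu = 0`: the founding draw of `2 * N_f` gene copies is the first of `t`
#' generations, the remaining `t - 1` run at size `N`, so
#' `H_t = H0 * (1 - 1/(2 N_f)) * (1 - 1/(2 N))^(t - 1)` for `t >= 1` and
#' `H_0 = H0`. Heterozygosity here is the identity form `1 - sum(p^2)`.
#'
#' @param H0 initial heterozygosity in `[0, 1]`.
#' @param N_f diploid founder count.
#' @param t generations since (and including) the founding draw.
#' @param N diploid size after founding.
#' @return expected heterozygosity.
#' @export
expected_heterozygosity_after_bottleneck <- function(H0, N_f, t, N) {
  if (H0 < 0 || H0 > 1) stop("H0 must lie in [0, 1]")
  if (N_f <= 0 || N <= 0) stop("population sizes must be positive")
  if (t < 0) stop("t must be non-negative")
  if (t == 0) return(H0)
  H0 * (1 - 1 / (2 * N_f)) * (1 - 1 / (2 * N))^(t - 1)
}

# evolve a pool (copies x loci) for `generations`, optionally with labels
wf_step <- function(pool, n_out, generations, mu, labels = NULL) {
  if (is.null(labels)) labels <- matrix(integer(0), 0, 0)
  wf_evolve_cpp(pool, labels, as.integer(n_out), as.integer(generations), mu)
}

# burn a root pool to approximate mutation-drift equilibrium: stop when mean
# heterozygosity changes < 1% over 100 generations, capped at 10 * 2N
burn_in_root <- function(n_copies, n_loci, mu, start_size = 20L) {
  pool <- matrix(as.integer(start_size), n_copies, n_loci)
  cap <- 10L * n_copies
  h_prev <- pool_heterozygosity_cpp(pool)
  done <- 0L
  while (done < cap) {
    pool <- wf_step(pool, n_copies, 100L, mu)$alleles
    done <- done + 100L
    h <- pool_heterozygosity_cpp(pool)
    if (abs(h - h_prev) < 0.01 * max(h_prev, 1e-12)) break
    h_prev <- h
  }
  pool
}

#' Run a serial-founder / admixture forward simulation
#'
#' See \code{\link{sim_config}} for the generative model. Returns sampled
#' genotypes in the package's standard container, a population metadata
#' table, and a truth record for parameter-recovery tests.
#'
#' @param config a `sim_config` (seed mandatory).
#' @return a list of class `admix_sim` with elements
#'   \describe{
#'     \item{genotypes}{a \code{\link{genotype_matrix}} of all sampled
#'       individuals (demes plus outgroups).}
#'     \item{meta}{data.frame: population, region, language_family,
#'       latitude, longitude, n_individuals, distance_km, founding_order.}
#'     \item{truth}{list: `alpha_configured` and `alpha_realized` (deme x
#'       source), `ancestry` (sampled individual x source-plus-native true
#'       fractions), `founding_order`, `expected_H` (drift-only closed form),
#'       `realized_H` (identity-form pool heterozygosity at sampling),
#'       `language_map`.}
#'   }
#' @export
simulate_genotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  N <- config$deme_size; L <- config$n_loci; mu <- config$mu
  two_n <- 2L * N
  g_between <- config$generations_between
  D <- config$n_demes
  chain_total <- g_between * D          # deme 1 founded this long ago
  pulse_at <- config$admixture_generations_ago
  sources <- names(config$outgroups)          # sampled outgroup populations
  alpha <- admixture_fractions(config)
  adm_sources <- colnames(alpha)              # sources that actually admix

  root <- burn_in_root(two_n, L, mu)
  H_root <- pool_heterozygosity_cpp(root)

  # timeline bookkeeping: every branch evolves independently after its split;
  # splits deeper than the chain start are handled by pre-evolving the branch
  out_pools <- list()
  for (s in sources) {
    t_s <- config$outgroups[[s]]
    out_pools[[s]] <- wf_step(root, two_n, t_s, mu)$alleles
  }

  # serial chain: a founding is `dur` WF generations at size N_f (the
  # founding draw is the first), after which the deme expands to N; deme d
  # is founded ages[d] generations before the present
  dur <- config$founder_duration
  demes <- vector("list", D)
  ages <- chain_total - (seq_len(D) - 1L) * g_between
  demes[[1]] <- wf_step(root, 2L * config$founder_size[1], dur, mu)$alleles
  # in founding order: deme d completes its inter-founding interval at full
  # size, then spawns deme d+1 from its current state
  for (d in seq_len(D - 1L)) {
    demes[[d]] <- wf_step(demes[[d]], two_n, g_between - dur, mu)$alleles
    demes[[d + 1]] <- wf_step(demes[[d]], 2L * config$founder_size[d + 1],
                              dur, mu)$alleles
  }
  # generations each deme still has to live when deme D has just been
  # founded: deme d < D has spent g_between (dur + the rest), deme D dur
  spent <- ifelse(seq_len(D) < D, g_between, dur)
  rem <- ages - spent
  if (any(rem < pulse_at))
    stop("admixture_generations_ago exceeds the youngest deme's remaining lifetime")

  # evolve to the pulse, apply it with ancestry labels, evolve to the present
  labels <- vector("list", D)
  n_src <- length(adm_sources)
  for (d in seq_len(D)) {
    demes[[d]] <- wf_step(demes[[d]], two_n, rem[d] - pulse_at, mu)$alleles
    lab <- matrix(0L, two_n, L)  # 0 = native
    if (n_src > 0 && any(alpha[d, ] > 0)) {
      u <- matrix(stats::runif(two_n * L), two_n, L)
      cuts <- cumsum(alpha[d, ])
      lower <- c(0, cuts[-n_src])
      for (si in seq_len(n_src)) {
        hit <- which(u >= lower[si] & u < cuts[si])
        if (length(hit)) {
          src <- out_pools[[adm_sources[si]]]
          cols <- ((hit - 1L) %/% two_n) + 1L
          rows <- sample.int(nrow(src), length(hit), replace = TRUE)
          demes[[d]][hit] <- src[cbind(rows, cols)]
          lab[hit] <- si
        }
      }
    }
    st <- wf_step(demes[[d]], two_n, pulse_at, mu, labels = lab)
    demes[[d]] <- st$alleles
    labels[[d]] <- st$labels
  }

  # sampling: pair random distinct gene-copy rows into diploid individuals
  sample_pool <- function(pool, n_ind, lab = NULL) {
    rows <- sample.int(nrow(pool), 2L * n_ind)
    calls <- array(NA_integer_, c(n_ind, L, 2))
    calls[, , 1] <- pool[rows[seq(1, 2 * n_ind, 2)], , drop = FALSE]
    calls[, , 2] <- pool[rows[seq(2, 2 * n_ind, 2)], , drop = FALSE]
    anc <- NULL
    if (!is.null(lab)) {
      l1 <- lab[rows[seq(1, 2 * n_ind, 2)], , drop = FALSE]
      l2 <- lab[rows[seq(2, 2 * n_ind, 2)], , drop = FALSE]
      anc <- matrix(0, n_ind, n_src + 1L,
                    dimnames = list(NULL, c("native", adm_sources)))
      for (si in 0:n_src) {
        anc[, si + 1L] <- (rowSums(l1 == si) + rowSums(l2 == si)) / (2 * L)
      }
    }
    list(calls = calls, ancestry = anc)
  }

  # language families over contiguous blocks, then random decoupling
  n_fam <- max(1L, ceiling(D / config$language_block_size))
  fam_names <- paste0("F", seq_len(n_fam))
  lang <- fam_names[((seq_len(D) - 1L) %/% config$language_block_size) + 1L]
  flip <- stats::runif(D) < config$language_decouple_prob
  lang[flip] <- sample(fam_names, sum(flip), replace = TRUE)

  deme_names <- sprintf("deme%02d", seq_len(D))
  calls_list <- list(); ids <- character(0); pop_of <- character(0)
  anc_list <- list()
  realized_H <- numeric(D)
  for (d in seq_len(D)) {
    sm <- sample_pool(demes[[d]], config$sample_size, labels[[d]])
    calls_list[[length(calls_list) + 1L]] <- sm$calls
    id <- sprintf("%s_i%03d", deme_names[d], seq_len(config$sample_size))
    ids <- c(ids, id)
    pop_of <- c(pop_of, stats::setNames(rep(deme_names[d], length(id)), id))
    anc_list[[d]] <- sm$ancestry
    realized_H[d] <- pool_heterozygosity_cpp(demes[[d]])
  }
  for (s in sources) {
    sm <- sample_pool(out_pools[[s]], config$outgroup_sample_size)
    calls_list[[length(calls_list) + 1L]] <- sm$calls
    id <- sprintf("%s_i%03d", s, seq_len(config$outgroup_sample_size))
    ids <- c(ids, id)
    pop_of <- c(pop_of, stats::setNames(rep(s, length(id)), id))
  }
  calls <- array(NA_integer_, c(length(ids), L, 2))
  at <- 0L
  for (b in calls_list) {
    n_b <- dim(b)[1]
    calls[at + seq_len(n_b), , ] <- b
    at <- at + n_b
  }
  G <- genotype_matrix(calls, ids, pop_of)

  n_out <- length(sources)
  lat <- config$origin[1] - config$deme_distance_km / 111.19494
  meta <- data.frame(
    population = c(deme_names, sources),
    region = c(paste0("chain", ((seq_len(D) - 1L) %/% config$language_block_size) + 1L),
               sources),
    language_family = c(lang, rep("NA", n_out)),
    latitude = c(lat, rep(0, n_out)),
    longitude = c(rep(config$origin[2], D), seq_len(n_out) * 30),
    n_individuals = c(rep(config$sample_size, D),
                      rep(config$outgroup_sample_size, n_out)),
    distance_km = c(config$deme_distance_km, rep(NA, n_out)),
    founding_order = c(seq_len(D), rep(NA, n_out)),
    stringsAsFactors = FALSE)

  ancestry <- do.call(rbind, anc_list)
  rownames(ancestry) <- ids[seq_len(D * config$sample_size)]
  realized_alpha <- do.call(rbind, lapply(anc_list, colMeans))
  rownames(realized_alpha) <- deme_names

  # drift-only expectation (exact at mu = 0): deme d's lineage spans
  # chain_total generations from the chain start, dur of them at each of
  # the d founder sizes on its path, the rest at N
  expected_H <- numeric(D)
  ff <- 1
  for (d in seq_len(D)) {
    ff <- ff * (1 - 1 / (2 * config$founder_size[d]))^dur
    expected_H[d] <- H_root * ff *
      (1 - 1 / (2 * N))^(chain_total - d * dur)
  }

  structure(list(
    genotypes = G, meta = meta,
    truth = list(alpha_configured = alpha,
                 alpha_realized = realized_alpha,
                 ancestry = ancestry,
                 founding_order = seq_len(D),
                 expected_H = stats::setNames(expected_H, deme_names),
                 realized_H = stats::setNames(realized_H, deme_names),
                 H_root = H_root,
                 language_map = stats::setNames(lang, deme_names))),
    class = "admix_sim")
}

#' @export
print.admix_sim <- function(x, ...) {
  cat(sprintf("admix_sim: %d demes + %d outgroups, %d loci, %d sampled individuals\n",
              length(x$truth$founding_order),
              sum(is.na(x$meta$founding_order)),
              length(x$genotypes$loci),
              length(x$genotypes$individual_ids)))
  invisible(x)
}
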
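test_that("the same seed reproduces the simulation bit-identically", {
  cfg <- sim_config(n_loci = 30, n_demes = 4, sample_size = 8, seed = 77)
  a <- simulate_genotypes(cfg)
  b <- simulate_genotypes(cfg)
  expect_identical(a$genotypes$calls, b$genotypes$calls)
  expect_identical(a$truth$alpha_realized, b$truth$alpha_realized)
  expect_identical(a$meta, b$meta)
  c <- simulate_genotypes(sim_config(n_loci = 30, n_demes = 4,
                                     sample_size = 8, seed = 78))
  expect_false(identical(a$genotypes$calls, c$genotypes$calls))
})

test_that("with mu = 0 no variation can arise from a monomorphic root", {
  cfg <- sim_config(n_loci = 12, n_demes = 3, mu = 0, sample_size = 6,
                    outgroups = list(), admixture = NULL,
                    admixture_generations_ago = 0, seed = 5)
  sim <- simulate_genotypes(cfg)
  expect_true(all(sim$genotypes$calls == sim$genotypes$calls[1, 1, 1]))
  expect_true(all(sim$truth$realized_H == 0))
  expect_true(all(sim$truth$expected_H == 0))
})

test_that("config validation enforces the generative preconditions", {
  expect_error(sim_config(seed = NULL), "seed")
  expect_error(sim_config(mu = 0.5, seed = 1), "mu")
  expect_error(sim_config(founder_size = 200, deme_size = 100, seed = 1),
               "founder_size")
  expect_error(sim_config(admixture = list(EUR = list(profile = "constant",
                                                      alpha = 0.6),
                                           EAS = list(profile = "constant",
                                                      alpha = 0.5)),
                          seed = 1), "sum")
  expect_error(sim_config(outgroups = list(), seed = 1), "outgroup")
})

test_that("admixture profiles map distance to fractions as documented", {
  cfg <- sim_config(n_demes = 4, deme_spacing_km = 1000,
                    admixture = list(EUR = list(profile = "exponential",
                                                alpha0 = 0.4, lambda = 1e-3),
                                     AFR = list(profile = "constant",
                                                alpha = 0.02)),
                    seed = 1)
  a <- admixture_fractions(cfg)
  expect_equal(a[, "EUR"], 0.4 * exp(-1e-3 * c(0, 1000, 2000, 3000)))
  expect_equal(a[, "AFR"], rep(0.02, 4))
})

test_that("closed-form bottleneck expectation handles the boundary cases", {
  expect_equal(expected_heterozygosity_after_bottleneck(0.8, 50, 0, 50), 0.8)
  expect_equal(expected_heterozygosity_after_bottleneck(0, 10, 30, 100), 0)
  expect_error(expected_heterozygosity_after_bottleneck(0.5, 0, 1, 10),
               "positive")
  expect_error(expected_heterozygosity_after_bottleneck(1.2, 5, 1, 10), "H0")
})

test_that("Monte-Carlo drift decay matches the closed form within 3 SE", {
  # pool with five equifrequent alleles: H0 = 0.8 exactly, mu = 0
  set.seed(202)
  L <- 30
  pool <- matrix(rep(10:14, each = 20), nrow = 100, ncol = L)
  n_rep <- 200
  h <- numeric(n_rep)
  for (r in seq_len(n_rep)) {
    out <- admixcline:::wf_step(pool, n_out = 100, generations = 20, mu = 0)
    h[r] <- admixcline:::pool_heterozygosity_cpp(out$alleles)
  }
  expected <- expected_heterozygosity_after_bottleneck(0.8, 50, 20, 50)
  se <- stats::sd(h) / sqrt(n_rep)
  expect_lt(abs(mean(h) - expected), 3 * se)
})

test_that("with mu = 0 the allele-size support never grows", {
  set.seed(31)
  pool <- matrix(sample(c(8L, 12L), 200 * 10, replace = TRUE), 200, 10)
  out <- admixcline:::wf_step(pool, 200, 50, 0)$alleles
  expect_true(all(out %in% c(8L, 12L)))
})

test_that("stepwise mutation drives an unbiased mean-size random walk", {
  set.seed(17)
  deltas <- replicate(60, {
    pool <- matrix(20L, 100, 20)
    out <- admixcline:::wf_step(pool, 100, 50, 0.02)$alleles
    mean(out) - 20
  })
  se <- stats::sd(deltas) / sqrt(length(deltas))
  expect_lt(abs(mean(deltas)), 3 * se)
})

test_that("realized admixture tracks the configured fractions", {
  sim <- simulate_genotypes(scenario_alpha_grid(3))
  cfgd <- sim$truth$alpha_configured[, "EUR"]
  real <- sim$truth$alpha_realized[, "EUR"]
  expect_lt(max(abs(cfgd - real)), 0.12)      # drift around the pulse
  expect_lt(mean(abs(cfgd - real)), 0.05)
  # individual truth rows are proper fractions
  expect_true(all(abs(rowSums(sim$truth$ancestry) - 1) < 1e-9))
  expect_true(all(sim$truth$ancestry >= 0 & sim$truth$ancestry <= 1))
})

test_that("serial founder chains lose diversity with founding order", {
  rhos <- vapply(1:10, function(s) {
    cfg <- sim_config(n_loci = 60, n_demes = 8, founder_size = 12,
                      sample_size = 10, outgroups = list(EUR = 400),
                      admixture = NULL, seed = s)
    sim <- simulate_genotypes(cfg)
    stats::cor(sim$truth$realized_H, sim$truth$founding_order,
               method = "spearman")
  }, numeric(1))
  expect_lt(mean(rhos), -0.4)
  expect_gte(sum(rhos < 0), 8)
})

test_that("language labels form contiguous blocks unless decoupled", {
  cfg <- sim_config(n_loci = 10, n_demes = 6, language_block_size = 2,
                    language_decouple_prob = 0, sample_size = 4, seed = 2)
  sim <- simulate_genotypes(cfg)
  expect_equal(unname(sim$truth$language_map),
               rep(c("F1", "F2", "F3"), each = 2))
})
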
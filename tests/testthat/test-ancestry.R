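# independent multinomial log-likelihood of pooled frequencies, the K = 1
# oracle: every observed copy scored against the pooled allele frequencies
pooled_loglik_oracle <- function(g) {
  ll <- 0
  for (l in seq_along(g$loci)) {
    a <- c(g$calls[, l, 1], g$calls[, l, 2])
    m <- c(g$missing_mask[, l, 1], g$missing_mask[, l, 2])
    a <- a[!m]
    p <- table(a) / length(a)
    ll <- ll + sum(log(p[as.character(a)]))
  }
  ll
}

test_that("K = 1 degenerates to pooled frequencies and their likelihood", {
  g <- random_geno(15, 8, miss = 0.1, seed = 21)
  fit <- fit_admixture(g, K = 1, seed = 1, n_starts = 1)
  expect_equal(unname(fit$Q[, 1]), rep(1, 15))
  expect_equal(fit$loglik, pooled_loglik_oracle(g), tolerance = 1e-6)
  # P equals pooled frequencies
  fr <- allele_frequencies(g, stats::setNames(rep("all", 15),
                                              g$individual_ids))
  for (l in g$loci) {
    cols <- which(attr(fit$P, "locus_of") == l)
    expect_equal(unname(fit$P[1, cols]),
                 unname(fr$freq[["all"]][[l]]), tolerance = 1e-6)
  }
})

test_that("fully diagnostic loci separate two demes perfectly at K = 2", {
  L <- 40; n <- 12
  calls <- array(NA_integer_, c(2 * n, L, 2))
  calls[1:n, , ] <- 10L
  calls[(n + 1):(2 * n), , ] <- 20L
  ids <- paste0("i", seq_len(2 * n))
  pops <- stats::setNames(rep(c("A", "B"), each = n), ids)
  g <- genotype_matrix(calls, ids, pops)
  fit <- fit_admixture(g, K = 2, seed = 4, n_starts = 2)
  expect_true(all(apply(fit$Q, 1, max) > 0.99))
  assign <- apply(fit$Q, 1, which.max)
  expect_equal(length(unique(assign[1:n])), 1L)
  expect_equal(length(unique(assign[(n + 1):(2 * n)])), 1L)
  expect_false(assign[1] == assign[n + 1])
})

test_that("EM log-likelihood is non-decreasing at every iteration", {
  g <- random_geno(20, 10, miss = 0.1, seed = 8)
  for (K in 1:3) {
    fit <- fit_admixture(g, K = K, seed = K, n_starts = 1)
    expect_true(all(diff(fit$loglik_trace) >= -1e-7 *
                      abs(fit$loglik_trace[-1])))
    expect_true(all(abs(rowSums(fit$Q) - 1) < 1e-9))
  }
})

test_that("fit rejects impossible K and empty loci", {
  g <- random_geno(5, 4, seed = 1)
  expect_error(fit_admixture(g, K = 6), "exceeds")
  expect_error(fit_admixture(g, K = 0), "K must be")
  g$missing_mask[, 2, ] <- TRUE
  expect_error(fit_admixture(g, K = 2), "no observed")
})

test_that("alignment recovers a known column permutation and K = 1 is a no-op", {
  g <- random_geno(18, 12, seed = 33)
  fit <- fit_admixture(g, K = 3, seed = 2, n_starts = 2)
  swapped <- fit
  perm <- c(3L, 1L, 2L)
  swapped$Q <- fit$Q[, perm]
  swapped$P <- fit$P[perm, ]
  out <- align_runs(list(swapped), reference = fit)[[1]]
  expect_equal(out$Q, fit$Q)
  f1 <- fit_admixture(g, K = 1, seed = 2, n_starts = 1)
  expect_equal(align_runs(list(f1))[[1]]$Q, f1$Q)
})

test_that("greedy alignment matches the exhaustive permutation oracle", {
  sim <- simulate_genotypes(scenario_true_k3(9))
  runs <- lapply(1:5, function(r)
    fit_admixture(sim$genotypes, K = 3, seed = 100 + r, n_starts = 1))
  ref <- runs[[1]]
  aligned <- align_runs(runs, reference = ref)
  for (i in seq_along(runs)) {
    sims <- vapply(all_perms(3L), function(p)
      sum(ref$Q * runs[[i]]$Q[, p]), numeric(1))
    best <- all_perms(3L)[[which.max(sims)]]
    expect_equal(aligned[[i]]$permutation, as.integer(best))
  }
  # alignment shrinks the across-run spread of Q
  spread <- function(fits) {
    qs <- simplify2array(lapply(fits, `[[`, "Q"))
    mean(apply(qs, c(1, 2), stats::sd))
  }
  expect_lt(spread(aligned), spread(runs) + 1e-12)
})

test_that("delta-K reproduces hand-computed second differences", {
  means <- c(-100, -80, -75, -74.5)
  ll <- rbind(means - 1, means, means + 1)   # sd exactly 1, means exact
  dk <- delta_k(ll, K_values = 5:8)
  expect_equal(dk$delta_K, c(NA, 15, 4.5, NA))
  expect_equal(dk$Lp, c(NA, 20, 5, 0.5))
})

test_that("linear mean log-likelihood gives zero delta-K everywhere", {
  means <- seq(-200, -140, by = 20)
  ll <- rbind(means - 2, means, means + 2)
  dk <- delta_k(ll, K_values = 2:5)
  expect_equal(dk$delta_K[2:3], c(0, 0))
})

test_that("zero across-run variance flags delta-K as undefined", {
  ll <- rbind(c(-10, -5, -4), c(-10, -5, -4), c(-10, -5, -4))
  dk <- delta_k(ll, K_values = 2:4)
  expect_true(is.na(dk$delta_K[2]))
  expect_error(delta_k(ll[1:2, ], K_values = 2:4), ">= 3")
})

test_that("population means of Q are exact averages and order-invariant", {
  g <- random_geno(16, 6, n_pops = 3, seed = 41)
  fit <- fit_admixture(g, K = 2, seed = 3, n_starts = 1)
  gr <- populations(g)
  pm <- ancestry_by_population(fit, gr)
  for (p in rownames(pm))
    expect_equal(pm[p, ], colMeans(fit$Q[gr == p, , drop = FALSE]))
  expect_true(all(abs(rowSums(pm) - 1) < 1e-9))
  # permuting individuals leaves the table unchanged
  set.seed(1); idx <- sample(16)
  fit2 <- fit; fit2$Q <- fit$Q[idx, ]
  expect_equal(pm[rownames(pm), ],
               ancestry_by_population(fit2, gr)[rownames(pm), ])
  expect_error(ancestry_by_population(fit, gr[-1]), "without a population")
})

test_that("cluster annotation finds dominant sources and flags the rest", {
  sim <- simulate_genotypes(scenario_alpha_grid(5))
  fit <- fit_admixture(sim$genotypes, K = 2, seed = 2, n_starts = 2)
  ann <- annotate_clusters(fit, populations(sim$genotypes),
                           list(EUR = "EUR"))
  expect_equal(sort(ann), c("EUR", "unassigned"))
  est <- non_native_ancestry(ancestry_by_population(fit,
                                                    populations(sim$genotypes)),
                             ann)
  expect_lt(est[["deme01"]], 0.05)
  expect_gt(est[["EUR"]], 0.95)
})

test_that("K-sensitivity curves flatten once K reaches the true cluster count", {
  sim <- simulate_genotypes(scenario_alpha_grid(13))
  series <- run_admixture_series(sim$genotypes, 2:4, n_runs = 3,
                                 seed = 55, n_starts = 1)
  sens <- k_sensitivity(series, populations(sim$genotypes),
                        list(EUR = "EUR"))
  eur <- sens[sens$component == "EUR" & sens$population == "deme06", ]
  eur <- eur[order(eur$K), ]
  expect_equal(nrow(eur), 3L)
  # true structure is native + EUR: the annotated EUR share of the most
  # admixed deme stays within a narrow band across K
  expect_lt(max(eur$ancestry) - min(eur$ancestry), 0.15)
})
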
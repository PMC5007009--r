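test_that("a single polymorphic locus puts all variance on PC1", {
  calls <- array(10L, c(6, 3, 2))
  calls[, 2, 1] <- c(10L, 10L, 10L, 12L, 12L, 12L)
  calls[, 2, 2] <- c(10L, 10L, 12L, 12L, 12L, 12L)
  ids <- paste0("i", 1:6)
  g <- genotype_matrix(calls, ids, stats::setNames(rep("p", 6), ids))
  ord <- pca_genotypes(g, n_axes = 3)
  expect_equal(ord$variance_fraction[1], 1, tolerance = 1e-10)
  expect_equal(ord$n_dropped_columns, 2L)  # two monomorphic loci
})

test_that("duplicated individuals get identical scores", {
  g <- random_geno(10, 8, seed = 44)
  calls <- g$calls[c(1:10, 1), , , drop = FALSE]
  ids <- c(g$individual_ids, "dup")
  g2 <- genotype_matrix(calls, ids,
                        stats::setNames(rep("p", 11), ids))
  ord <- pca_genotypes(g2, n_axes = 4)
  expect_equal(ord$scores["ind1", ], ord$scores["dup", ], tolerance = 1e-8)
})

test_that("PCA scores match an independent eigendecomposition oracle", {
  g <- random_geno(30, 10, seed = 77, alleles = 9:12)
  ord <- pca_genotypes(g, n_axes = 5)
  X <- dosage_oracle(g)
  X <- X[, apply(X, 2, stats::var) > 1e-12, drop = FALSE]
  Xs <- scale(X)
  ev <- eigen(stats::cov(Xs), symmetric = TRUE)
  scores <- Xs %*% ev$vectors[, 1:5]
  for (j in 1:5) {
    agree <- max(abs(scores[, j] - ord$scores[, j]))
    flip <- max(abs(scores[, j] + ord$scores[, j]))
    expect_lt(min(agree, flip), 1e-8)
  }
  expect_equal(ord$eigenvalues[1:5] * (29 / 29), ev$values[1:5],
               tolerance = 1e-8)
  expect_true(all(diff(ord$variance_fraction) <= 1e-12))
})

test_that("classical MDS recovers planar configurations", {
  set.seed(10)
  pts <- cbind(runif(5, -3, 3), runif(5, -3, 3))
  D <- as.matrix(stats::dist(pts))
  ord <- classical_mds(D, n_axes = 2)
  Drec <- as.matrix(stats::dist(ord$scores))
  expect_equal(Drec, D, tolerance = 1e-8, ignore_attr = TRUE)
  expect_lt(ord$negative_eigenvalue_mass, 1e-8)
})

test_that("a regular simplex gives equal positive eigenvalues", {
  n <- 5
  D <- matrix(1, n, n) - diag(n)
  ord <- suppressWarnings(classical_mds(D, n_axes = n - 1))
  eig <- ord$eigenvalues[ord$eigenvalues > 1e-9]
  expect_equal(length(eig), n - 1L)
  expect_lt(diff(range(eig)), 1e-9)
})

test_that("MDS matches an independent double-centering oracle", {
  set.seed(21)
  pts <- matrix(rnorm(8 * 3), 8, 3)
  D <- as.matrix(stats::dist(pts))
  ord <- classical_mds(D, n_axes = 3)
  n <- nrow(D)
  J <- diag(n) - matrix(1 / n, n, n)
  B <- -0.5 * J %*% D^2 %*% J
  ev <- eigen(B, symmetric = TRUE)
  oracle <- ev$vectors[, 1:3] %*% diag(sqrt(ev$values[1:3]))
  for (j in 1:3) {
    agree <- max(abs(oracle[, j] - ord$scores[, j]))
    flip <- max(abs(oracle[, j] + ord$scores[, j]))
    expect_lt(min(agree, flip), 1e-8)
  }
})

test_that("MDS on distances between PCA scores reproduces the scores", {
  g <- random_geno(15, 8, seed = 31)
  ord <- pca_genotypes(g, n_axes = 3)
  D <- as.matrix(stats::dist(ord$scores))
  rec <- classical_mds(D, n_axes = 3)
  expect_equal(as.matrix(stats::dist(rec$scores)), D,
               tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("MDS validates its input and truncates to positive eigenvalues", {
  D <- matrix(c(0, 1, 2, 0), 2, 2)
  expect_error(classical_mds(D), "symmetric")
  pts <- cbind(1:4)
  D <- as.matrix(stats::dist(pts))        # rank-1 configuration
  expect_warning(ord <- classical_mds(D, n_axes = 3), "truncating")
  expect_equal(ncol(ord$scores), 1L)
})

test_that("axis-covariate correlations behave at the extremes", {
  g <- random_geno(20, 10, seed = 50)
  ord <- pca_genotypes(g, n_axes = 3)
  r <- axis_covariate_correlation(ord, ord$scores[, 1], axes = 1)
  expect_equal(unname(r), 1, tolerance = 1e-10)
  z0 <- rnorm(20)
  z <- stats::resid(stats::lm(z0 ~ ord$scores))
  r <- axis_covariate_correlation(ord, as.numeric(z), axes = 1:3)
  expect_true(all(abs(r) < 1e-10))
  expect_warning(r <- axis_covariate_correlation(ord, rep(1, 20)),
                 "constant")
  expect_true(all(is.na(r)))
})

test_that("leading axis tracks true ancestry in an admixture simulation", {
  sim <- simulate_genotypes(scenario_alpha_grid(2))
  g <- subset_genotypes(sim$genotypes,
                        keep_populations = sprintf("deme%02d", 1:6))
  ord <- pca_genotypes(g, n_axes = 2)
  truth <- 1 - sim$truth$ancestry[rownames(ord$scores), "native"]
  r <- axis_covariate_correlation(ord, truth, axes = 1)
  expect_gt(abs(r), 0.9)
})

test_that("concordant families give perfect neighbour rates and small p", {
  # two tight clades, families aligned with them; clades of six keep the
  # label-permutation space large enough for p to reach 0.01
  set.seed(6)
  pts <- rbind(matrix(rnorm(12, 0, 0.1), 6, 2),
               matrix(rnorm(12, 10, 0.1), 6, 2))
  D <- as.matrix(stats::dist(pts))
  rownames(D) <- colnames(D) <- paste0("p", 1:12)
  fams <- stats::setNames(rep(c("A", "B"), each = 6), rownames(D))
  ls <- gene_language_summary(D, fams, n_perm = 999, seed = 3)
  expect_equal(ls$nn_same_family_rate, 1)
  expect_lte(ls$p_perm, 0.01)
  expect_gt(ls$contrast, 0)
})

test_that("random family labels calibrate the permutation null", {
  set.seed(40)
  pts <- matrix(rnorm(24), 12, 2)
  D <- as.matrix(stats::dist(pts))
  rownames(D) <- colnames(D) <- paste0("p", 1:12)
  rejections <- 0L
  for (s in 1:20) {
    set.seed(1000 + s)
    fams <- stats::setNames(sample(rep(c("A", "B", "C"), each = 4)),
                            rownames(D))
    ls <- gene_language_summary(D, fams, n_perm = 199, seed = s)
    if (ls$p_perm <= 0.05) rejections <- rejections + 1L
  }
  expect_lte(rejections, 4L)   # binomial 95% upper bound at alpha = 0.05
  # reproducibility and validity of the permutation p
  fams <- stats::setNames(rep(c("A", "B", "C"), each = 4), rownames(D))
  p1 <- gene_language_summary(D, fams, n_perm = 199, seed = 7)$p_perm
  p2 <- gene_language_summary(D, fams, n_perm = 199, seed = 7)$p_perm
  expect_identical(p1, p2)
  expect_gte(p1, 1 / 200)
})

test_that("all-singleton families flag the within statistic undefined", {
  pts <- matrix(rnorm(8), 4, 2)
  D <- as.matrix(stats::dist(pts))
  rownames(D) <- colnames(D) <- paste0("p", 1:4)
  fams <- stats::setNames(paste0("F", 1:4), rownames(D))
  ls <- gene_language_summary(D, fams, n_perm = 99, seed = 1)
  expect_true(is.na(ls$contrast))
  expect_true(is.na(ls$nn_same_family_rate))
  expect_error(gene_language_summary(D, fams, n_perm = 99), "seed")
})
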
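test_that("pearson_cor matches the textbook formula and cor.test", {
  expect_equal(pearson_cor(1:10, 2 * (1:10) + 1)$r, 1)
  x <- c(1, -1, 1, -1); y <- c(1, 1, -1, -1)       # orthogonal after centering
  expect_equal(pearson_cor(x, y)$r, 0)
  set.seed(19)
  x <- rnorm(29); y <- rnorm(29)
  got <- pearson_cor(x, y)
  r_hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  p_hand <- 2 * stats::pt(-abs(r_hand * sqrt(27 / (1 - r_hand^2))), 27)
  expect_equal(got$r, r_hand, tolerance = 1e-12)
  expect_equal(got$p, p_hand, tolerance = 1e-12)
  ct <- stats::cor.test(x, y)
  expect_equal(got$r, unname(ct$estimate), tolerance = 1e-12)
  expect_equal(got$p, ct$p.value, tolerance = 1e-10)
  expect_true(is.na(pearson_cor(rep(1, 5), rnorm(5))$r))
})

test_that("partial correlation reduces and degenerates as the formula says", {
  set.seed(23)
  x <- rnorm(20); y <- rnorm(20)
  z0 <- rnorm(20)
  z <- stats::resid(stats::lm(z0 ~ x + y))   # exactly uncorrelated control
  expect_equal(partial_correlation(x, y, z)$r, pearson_cor(x, y)$r,
               tolerance = 1e-10)
  out <- partial_correlation(x, y, x)        # degenerate control
  expect_false(out$defined)
  expect_true(is.na(out$r))
  # constant z: nothing to remove
  out <- partial_correlation(x, y, rep(2, 20))
  expect_equal(out$r, pearson_cor(x, y)$r)
})

test_that("formula and residual-regression partial correlations coincide", {
  set.seed(37)
  for (i in 1:50) {
    x <- rnorm(29); y <- rnorm(29); z <- rnorm(29)
    r_formula <- partial_correlation(x, y, z)$r
    r_resid <- stats::cor(stats::resid(stats::lm(x ~ z)),
                          stats::resid(stats::lm(y ~ z)))
    expect_equal(r_formula, r_resid, tolerance = 1e-10)
  }
})

test_that("jackknife drops are exact on collinear and duplicated data", {
  x <- 1:12; y <- 3 - 0.5 * x                     # perfectly collinear
  units <- stats::setNames(rep(c("u1", "u2", "u3"), each = 4),
                           paste0("pop", 1:12))
  jk <- jackknife_influence(x, y, units = units)
  expect_equal(jk$r, rep(-1, 4))
  expect_equal(jk$delta_r[-1], rep(0, 3), tolerance = 1e-12)
  # duplicated data: dropping one copy of a unit recovers the baseline r
  set.seed(3)
  x <- rnorm(8); y <- rnorm(8)
  r_base <- pearson_cor(x, y)$r
  x2 <- c(x, x); y2 <- c(y, y)
  units2 <- c(rep("copy1", 8), rep("copy2", 8))
  jk2 <- jackknife_influence(x2, y2, units = units2)
  expect_equal(jk2$r[jk2$unit == "copy1"], r_base, tolerance = 1e-12)
})

test_that("drops leaving too few populations are flagged, not computed", {
  x <- rnorm(6); y <- rnorm(6)
  units <- rep(c("big", "small"), c(4, 2))
  jk <- jackknife_influence(x, y, units = units)
  expect_true(is.na(jk$r[jk$unit == "big"]))      # 2 left < 4
  expect_false(is.na(jk$r[jk$unit == "small"]))
})

test_that("gradient analysis handles degenerate covariates and exact clines", {
  div <- data.frame(population = paste0("p", 1:8),
                    H = seq(0.8, 0.1, length.out = 8))
  geo <- data.frame(population = paste0("p", 1:8),
                    distance_km = seq(0, 7000, length.out = 8))
  z0 <- stats::setNames(rep(0, 8), paste0("p", 1:8))
  g <- gradient_analysis(div, geo, covariate = z0)
  expect_equal(g$r, -1)
  expect_equal(g$r_partial, g$r)                  # zero covariate
  # scale invariance: km -> miles, H -> percent
  div2 <- div; div2$H <- 100 * div$H
  geo2 <- geo; geo2$distance_km <- geo$distance_km / 1.609
  set.seed(8)
  div$H <- div$H + rnorm(8, 0, 0.05)
  div2$H <- 100 * div$H
  z <- stats::setNames(runif(8), div$population)
  g1 <- gradient_analysis(div, geo, covariate = z)
  g2 <- gradient_analysis(div2, geo2, covariate = z)
  expect_equal(g1$r, g2$r, tolerance = 1e-12)
  expect_equal(g1$r_partial, g2$r_partial, tolerance = 1e-12)
  # misaligned populations error out
  geo_bad <- geo; geo_bad$population[1] <- "zzz"
  expect_error(gradient_analysis(div, geo_bad, covariate = z), "misaligned")
})

test_that("residual pairs reproduce the partial correlation graphically", {
  set.seed(91)
  n <- 15
  div <- data.frame(population = paste0("p", 1:n), H = runif(n, 0.2, 0.8))
  geo <- data.frame(population = paste0("p", 1:n),
                    distance_km = runif(n, 0, 9000))
  z <- stats::setNames(runif(n), div$population)
  g <- gradient_analysis(div, geo, covariate = z)
  r_resid <- stats::cor(g$residuals$resid_distance, g$residuals$resid_H)
  expect_equal(g$r_partial, r_resid, tolerance = 1e-10)
})

test_that("jackknife means stay near the baseline on homogeneous data", {
  set.seed(55)
  n <- 20
  x <- runif(n, 0, 1000)
  y <- 0.7 - 4e-4 * x + rnorm(n, 0, 0.03)
  jk <- jackknife_influence(x, y)
  drops <- jk[-1, ]
  expect_lt(abs(mean(drops$r) - jk$r[1]), 0.02)
})

test_that("bootstrap CI brackets the estimate and is reproducible", {
  set.seed(12)
  x <- rnorm(12); y <- 0.5 * x + rnorm(12); z <- rnorm(12)
  a <- bootstrap_partial_ci(x, y, z, n_boot = 200, seed = 5)
  b <- bootstrap_partial_ci(x, y, z, n_boot = 200, seed = 5)
  expect_identical(a, b)
  expect_lte(a$lower, a$upper)
  expect_gte(a$n_boot_used, 190)
})
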
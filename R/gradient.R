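#' Pearson correlation with a t-based p-value
#'
#' Two-sided p from `t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2` degrees
#' of freedom. Constant input is flagged `NA` rather than an error surface.
#'
#' @param x,y numeric vectors, `n >= 3`.
#' @return list: `r`, `p`, `n`.
#' @export
pearson_cor <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("need n >= 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(r = NA_real_, p = NA_real_, n = n))
  r <- stats::cor(x, y)
  p <- if (abs(r) >= 1) 0 else {
    t <- r * sqrt((n - 2) / (1 - r^2))
    2 * stats::pt(-abs(t), df = n - 2)
  }
  list(r = r, p = p, n = n)
}

#' First-order partial correlation
#'
#' `r_xy.z = (r_xy - r_xz r_yz) / sqrt((1 - r_xz^2)(1 - r_yz^2))`, the
#' correlation between `x` and `y` after linearly removing `z`; identically
#' the correlation of the residuals from regressing `x` on `z` and `y` on
#' `z`. Two-sided p from a t statistic on `n - 3` degrees of freedom.
#' Degenerate controls (`|r_xz| = 1` or `|r_yz| = 1`, or constant `z`) give
#' `NA`, flagged via the `defined` field.
#'
#' @param x,y numeric vectors, `n >= 4`.
#' @param z control covariate. A constant `z` reduces the partial
#'   correlation to the plain correlation (nothing to remove).
#' @return list: `r`, `p`, `n`, `defined`.
#' @export
partial_correlation <- function(x, y, z) {
  ok <- stats::complete.cases(x, y, z)
  x <- x[ok]; y <- y[ok]; z <- z[ok]
  n <- length(x)
  if (n < 4) stop("need n >= 4 complete triples")
  if (stats::sd(z) == 0) {
    base <- pearson_cor(x, y)
    return(list(r = base$r, p = base$p, n = n, defined = !is.na(base$r)))
  }
  r_xy <- stats::cor(x, y); r_xz <- stats::cor(x, z); r_yz <- stats::cor(y, z)
  den <- (1 - r_xz^2) * (1 - r_yz^2)
  if (den <= .Machine$double.eps)
    return(list(r = NA_real_, p = NA_real_, n = n, defined = FALSE))
  r <- (r_xy - r_xz * r_yz) / sqrt(den)
  p <- if (abs(r) >= 1) 0 else {
    t <- r * sqrt((n - 3) / (1 - r^2))
    2 * stats::pt(-abs(t), df = n - 3)
  }
  list(r = r, p = p, n = n, defined = TRUE)
}

#' Drop-one jackknife attribution of a (partial) correlation
#'
#' Recomputes the correlation and partial correlation of `y` vs `x`
#' (controlling `z`) with each unit removed in turn. Units are either the
#' populations themselves or groups of populations (regions); the influence
#' of a unit is the signed change `delta_r = r(without unit) - r(baseline)`,
#' so negative values mean removal strengthens a negative correlation.
#'
#' @param x,y,z aligned numeric vectors per population (`z` may be NULL for
#'   correlation only).
#' @param units named character/factor vector assigning each population to a
#'   unit; defaults to one unit per population.
#' @param labels population labels (used when `units` is per population).
#' @return data.frame with a `baseline` first row then one row per dropped
#'   unit: `unit`, `n_left`, `r`, `p`, `r_partial`, `p_partial`, `delta_r`,
#'   `delta_r_partial`. Drops leaving fewer than 4 populations are flagged
#'   `NA`.
#' @export
jackknife_influence <- function(x, y, z = NULL, units = NULL, labels = NULL) {
  n <- length(x)
  if (is.null(labels)) labels <- paste0("pop", seq_len(n))
  if (is.null(units)) units <- stats::setNames(labels, labels)
  if (length(units) != n) stop("units must assign every population")
  compute <- function(keep) {
    r <- pearson_cor(x[keep], y[keep])
    if (!is.null(z)) {
      pr <- partial_correlation(x[keep], y[keep], z[keep])
      c(r = r$r, p = r$p, r_partial = pr$r, p_partial = pr$p)
    } else c(r = r$r, p = r$p, r_partial = NA_real_, p_partial = NA_real_)
  }
  base <- compute(rep(TRUE, n))
  rows <- list(data.frame(unit = "(baseline)", n_left = n,
                          r = base["r"], p = base["p"],
                          r_partial = base["r_partial"],
                          p_partial = base["p_partial"],
                          delta_r = 0, delta_r_partial = 0,
                          stringsAsFactors = FALSE))
  for (u in unique(units)) {
    keep <- units != u
    if (sum(keep) < 4) {
      rows[[length(rows) + 1L]] <- data.frame(
        unit = u, n_left = sum(keep), r = NA_real_, p = NA_real_,
        r_partial = NA_real_, p_partial = NA_real_,
        delta_r = NA_real_, delta_r_partial = NA_real_,
        stringsAsFactors = FALSE)
      next
    }
    v <- compute(keep)
    rows[[length(rows) + 1L]] <- data.frame(
      unit = u, n_left = sum(keep), r = v["r"], p = v["p"],
      r_partial = v["r_partial"], p_partial = v["p_partial"],
      delta_r = v["r"] - base["r"],
      delta_r_partial = v["r_partial"] - base["r_partial"],
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Diversity-versus-distance gradient analysis
#'
#' The package's core inference in one call: Pearson correlation of gene
#' diversity against route-constrained distance from the origin, the partial
#' correlation controlling a single combined admixture covariate
#' (non-native ancestry), residual pairs for plotting, and drop-one
#' jackknife tables at the population and (optionally) region level.
#'
#' @param diversity data.frame from \code{\link{gene_diversity}} (columns
#'   `population`, `H`).
#' @param geotable data.frame from \code{\link{build_geotable}} (columns
#'   `population`, `distance_km`).
#' @param covariate named numeric vector per population (e.g. from
#'   \code{\link{non_native_ancestry}}), or NULL for correlation only.
#' @param regions optional named character vector population -> region for
#'   the region-level jackknife.
#' @return a `gradient_result`: list with `r`, `p`, `r_partial`,
#'   `p_partial`, `n`, `data` (merged per-population table), `residuals`
#'   (residuals of H and distance on the covariate), `jackknife_population`,
#'   `jackknife_region`.
#' @export
gradient_analysis <- function(diversity, geotable, covariate = NULL,
                              regions = NULL) {
  df <- merge(diversity[, c("population", "H")],
              geotable[, c("population", "distance_km")],
              by = "population")
  if (nrow(df) < nrow(diversity) || nrow(df) < nrow(geotable))
    stop("misaligned population sets between diversity and geotable")
  if (!is.null(covariate)) {
    miss <- setdiff(df$population, names(covariate))
    if (length(miss))
      stop("covariate missing populations: ", paste(miss, collapse = ", "))
    df$covariate <- as.numeric(covariate[df$population])
  }
  x <- df$distance_km; y <- df$H
  base <- pearson_cor(x, y)
  if (!is.null(covariate)) {
    pr <- partial_correlation(x, y, df$covariate)
    if (stats::sd(df$covariate) > 0) {
      res_y <- stats::resid(stats::lm(y ~ df$covariate))
      res_x <- stats::resid(stats::lm(x ~ df$covariate))
    } else {
      res_y <- y - mean(y); res_x <- x - mean(x)
    }
    residuals <- data.frame(population = df$population,
                            resid_distance = as.numeric(res_x),
                            resid_H = as.numeric(res_y))
  } else {
    pr <- list(r = NA_real_, p = NA_real_)
    residuals <- NULL
  }
  z <- if (!is.null(covariate)) df$covariate else NULL
  jk_pop <- jackknife_influence(x, y, z, labels = df$population)
  jk_reg <- NULL
  if (!is.null(regions)) {
    miss <- setdiff(df$population, names(regions))
    if (length(miss))
      stop("regions missing populations: ", paste(miss, collapse = ", "))
    jk_reg <- jackknife_influence(x, y, z,
                                  units = as.character(regions[df$population]),
                                  labels = df$population)
  }
  structure(list(r = base$r, p = base$p,
                 r_partial = pr$r, p_partial = pr$p, n = nrow(df),
                 data = df, residuals = residuals,
                 jackknife_population = jk_pop,
                 jackknife_region = jk_reg),
            class = "gradient_result")
}

#' @export
print.gradient_result <- function(x, ...) {
  cat(sprintf("gradient_result: n = %d populations\n", x$n))
  cat(sprintf("  r = %.3f (p = %.3g)\n", x$r, x$p))
  if (!is.na(x$r_partial))
    cat(sprintf("  r_partial = %.3f (p = %.3g), controlling non-native ancestry\n",
                x$r_partial, x$p_partial))
  invisible(x)
}

#' Bootstrap confidence interval for the partial correlation
#'
#' Nonparametric bootstrap over populations: resamples the (distance, H,
#' covariate) triples with replacement and recomputes the partial
#' correlation. Resamples in which the partial correlation is undefined
#' (degenerate control) are discarded.
#'
#' @param x,y,z aligned numeric vectors per population.
#' @param n_boot bootstrap replicates.
#' @param level confidence level.
#' @param seed integer seed.
#' @return list: `lower`, `upper`, `estimate`, `n_boot_used`.
#' @export
bootstrap_partial_ci <- function(x, y, z, n_boot = 1000L, level = 0.95,
                                 seed = 1L) {
  set.seed(seed)
  n <- length(x)
  est <- partial_correlation(x, y, z)$r
  reps <- numeric(0)
  for (b in seq_len(n_boot)) {
    idx <- sample.int(n, n, replace = TRUE)
    if (stats::sd(x[idx]) == 0 || stats::sd(y[idx]) == 0) next
    r <- partial_correlation(x[idx], y[idx], z[idx])$r
    if (!is.na(r)) reps <- c(reps, r)
  }
  a <- (1 - level) / 2
  q <- stats::quantile(reps, c(a, 1 - a), names = FALSE)
  list(lower = q[1], upper = q[2], estimate = est,
       n_boot_used = length(reps))
}
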
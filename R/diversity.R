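#' Per-population gene diversity
#'
#' Nei's unbiased gene diversity per locus,
#' `H_hat = m/(m-1) * (1 - sum(p_hat^2))` with `m` the observed gene copies,
#' averaged over the loci with defined frequencies and at least `min_copies`
#' copies. The `m/(m-1)` correction matters for the small, unequal samples
#' typical of compiled microsatellite data.
#'
#' @param freqs an `allele_freq_table` from \code{\link{allele_frequencies}}.
#' @param min_copies minimum observed gene copies for a locus to enter a
#'   population's average (default 2; the estimator needs `m >= 2`).
#' @return data.frame: `population`, `H` (NA when no locus is usable),
#'   `n_loci_used`, `mean_gene_copies`.
#' @export
gene_diversity <- function(freqs, min_copies = 2L) {
  rows <- lapply(freqs$populations, function(p) {
    hs <- c(); ms <- c()
    for (l in freqs$loci) {
      f <- freqs$freq[[p]][[l]]
      m <- freqs$gene_copies[p, l]
      if (is.null(f) || m < min_copies) next
      hs <- c(hs, m / (m - 1) * (1 - sum(f^2)))
      ms <- c(ms, m)
    }
    data.frame(population = p,
               H = if (length(hs)) mean(hs) else NA_real_,
               n_loci_used = length(hs),
               mean_gene_copies = if (length(ms)) mean(ms) else NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# shared frame: frequencies of both populations over the union of alleles
pair_freq <- function(fx, fy) {
  alleles <- union(names(fx), names(fy))
  px <- stats::setNames(rep(0, length(alleles)), alleles)
  py <- px
  px[names(fx)] <- fx; py[names(fy)] <- fy
  list(px = px, py = py)
}

#' Nei's minimum genetic distance
#'
#' Per locus `D = (J_X + J_Y)/2 - J_XY` with `J_X = sum(p_X^2)`,
#' `J_XY = sum(p_X * p_Y)`, averaged over the loci with defined frequencies
#' in both populations (pairwise deletion). Invariant to allele relabelling.
#'
#' @param freqs an `allele_freq_table`.
#' @return a `genetic_dist`: list with `D` (symmetric matrix, zero diagonal),
#'   `loci_used` (pairwise counts), `measure = "nei_minimum"`. Pairs with no
#'   shared defined locus are `NA`.
#' @export
nei_minimum_distance <- function(freqs) {
  pairwise_distance(freqs, function(px, py) {
    (sum(px^2) + sum(py^2)) / 2 - sum(px * py)
  }, "nei_minimum")
}

#' Goldstein's (delta mu)^2 genetic distance
#'
#' Per locus `(mu_X - mu_Y)^2`, the squared difference of frequency-weighted
#' mean allele sizes, averaged over shared defined loci. Interprets allele
#' labels as additive sizes (repeat counts or base pairs), as appropriate
#' under stepwise mutation; unlike Nei's distance it is *not* invariant to
#' allele relabelling.
#'
#' @param freqs an `allele_freq_table` whose allele labels are numeric sizes.
#' @return a `genetic_dist` with `measure = "delta_mu_sq"`.
#' @export
delta_mu_squared <- function(freqs) {
  pairwise_distance(freqs, function(px, py) {
    sz <- suppressWarnings(as.numeric(names(px)))
    if (anyNA(sz)) stop("(delta mu)^2 requires numeric allele sizes")
    (sum(sz * px) - sum(sz * py))^2
  }, "delta_mu_sq")
}

pairwise_distance <- function(freqs, locus_fn, measure) {
  pops <- freqs$populations
  n <- length(pops)
  D <- matrix(0, n, n, dimnames = list(pops, pops))
  used <- matrix(0L, n, n, dimnames = list(pops, pops))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (j <= i) next
    vals <- c()
    for (l in freqs$loci) {
      fx <- freqs$freq[[pops[i]]][[l]]
      fy <- freqs$freq[[pops[j]]][[l]]
      if (is.null(fx) || is.null(fy)) next
      pf <- pair_freq(fx, fy)
      vals <- c(vals, locus_fn(pf$px, pf$py))
    }
    used[i, j] <- used[j, i] <- length(vals)
    D[i, j] <- D[j, i] <- if (length(vals)) mean(vals) else NA_real_
  }
  structure(list(D = D, loci_used = used, measure = measure),
            class = "genetic_dist")
}

#' @export
print.genetic_dist <- function(x, ...) {
  cat(sprintf("genetic_dist (%s): %d populations\n",
              x$measure, nrow(x$D)))
  invisible(x)
}

#' Correlation between two distance matrices
#'
#' Pearson correlation over the strict upper triangles (each unordered pair
#' counted once). The matrices must share the population set and order.
#'
#' @param d1,d2 `genetic_dist` objects or bare symmetric matrices.
#' @return Pearson `r`, or `NA` with a warning if either triangle is
#'   constant.
#' @export
matrix_correlation <- function(d1, d2) {
  m1 <- if (inherits(d1, "genetic_dist")) d1$D else d1
  m2 <- if (inherits(d2, "genetic_dist")) d2$D else d2
  if (!identical(dim(m1), dim(m2)))
    stop("distance matrices differ in dimension")
  if (!is.null(rownames(m1)) && !is.null(rownames(m2)) &&
      !identical(rownames(m1), rownames(m2)))
    stop("distance matrices differ in population order")
  ut <- upper.tri(m1)
  x <- m1[ut]; y <- m2[ut]
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("constant distance matrix: correlation undefined")
    return(NA_real_)
  }
  stats::cor(x, y)
}

#' Write a distance matrix as a PHYLIP-style square table
#'
#' @param d a `genetic_dist`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_phylip_distances <- function(d, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%5d", nrow(d$D)), con)
  for (i in seq_len(nrow(d$D)))
    writeLines(paste(c(sprintf("%-10s", rownames(d$D)[i]),
                       sprintf("%.6f", d$D[i, ])), collapse = " "), con)
  invisible(path)
}
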
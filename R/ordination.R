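#' PCA of scaled individual allele counts
#'
#' Expands the genotypes into an individual x (locus, allele) dosage matrix
#' (0/1/2 copies of each allele, rescaled to diploid dosage when one copy is
#' missing), mean-imputes fully missing entries per column, drops
#' zero-variance columns (count reported), column-centres and unit-scales,
#' and eigendecomposes the covariance. Each axis is oriented so that its
#' largest-magnitude loading is positive, for reproducible plots.
#'
#' @param g a \code{\link{genotype_matrix}}.
#' @param n_axes axes to keep (truncated to the matrix rank).
#' @param scale unit-variance scaling of columns (default TRUE).
#' @return an `ordination`: list with `scores` (individuals x axes),
#'   `eigenvalues` (all), `variance_fraction` (per kept axis),
#'   `loadings`, `n_dropped_columns`, `method = "pca"`.
#' @export
pca_genotypes <- function(g, n_axes = 10L, scale = TRUE) {
  N <- length(g$individual_ids)
  if (N < 2) stop("PCA needs at least two individuals")
  enc <- encode_genotypes(g)
  X <- matrix(NA_real_, N, enc$n_col)
  for (l in seq_len(enc$L)) {
    cols <- enc$col_offset[l] + seq_len(enc$n_alleles[l])
    cnt <- matrix(0, N, enc$n_alleles[l])
    obs <- rep(0L, N)
    for (cpy in 1:2) {
      ok <- which(!g$missing_mask[, l, cpy])
      a <- match(g$calls[ok, l, cpy], enc$allele_levels[[l]])
      cnt[cbind(ok, a)] <- cnt[cbind(ok, a)] + 1
      obs[ok] <- obs[ok] + 1L
    }
    some <- obs > 0L
    cnt[some, ] <- cnt[some, , drop = FALSE] * (2 / obs[some])
    cnt[!some, ] <- NA_real_
    X[, cols] <- cnt
  }
  # mean imputation per column, then drop constant columns
  cm <- colMeans(X, na.rm = TRUE)
  nas <- which(is.na(X), arr.ind = TRUE)
  if (nrow(nas)) X[nas] <- cm[nas[, 2]]
  v <- apply(X, 2, stats::var)
  keep <- v > 1e-12
  n_dropped <- sum(!keep)
  X <- X[, keep, drop = FALSE]
  X <- scale(X, center = TRUE, scale = scale)
  pc <- stats::prcomp(X, center = FALSE, scale. = FALSE)
  eig <- pc$sdev^2
  n_axes <- min(n_axes, sum(eig > 1e-12))
  scores <- pc$x[, seq_len(n_axes), drop = FALSE]
  loadings <- pc$rotation[, seq_len(n_axes), drop = FALSE]
  for (j in seq_len(n_axes)) {
    i_max <- which.max(abs(loadings[, j]))
    if (loadings[i_max, j] < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  rownames(scores) <- g$individual_ids
  structure(list(scores = scores, eigenvalues = eig,
                 variance_fraction = eig[seq_len(n_axes)] / sum(eig),
                 loadings = loadings, n_dropped_columns = n_dropped,
                 method = "pca"),
            class = "ordination")
}

#' Classical (Torgerson) multidimensional scaling
#'
#' Metric scaling of a distance matrix: double-centre `-D^2/2`,
#' eigendecompose, take coordinates along the top positive eigenvalues.
#' The mass of negative eigenvalues is reported as a diagnostic of how far
#' the distances are from Euclidean. Axes follow the same sign convention
#' as \code{\link{pca_genotypes}}.
#'
#' @param d a `genetic_dist` or bare symmetric zero-diagonal matrix.
#' @param n_axes coordinates to return; truncated (with a warning) to the
#'   number of positive eigenvalues.
#' @return an `ordination` with `method = "cmds"` and
#'   `negative_eigenvalue_mass`.
#' @export
classical_mds <- function(d, n_axes = 2L) {
  D <- if (inherits(d, "genetic_dist")) d$D else as.matrix(d)
  if (!isTRUE(all.equal(D, t(D), tolerance = 1e-8)))
    stop("distance matrix must be symmetric")
  if (any(abs(diag(D)) > 1e-12)) stop("distance matrix must have zero diagonal")
  mds <- stats::cmdscale(D, k = min(n_axes, nrow(D) - 1L), eig = TRUE)
  eig <- mds$eig
  n_pos <- sum(eig > 1e-9 * max(abs(eig)))
  if (n_axes > n_pos) {
    warning("n_axes exceeds positive eigenvalues; truncating to ", n_pos)
    n_axes <- n_pos
  }
  scores <- mds$points[, seq_len(n_axes), drop = FALSE]
  for (j in seq_len(ncol(scores))) {
    i_max <- which.max(abs(scores[, j]))
    if (scores[i_max, j] < 0) scores[, j] <- -scores[, j]
  }
  rownames(scores) <- rownames(D)
  pos_mass <- sum(eig[eig > 0])
  structure(list(scores = scores, eigenvalues = eig,
                 variance_fraction = eig[seq_len(n_axes)] / pos_mass,
                 negative_eigenvalue_mass = sum(abs(eig[eig < 0])) /
                   sum(abs(eig)),
                 method = "cmds"),
            class = "ordination")
}

#' @export
print.ordination <- function(x, ...) {
  cat(sprintf("ordination (%s): %d entities, %d axes; variance fractions: %s\n",
              x$method, nrow(x$scores), ncol(x$scores),
              paste(sprintf("%.3f", x$variance_fraction), collapse = ", ")))
  invisible(x)
}

#' Correlation of ordination axes with a covariate
#'
#' Pearson r of each requested axis score against a per-entity covariate,
#' optionally on a subset of the entities (e.g. only the populations of one
#' continent). A constant covariate on the subset is flagged `NA`.
#'
#' @param ord an `ordination`.
#' @param covariate named numeric vector (names matching score rownames) or
#'   an unnamed vector aligned to the rows.
#' @param axes integer axes (default all kept).
#' @param subset optional character vector of entity names, or logical mask.
#' @return named numeric vector of r per axis.
#' @export
axis_covariate_correlation <- function(ord, covariate,
                                       axes = seq_len(ncol(ord$scores)),
                                       subset = NULL) {
  sc <- ord$scores
  if (!is.null(names(covariate))) covariate <- covariate[rownames(sc)]
  if (length(covariate) != nrow(sc))
    stop("covariate must align with ordination entities")
  if (!is.null(subset)) {
    mask <- if (is.logical(subset)) subset else rownames(sc) %in% subset
    sc <- sc[mask, , drop = FALSE]; covariate <- covariate[mask]
  }
  if (stats::sd(covariate, na.rm = TRUE) == 0) {
    warning("constant covariate: correlations undefined")
    return(stats::setNames(rep(NA_real_, length(axes)),
                           paste0("axis", axes)))
  }
  out <- vapply(axes, function(j) stats::cor(sc[, j], covariate,
                                             use = "complete.obs"),
                numeric(1))
  stats::setNames(out, paste0("axis", axes))
}

#' Gene-language correspondence summary
#'
#' Quantifies how well language families track genetic distance: the
#' contrast between mean between-family and mean within-family distance
#' (positive when same-family populations are genetically closer), the rate
#' at which a population's nearest genetic neighbour speaks a language of
#' the same family (computed over populations with at least one same-family
#' partner), and a permutation p-value for the contrast obtained by
#' shuffling family labels, `p = (1 + #{perm >= obs}) / (n_perm + 1)`.
#'
#' @param d a `genetic_dist` or symmetric matrix.
#' @param families named character vector population -> family; populations
#'   labelled `NA` or `"NA"` are excluded.
#' @param n_perm label permutations (>= 999 recommended).
#' @param seed mandatory integer seed.
#' @return a `language_summary`: list with `families` (data.frame: family,
#'   n, within_mean), `within_mean`, `between_mean`, `contrast`,
#'   `nn_same_family_rate`, `p_perm`, `n_perm`, `seed`.
#' @export
gene_language_summary <- function(d, families, n_perm = 999L, seed) {
  if (missing(seed) || is.null(seed)) stop("seed is mandatory")
  D <- if (inherits(d, "genetic_dist")) d$D else as.matrix(d)
  keep <- names(families)[!is.na(families) & families != "NA"]
  keep <- intersect(rownames(D), keep)
  D <- D[keep, keep]
  fam <- as.character(families[keep])
  n <- length(keep)
  same <- outer(fam, fam, "==")
  ut <- upper.tri(D)
  stat <- function(same_mat) {
    w <- D[ut & same_mat]; b <- D[ut & !same_mat]
    if (!length(w) || !length(b)) return(NA_real_)
    mean(b) - mean(w)
  }
  contrast <- stat(same)
  # nearest-neighbour same-family rate over populations with a partner
  has_partner <- vapply(seq_len(n), function(i) sum(fam == fam[i]) > 1,
                        logical(1))
  nn_rate <- if (any(has_partner)) {
    hits <- vapply(which(has_partner), function(i) {
      dd <- D[i, ]; dd[i] <- Inf
      fam[which.min(dd)] == fam[i]
    }, logical(1))
    mean(hits)
  } else NA_real_
  p_perm <- NA_real_
  if (!is.na(contrast)) {
    set.seed(seed)
    hits <- 0L
    for (b in seq_len(n_perm)) {
      pf <- sample(fam)
      s <- stat(outer(pf, pf, "=="))
      if (!is.na(s) && s >= contrast) hits <- hits + 1L
    }
    p_perm <- (1 + hits) / (n_perm + 1)
  }
  fam_tab <- do.call(rbind, lapply(sort(unique(fam)), function(f) {
    idx <- fam == f
    within <- if (sum(idx) > 1) mean(D[idx, idx][upper.tri(D[idx, idx])])
              else NA_real_
    data.frame(family = f, n = sum(idx), within_mean = within,
               stringsAsFactors = FALSE)
  }))
  structure(list(families = fam_tab,
                 within_mean = if (any(same[ut])) mean(D[ut & same]) else NA_real_,
                 between_mean = mean(D[ut & !same]),
                 contrast = contrast,
                 nn_same_family_rate = nn_rate,
                 p_perm = p_perm, n_perm = n_perm, seed = seed),
            class = "language_summary")
}

#' @export
print.language_summary <- function(x, ...) {
  cat(sprintf("language_summary: %d families over %d populations\n",
              nrow(x$families), sum(x$families$n)))
  cat(sprintf("  between - within contrast = %.4g (perm p = %.3g)\n",
              x$contrast, x$p_perm))
  cat(sprintf("  nearest-neighbour same-family rate = %.3f\n",
              x$nn_same_family_rate))
  invisible(x)
}
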
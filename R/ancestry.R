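# Internal: flatten a genotype matrix into the observation vectors the EM
# core consumes. Alleles are recoded per locus to 0-based indices into a
# global column space (one contiguous block per locus).
encode_genotypes <- function(g) {
  N <- length(g$individual_ids); L <- length(g$loci)
  allele_levels <- vector("list", L)
  for (l in seq_len(L)) {
    a <- c(g$calls[, l, 1], g$calls[, l, 2])
    m <- c(g$missing_mask[, l, 1], g$missing_mask[, l, 2])
    lev <- sort(unique(a[!m]))
    if (!length(lev))
      stop("locus ", g$loci[l], " has no observed gene copies")
    allele_levels[[l]] <- lev
  }
  n_alleles <- lengths(allele_levels)
  col_offset <- c(0L, cumsum(n_alleles))[seq_len(L)]
  ind <- integer(0); loc <- integer(0); col <- integer(0)
  for (cpy in 1:2) {
    for (l in seq_len(L)) {
      ok <- which(!g$missing_mask[, l, cpy])
      a <- match(g$calls[ok, l, cpy], allele_levels[[l]]) - 1L
      ind <- c(ind, ok - 1L)
      loc <- c(loc, rep(l - 1L, length(ok)))
      col <- c(col, col_offset[l] + a)
    }
  }
  list(ind = ind, loc = loc, col = col, N = N, L = L,
       n_alleles = as.integer(n_alleles), col_offset = as.integer(col_offset),
       n_col = sum(n_alleles), allele_levels = allele_levels)
}

# pooled allele frequencies in the EM's global column space
pooled_frequencies <- function(enc) {
  f <- numeric(enc$n_col)
  tab <- tabulate(enc$col + 1L, nbins = enc$n_col)
  for (l in seq_len(enc$L)) {
    idx <- enc$col_offset[l] + seq_len(enc$n_alleles[l])
    f[idx] <- tab[idx] / sum(tab[idx])
  }
  f
}

#' Maximum-likelihood admixture proportion estimation
#'
#' Fits the unsupervised admixture model for multi-allelic loci by EM: each
#' gene copy of individual `i` at locus `l` is drawn from cluster `k` with
#' probability `q_ik` and then carries allele `a` with probability
#' `p_kla`, so `log L = sum over observed copies of log sum_k q_ik p_kla`.
#' Missing gene copies contribute nothing. Both `Q` and the per-locus
#' frequency blocks of `P` remain row-stochastic at every iteration and the
#' log-likelihood is non-decreasing (an EM fixed point). Multiple random
#' starts are run and the best kept.
#'
#' @param g a \code{\link{genotype_matrix}}.
#' @param K number of ancestral clusters, `1 <= K <= N`.
#' @param seed integer seed for the random starts.
#' @param tol relative log-likelihood convergence tolerance.
#' @param max_iter maximum EM iterations per start.
#' @param n_starts random restarts; the best final log-likelihood wins.
#' @param freq_floor lower bound on cluster allele frequencies, guarding
#'   `log(0)` on private alleles.
#' @return an `ancestry_fit`: list with `K`, `Q` (N x K, rows sum to 1,
#'   rownames are individual ids), `P` (K x total allele columns with a
#'   `locus_of` attribute), `loglik`, `loglik_trace` (of the winning start),
#'   `n_iter`, `converged`, `seed`.
#' @export
fit_admixture <- function(g, K, seed = 1L, tol = 1e-6, max_iter = 2000L,
                          n_starts = 5L, freq_floor = 1e-9) {
  N <- length(g$individual_ids)
  if (K < 1) stop("K must be >= 1")
  if (K > N) stop("K exceeds the number of individuals")
  enc <- encode_genotypes(g)
  pooled <- pooled_frequencies(enc)
  set.seed(seed)
  best <- NULL
  for (s in seq_len(n_starts)) {
    gam <- matrix(stats::rgamma(N * K, shape = 1), N, K)
    Q0 <- gam / rowSums(gam)
    P0 <- matrix(rep(pooled, each = K), K, enc$n_col) *
      matrix(stats::runif(K * enc$n_col, 0.7, 1.3), K, enc$n_col)
    for (l in seq_len(enc$L)) {
      idx <- enc$col_offset[l] + seq_len(enc$n_alleles[l])
      P0[, idx] <- P0[, idx, drop = FALSE] /
        rowSums(P0[, idx, drop = FALSE])
    }
    fit <- admixture_em_cpp(enc$ind, enc$col, enc$loc, N, enc$n_col, enc$L,
                            enc$col_offset, enc$n_alleles, Q0, P0,
                            as.integer(max_iter), tol, freq_floor)
    if (!is.finite(fit$loglik)) stop("non-finite likelihood during EM")
    if (is.null(best) || fit$loglik > best$loglik) best <- fit
  }
  rownames(best$Q) <- g$individual_ids
  locus_of <- rep(g$loci, enc$n_alleles)
  colnames(best$P) <- paste0(locus_of, ".",
                             unlist(lapply(enc$allele_levels, as.character)))
  attr(best$P, "locus_of") <- locus_of
  structure(list(K = as.integer(K), Q = best$Q, P = best$P,
                 loglik = best$loglik, loglik_trace = best$loglik_trace,
                 n_iter = best$n_iter, converged = best$converged,
                 seed = seed),
            class = "ancestry_fit")
}

#' @export
print.ancestry_fit <- function(x, ...) {
  cat(sprintf("ancestry_fit: K = %d, %d individuals, loglik = %.2f (%d EM iterations%s)\n",
              x$K, nrow(x$Q), x$loglik, x$n_iter,
              if (x$converged) "" else ", not converged"))
  invisible(x)
}

#' Replicated admixture fits across a range of K
#'
#' Runs \code{\link{fit_admixture}} `n_runs` times (distinct seeds) at every
#' `K` in a contiguous range, collecting the per-run log-likelihoods that
#' feed \code{\link{delta_k}}.
#'
#' @param g a `genotype_matrix`.
#' @param K_values contiguous increasing integer vector.
#' @param n_runs replicate runs per K (>= 3 for delta-K).
#' @param seed master seed; run seeds are derived from it.
#' @param ... passed to `fit_admixture` (e.g. `n_starts`, `tol`).
#' @return a `run_series`: list with `K_values`, `runs` (list per K of
#'   `ancestry_fit`s), `loglik` (n_runs x n_K matrix), `seed`.
#' @export
run_admixture_series <- function(g, K_values, n_runs = 3L, seed = 1L, ...) {
  if (any(diff(K_values) != 1L)) stop("K_values must be contiguous")
  runs <- vector("list", length(K_values))
  names(runs) <- paste0("K", K_values)
  ll <- matrix(NA_real_, n_runs, length(K_values),
               dimnames = list(NULL, paste0("K", K_values)))
  for (ki in seq_along(K_values)) {
    runs[[ki]] <- vector("list", n_runs)
    for (r in seq_len(n_runs)) {
      fit <- fit_admixture(g, K_values[ki],
                           seed = seed + 1000L * ki + r, ...)
      runs[[ki]][[r]] <- fit
      ll[r, ki] <- fit$loglik
    }
  }
  structure(list(K_values = as.integer(K_values), runs = runs,
                 loglik = ll, seed = seed),
            class = "run_series")
}

#' Align cluster labels across replicate runs
#'
#' Cluster labels are arbitrary, so replicate runs must be permuted onto a
#' common labelling before averaging (the label-switching problem). Each
#' run's columns are matched to the reference greedily by the dot product of
#' `Q` columns: the globally best (reference, run) column pair is fixed
#' first, then the next best among the remainder, and so on. When a run has
#' one more cluster than the reference the unmatched column keeps its slot at
#' the end, which supports tracking clusters across consecutive K.
#'
#' @param results list of `ancestry_fit`s sharing the individual set.
#' @param reference an `ancestry_fit` to align to; default the first result.
#' @return the list with `Q` columns (and `P` rows) permuted; each fit gains
#'   a `permutation` element (new label -> original label).
#' @export
align_runs <- function(results, reference = results[[1]]) {
  lapply(results, function(fit) {
    if (nrow(fit$Q) != nrow(reference$Q))
      stop("runs disagree on the number of individuals")
    if (abs(fit$K - reference$K) > 1L)
      stop("alignment supports K differing by at most 1")
    Kr <- reference$K; Kf <- fit$K
    S <- crossprod(reference$Q, fit$Q)  # Kr x Kf similarity
    perm <- integer(Kf)
    used_r <- rep(FALSE, Kr); used_f <- rep(FALSE, Kf)
    for (step in seq_len(min(Kr, Kf))) {
      S_mask <- S
      S_mask[used_r, ] <- -Inf
      S_mask[, used_f] <- -Inf
      ij <- arrayInd(which.max(S_mask), dim(S))
      perm[ij[1]] <- ij[2]
      used_r[ij[1]] <- TRUE; used_f[ij[2]] <- TRUE
    }
    if (Kf > Kr) perm[(Kr + 1):Kf] <- which(!used_f)
    perm <- perm[perm > 0]
    fit$Q <- fit$Q[, perm, drop = FALSE]
    fit$P <- fit$P[perm, , drop = FALSE]
    fit$permutation <- perm
    fit
  })
}

#' Evanno delta-K table
#'
#' For a contiguous K range with replicated runs, computes per K the first
#' difference of the mean log-likelihood `L'(K)`, the absolute second
#' difference `|L''(K)| = |mean L(K+1) - 2 mean L(K) + mean L(K-1)|`, and
#' `delta_K = |L''(K)| / sd(L(K))` over runs. Endpoints, and any K whose
#' across-run standard deviation is zero, are flagged `NA` rather than
#' infinite.
#'
#' @param series a `run_series` from \code{\link{run_admixture_series}}, or
#'   a matrix of log-likelihoods (runs x K) with `K` values as an attribute
#'   or taken from `K_values`.
#' @param K_values optional K values when `series` is a bare matrix.
#' @return data.frame: `K`, `mean_L`, `sd_L`, `Lp`, `Lpp_abs`, `delta_K`.
#' @export
delta_k <- function(series, K_values = NULL) {
  if (inherits(series, "run_series")) {
    ll <- series$loglik; K_values <- series$K_values
  } else {
    ll <- as.matrix(series)
    if (is.null(K_values)) stop("K_values required for a bare matrix")
  }
  if (nrow(ll) < 3L) stop("delta-K needs >= 3 replicate runs per K")
  if (any(diff(K_values) != 1L)) stop("K range must be contiguous")
  nK <- length(K_values)
  mean_L <- colMeans(ll); sd_L <- apply(ll, 2, stats::sd)
  Lp <- c(NA, diff(mean_L))
  Lpp <- rep(NA_real_, nK)
  dK <- rep(NA_real_, nK)
  for (i in seq_len(nK)) {
    if (i == 1L || i == nK) next
    Lpp[i] <- abs(mean_L[i + 1] - 2 * mean_L[i] + mean_L[i - 1])
    if (sd_L[i] > 0) dK[i] <- Lpp[i] / sd_L[i]
  }
  data.frame(K = K_values, mean_L = mean_L, sd_L = sd_L,
             Lp = Lp, Lpp_abs = Lpp, delta_K = dK, row.names = NULL)
}

#' Population-mean ancestry proportions
#'
#' @param fit an `ancestry_fit` (align replicate runs first if averaging).
#' @param grouping named character vector individual id -> population.
#' @return matrix population x cluster of mean `Q`; rows sum to 1.
#' @export
ancestry_by_population <- function(fit, grouping) {
  ids <- rownames(fit$Q)
  miss <- setdiff(ids, names(grouping))
  if (length(miss))
    stop("individuals without a population: ", paste(miss, collapse = ", "))
  gr <- grouping[ids]
  pops <- unique(gr)
  out <- t(vapply(pops, function(p)
    colMeans(fit$Q[gr == p, , drop = FALSE]), numeric(fit$K)))
  rownames(out) <- pops
  out
}

#' Annotate clusters by their dominant continental group
#'
#' A cluster is labeled with a source group when that group's mean membership
#' in the cluster exceeds `threshold`; ties are broken by the larger group
#' sample size. Clusters with no dominant group are labeled `"unassigned"`,
#' never dropped.
#'
#' @param fit an `ancestry_fit`.
#' @param grouping named character vector individual id -> population.
#' @param source_groups named list: annotation label -> character vector of
#'   population names regarded as that source (e.g.
#'   `list(AFR = "AFR", EUR = "EUR", EAS = "EAS")`).
#' @param threshold dominance threshold on mean membership.
#' @return character vector of length `K`: annotation per cluster.
#' @export
annotate_clusters <- function(fit, grouping, source_groups, threshold = 0.5) {
  ids <- rownames(fit$Q)
  gr <- grouping[ids]
  ann <- rep("unassigned", fit$K)
  for (k in seq_len(fit$K)) {
    means <- vapply(source_groups, function(pops) {
      sel <- gr %in% pops
      if (!any(sel)) return(NA_real_)
      mean(fit$Q[sel, k])
    }, numeric(1))
    sizes <- vapply(source_groups, function(pops) sum(gr %in% pops), numeric(1))
    ok <- which(!is.na(means) & means > threshold)
    if (length(ok)) {
      top <- ok[order(-means[ok], -sizes[ok])][1]
      ann[k] <- names(source_groups)[top]
    }
  }
  ann
}

#' Combined non-native ancestry per population
#'
#' Sums the population-mean memberships of every cluster annotated to a
#' source group (i.e. not `native_label` and not `"unassigned"` unless
#' requested), giving the single covariate used by the partial-correlation
#' analysis.
#'
#' @param pop_q population x cluster matrix from
#'   \code{\link{ancestry_by_population}}.
#' @param annotation cluster annotation from \code{\link{annotate_clusters}}.
#' @param source_labels annotations counted as non-native; defaults to every
#'   label other than `"unassigned"`.
#' @return named numeric vector per population.
#' @export
non_native_ancestry <- function(pop_q, annotation,
                                source_labels = setdiff(unique(annotation),
                                                        "unassigned")) {
  sel <- annotation %in% source_labels
  if (!any(sel)) return(stats::setNames(rep(0, nrow(pop_q)), rownames(pop_q)))
  rowSums(pop_q[, sel, drop = FALSE])
}

#' Ancestry-versus-K sensitivity curves
#'
#' For each K in a run series: aligns the replicate runs, averages `Q`,
#' aggregates to population means, annotates clusters by their dominant
#' continental group, and sums memberships per annotation. The result traces
#' how each annotated ancestry component in each population responds to the
#' choice of K.
#'
#' @param series a `run_series`.
#' @param grouping named character vector individual id -> population.
#' @param source_groups as in \code{\link{annotate_clusters}}.
#' @param threshold annotation dominance threshold.
#' @return long data.frame: `population`, `K`, `component`, `ancestry`.
#' @export
k_sensitivity <- function(series, grouping, source_groups, threshold = 0.5) {
  out <- list()
  for (ki in seq_along(series$K_values)) {
    K <- series$K_values[ki]
    aligned <- align_runs(series$runs[[ki]])
    Qbar <- Reduce(`+`, lapply(aligned, `[[`, "Q")) / length(aligned)
    fit <- aligned[[1]]; fit$Q <- Qbar
    ann <- annotate_clusters(fit, grouping, source_groups, threshold)
    pop_q <- ancestry_by_population(fit, grouping)
    for (comp in unique(c(ann, "unassigned"))) {
      sel <- ann == comp
      if (!any(sel)) next
      val <- rowSums(pop_q[, sel, drop = FALSE])
      out[[length(out) + 1L]] <- data.frame(
        population = rownames(pop_q), K = K, component = comp,
        ancestry = as.numeric(val), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
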
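# Shared fixture builders. Everything is generated in code at test time.

# small genotype matrix from an N x L matrix of "a/b" strings, e.g. "10/12";
# "./." marks a fully missing genotype, "10/." one missing copy
geno_from_strings <- function(m, pops) {
  N <- nrow(m); L <- ncol(m)
  calls <- array(NA_integer_, c(N, L, 2))
  for (i in seq_len(N)) for (l in seq_len(L)) {
    ab <- strsplit(m[i, l], "/", fixed = TRUE)[[1]]
    for (cpy in 1:2)
      if (ab[cpy] != ".") calls[i, l, cpy] <- as.integer(ab[cpy])
  }
  ids <- paste0("ind", seq_len(N))
  genotype_matrix(calls, ids, stats::setNames(pops, ids))
}

# random diploid fixture with optional missingness
random_geno <- function(N, L, n_pops = 2, alleles = 8:14, miss = 0,
                        seed = 1) {
  set.seed(seed)
  calls <- array(sample(alleles, N * L * 2, replace = TRUE), c(N, L, 2))
  if (miss > 0) {
    mask <- array(runif(N * L * 2) < miss, c(N, L, 2))
    calls[mask] <- NA_integer_
  }
  ids <- paste0("ind", seq_len(N))
  pops <- stats::setNames(rep(paste0("pop", seq_len(n_pops)), length.out = N),
                          ids)
  genotype_matrix(calls, ids, pops)
}

# all permutations of 1:n (tiny n only), for exhaustive alignment oracles
all_perms <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (p in all_perms(n - 1L)) for (pos in seq_len(n)) {
    out[[length(out) + 1L]] <- append(p, n, after = pos - 1L)
  }
  out
}

# brute-force per-locus recomputation of unbiased gene diversity from raw
# genotypes, independent of allele_frequencies()
gene_diversity_oracle <- function(g, pop) {
  rows <- which(populations(g) == pop)
  hs <- c()
  for (l in seq_along(g$loci)) {
    a <- c(g$calls[rows, l, 1], g$calls[rows, l, 2])
    m <- c(g$missing_mask[rows, l, 1], g$missing_mask[rows, l, 2])
    a <- a[!m]
    if (length(a) < 2) next
    p <- as.numeric(table(a)) / length(a)
    hs <- c(hs, length(a) / (length(a) - 1) * (1 - sum(p^2)))
  }
  mean(hs)
}

# independent dosage-matrix builder for PCA oracles (no-missing fixtures)
dosage_oracle <- function(g) {
  N <- length(g$individual_ids)
  cols <- list()
  for (l in seq_along(g$loci)) {
    alle <- sort(unique(c(g$calls[, l, ])))
    for (a in alle)
      cols[[length(cols) + 1L]] <- (g$calls[, l, 1] == a) +
                                   (g$calls[, l, 2] == a)
  }
  do.call(cbind, cols)
}

# independent per-allele tally of frequencies, the brute-force oracle for
# allele_frequencies()
tally_oracle <- function(g, pop, locus_index) {
  rows <- which(populations(g) == pop)
  a <- c(g$calls[rows, locus_index, 1], g$calls[rows, locus_index, 2])
  m <- c(g$missing_mask[rows, locus_index, 1],
         g$missing_mask[rows, locus_index, 2])
  a <- a[!m]
  if (!length(a)) return(NULL)
  tab <- table(a)
  stats::setNames(as.numeric(tab) / length(a), names(tab))
}
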
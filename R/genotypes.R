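#' Construct a diploid microsatellite genotype matrix
#'
#' The central data container: integer allele sizes for `N` individuals at
#' `L` loci, two gene copies each, with a per-gene-copy missingness mask.
#' Allele sizes may be repeat counts or base-pair sizes; they are stored as
#' given and only interpreted additively by size-based statistics such as
#' \code{\link{delta_mu_squared}}.
#'
#' @param calls integer array `N x L x 2` of allele sizes. Entries under the
#'   mask are ignored (conventionally `NA`).
#' @param individual_ids character vector of length `N`, unique.
#' @param population_of named character vector mapping every individual id to
#'   a population name.
#' @param loci character vector of `L` locus names (defaults to `L1..LL`).
#' @param missing_mask logical array `N x L x 2`; `TRUE` marks a missing gene
#'   copy. Defaults to `is.na(calls)`. Each gene copy is masked
#'   independently: a heterozygote with one unreadable allele still
#'   contributes its observed copy.
#' @return an object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(calls, individual_ids, population_of,
                            loci = NULL, missing_mask = NULL) {
  if (length(dim(calls)) != 3L || dim(calls)[3] != 2L)
    stop("`calls` must be an N x L x 2 array")
  N <- dim(calls)[1]; L <- dim(calls)[2]
  if (length(individual_ids) != N)
    stop("length(individual_ids) must equal nrow(calls)")
  if (anyDuplicated(individual_ids))
    stop("duplicate individual ids: ",
         paste(unique(individual_ids[duplicated(individual_ids)]), collapse = ", "))
  if (is.null(loci)) loci <- paste0("L", seq_len(L))
  if (length(loci) != L) stop("length(loci) must equal ncol(calls)")
  if (is.null(missing_mask)) missing_mask <- is.na(calls)
  if (!identical(dim(missing_mask), dim(calls)))
    stop("missing_mask must match calls in shape")
  missing <- setdiff(individual_ids, names(population_of))
  if (length(missing))
    stop("individuals without a population: ", paste(missing, collapse = ", "))
  population_of <- population_of[individual_ids]
  storage.mode(calls) <- "integer"
  observed <- calls[!missing_mask]
  if (any(!is.na(observed) & observed <= 0L))
    stop("observed allele sizes must be positive integers")
  if (anyNA(observed))
    stop("NA call outside the missing mask")
  obj <- list(calls = calls,
              individual_ids = as.character(individual_ids),
              population_of = stats::setNames(as.character(population_of),
                                              individual_ids),
              loci = as.character(loci),
              missing_mask = missing_mask)
  class(obj) <- "genotype_matrix"
  obj
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d individuals x %d loci (%d populations), %.1f%% missing gene copies\n",
              length(x$individual_ids), length(x$loci),
              length(unique(x$population_of)), 100 * mean(x$missing_mask)))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$calls)

#' Population labels of a genotype matrix
#' @param g a `genotype_matrix`.
#' @return named character vector, individual id -> population.
#' @export
populations <- function(g) g$population_of

#' Read STRUCTURE-format genotype text
#'
#' Whitespace-delimited text with the individual id in column 1 and the
#' population label in column 2, followed by allele columns. Two dialects are
#' auto-detected from how often each individual id occurs: two rows per
#' individual with `L` allele columns each (dialect `"two_row"`), or one row
#' per individual with `2L` interleaved allele columns (dialect `"one_row"`).
#'
#' @param path file path.
#' @param missing_code integer sentinel for a missing gene copy (STRUCTURE
#'   convention `-9`).
#' @param loci optional locus names; defaults to `L1..LL`.
#' @return a `genotype_matrix`; the detected dialect is stored in
#'   `attr(, "dialect")`.
#' @export
read_structure <- function(path, missing_code = -9L, loci = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty genotype file: ", path)
  tok <- strsplit(trimws(lines), "[[:space:]]+")
  nfield <- lengths(tok)
  if (length(unique(nfield)) != 1L)
    stop(sprintf("ragged rows: line %d has %d fields, expected %d",
                 which(nfield != nfield[1])[1], nfield[which(nfield != nfield[1])[1]],
                 nfield[1]))
  ids_raw <- vapply(tok, `[`, "", 1L)
  pops_raw <- vapply(tok, `[`, "", 2L)
  n_allele_cols <- nfield[1] - 2L
  if (n_allele_cols < 1L) stop("no allele columns found")
  counts <- table(ids_raw)
  if (all(counts == 2L)) {
    dialect <- "two_row"
    L <- n_allele_cols
    ids <- unique(ids_raw)
    N <- length(ids)
    calls <- array(NA_integer_, c(N, L, 2))
    pop_of <- character(N); names(pop_of) <- ids
    for (i in seq_len(N)) {
      rows <- which(ids_raw == ids[i])
      pop_of[i] <- pops_raw[rows[1]]
      for (cpy in 1:2) {
        v <- suppressWarnings(as.integer(tok[[rows[cpy]]][-(1:2)]))
        if (anyNA(v)) stop("non-integer allele entry for individual ", ids[i])
        calls[i, , cpy] <- v
      }
    }
  } else if (all(counts == 1L)) {
    dialect <- "one_row"
    if (n_allele_cols %% 2L != 0L)
      stop("individual ", ids_raw[1],
           ": odd number of allele entries in one-row dialect")
    L <- n_allele_cols %/% 2L
    ids <- ids_raw
    N <- length(ids)
    calls <- array(NA_integer_, c(N, L, 2))
    pop_of <- stats::setNames(pops_raw, ids)
    for (i in seq_len(N)) {
      v <- suppressWarnings(as.integer(tok[[i]][-(1:2)]))
      if (anyNA(v)) stop("non-integer allele entry for individual ", ids[i])
      calls[i, , 1] <- v[seq(1, 2 * L, by = 2)]
      calls[i, , 2] <- v[seq(2, 2 * L, by = 2)]
    }
  } else {
    stop("inconsistent rows per individual: ids must occur once (one-row) or twice (two-row)")
  }
  mask <- calls == missing_code
  calls[mask] <- NA_integer_
  g <- genotype_matrix(calls, ids, pop_of, loci = loci, missing_mask = mask)
  attr(g, "dialect") <- dialect
  g
}

#' Write STRUCTURE-format genotype text
#'
#' @param g a `genotype_matrix`.
#' @param path output file path.
#' @param dialect `"two_row"` or `"one_row"` (see \code{\link{read_structure}}).
#' @param missing_code integer sentinel written for masked gene copies.
#' @return `path`, invisibly.
#' @export
write_structure <- function(g, path, dialect = c("two_row", "one_row"),
                            missing_code = -9L) {
  dialect <- match.arg(dialect)
  calls <- g$calls
  calls[g$missing_mask] <- missing_code
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(g$individual_ids)) {
    id <- g$individual_ids[i]; pop <- g$population_of[i]
    if (dialect == "two_row") {
      for (cpy in 1:2)
        writeLines(paste(c(id, pop, calls[i, , cpy]), collapse = " "), con)
    } else {
      inter <- as.vector(rbind(calls[i, , 1], calls[i, , 2]))
      writeLines(paste(c(id, pop, inter), collapse = " "), con)
    }
  }
  invisible(path)
}

#' Subset a genotype matrix
#'
#' @param g a `genotype_matrix`.
#' @param individuals character vector of individual ids to keep, or NULL.
#' @param keep_populations character vector of populations to keep, or NULL.
#' @return a `genotype_matrix` restricted to the selected individuals.
#' @export
subset_genotypes <- function(g, individuals = NULL, keep_populations = NULL) {
  keep <- g$individual_ids
  if (!is.null(individuals)) keep <- intersect(keep, individuals)
  if (!is.null(keep_populations))
    keep <- keep[g$population_of[keep] %in% keep_populations]
  idx <- match(keep, g$individual_ids)
  if (!length(idx)) stop("no individuals left after subsetting")
  genotype_matrix(g$calls[idx, , , drop = FALSE], keep,
                  g$population_of[keep], g$loci,
                  g$missing_mask[idx, , , drop = FALSE])
}

#' Read a population metadata table
#'
#' CSV with columns `population, region, language_family, latitude,
#' longitude` (extra columns are kept). Coordinates are validated;
#' `language_family` may be `"NA"` for populations outside the scope of the
#' language analysis.
#'
#' @param path CSV file path.
#' @param aliases optional named character vector mapping spelling variants
#'   to canonical population names (e.g. `c("Surui" = "Suruí")`).
#' @return a `data.frame` with one row per population.
#' @export
read_population_metadata <- function(path, aliases = NULL) {
  meta <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  needed <- c("population", "region", "language_family", "latitude", "longitude")
  miss <- setdiff(needed, names(meta))
  if (length(miss)) stop("metadata missing columns: ", paste(miss, collapse = ", "))
  if (!is.null(aliases)) {
    hit <- meta$population %in% names(aliases)
    meta$population[hit] <- aliases[meta$population[hit]]
  }
  if (anyDuplicated(meta$population))
    stop("duplicate population rows in metadata")
  if (any(meta$latitude < -90 | meta$latitude > 90, na.rm = TRUE))
    stop("latitude out of [-90, 90]")
  if (any(meta$longitude <= -180 | meta$longitude > 180, na.rm = TRUE))
    stop("longitude out of (-180, 180]")
  meta
}

#' Per-population allele frequencies
#'
#' Relative allele frequencies per (population, locus) computed from
#' non-missing gene copies only, with the number of observed gene copies
#' recorded. A (population, locus) cell with zero observed copies is flagged
#' undefined (`NULL` frequencies, `gene_copies = 0`), never zero-filled.
#'
#' @param g a `genotype_matrix`.
#' @param grouping named character vector individual id -> group; defaults to
#'   the matrix's own populations.
#' @return an `allele_freq_table`: list with `freq[[pop]][[locus]]` (named
#'   numeric vectors, names are allele sizes), `gene_copies` (pop x locus
#'   integer matrix), `populations`, `loci`.
#' @export
allele_frequencies <- function(g, grouping = populations(g)) {
  miss <- setdiff(g$individual_ids, names(grouping))
  if (length(miss))
    stop("grouping does not cover individuals: ", paste(miss, collapse = ", "))
  grouping <- grouping[g$individual_ids]
  pops <- unique(grouping)
  L <- length(g$loci)
  copies <- matrix(0L, length(pops), L, dimnames = list(pops, g$loci))
  freq <- vector("list", length(pops)); names(freq) <- pops
  for (p in pops) {
    rows <- which(grouping == p)
    fl <- vector("list", L); names(fl) <- g$loci
    for (l in seq_len(L)) {
      a <- c(g$calls[rows, l, 1], g$calls[rows, l, 2])
      m <- c(g$missing_mask[rows, l, 1], g$missing_mask[rows, l, 2])
      a <- a[!m]
      copies[p, l] <- length(a)
      if (length(a)) {
        tab <- table(a)
        fl[[l]] <- stats::setNames(as.numeric(tab) / length(a), names(tab))
      } else fl[[l]] <- NULL
    }
    freq[[p]] <- fl
  }
  structure(list(freq = freq, gene_copies = copies,
                 populations = pops, loci = g$loci),
            class = "allele_freq_table")
}

#' @export
print.allele_freq_table <- function(x, ...) {
  cat(sprintf("allele_freq_table: %d populations x %d loci\n",
              length(x$populations), length(x$loci)))
  invisible(x)
}

#' Export an allele-frequency table as long-format CSV
#'
#' @param freqs an `allele_freq_table`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_allele_frequencies <- function(freqs, path) {
  rows <- list()
  for (p in freqs$populations) for (l in freqs$loci) {
    f <- freqs$freq[[p]][[l]]
    if (is.null(f)) next
    rows[[length(rows) + 1L]] <- data.frame(
      population = p, locus = l, allele = as.integer(names(f)),
      frequency = as.numeric(f),
      gene_copies = freqs$gene_copies[p, l])
  }
  out <- do.call(rbind, rows)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
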
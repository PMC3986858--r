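#' Diploid microsatellite genotype table
#'
#' The central container of the package: diploid genotypes (allele sizes in
#' base pairs) for a set of individuals at a set of microsatellite loci,
#' together with a population label per individual. Missing calls are `NA`
#' in both allele slots; a call is either fully observed (two alleles) or
#' fully missing.
#'
#' @param individuals character vector of unique individual IDs.
#' @param populations character vector of population labels, one per
#'   individual; must be non-empty strings.
#' @param loci character vector of locus names.
#' @param allele1,allele2 integer matrices (`n_individuals x n_loci`) of
#'   allele sizes in base pairs; `NA` for missing calls. Within a call the
#'   pair is unordered; the constructor stores `pmin`/`pmax` so equal tables
#'   compare equal regardless of input slot order.
#'
#' @return An object of class `genotype_table`: a list with elements
#'   `individuals`, `populations`, `loci`, `allele1`, `allele2`.
#' @export
genotype_table <- function(individuals, populations, loci, allele1, allele2) {
  individuals <- as.character(individuals)
  populations <- as.character(populations)
  loci <- as.character(loci)
  allele1 <- as.matrix(allele1)
  allele2 <- as.matrix(allele2)
  storage.mode(allele1) <- "integer"
  storage.mode(allele2) <- "integer"
  n <- length(individuals)
  L <- length(loci)
  if (length(populations) != n)
    stop("populations must have one label per individual")
  if (any(!nzchar(populations)) || anyNA(populations))
    stop("population labels must be non-empty")
  if (!all(dim(allele1) == c(n, L)) || !all(dim(allele2) == c(n, L)))
    stop("allele matrices must be n_individuals x n_loci")
  half <- is.na(allele1) != is.na(allele2)
  if (any(half))
    stop("half-missing calls found: a call must have exactly 2 alleles or be missing")
  if (any(allele1 <= 0, na.rm = TRUE) || any(allele2 <= 0, na.rm = TRUE))
    stop("allele sizes must be positive")
  a1 <- pmin(allele1, allele2)
  a2 <- pmax(allele1, allele2)
  dimnames(a1) <- dimnames(a2) <- list(individuals, loci)
  structure(
    list(individuals = individuals, populations = populations, loci = loci,
         allele1 = a1, allele2 = a2),
    class = "genotype_table")
}

#' @export
print.genotype_table <- function(x, ...) {
  cat(sprintf("<genotype_table> %d individuals x %d loci, %d populations\n",
              length(x$individuals), length(x$loci),
              length(unique(x$populations))))
  miss <- mean(is.na(x$allele1))
  cat(sprintf("  missing calls: %.1f%%\n", 100 * miss))
  invisible(x)
}

#' Number of individuals / loci in a genotype table
#' @param table a [genotype_table()].
#' @return integer count.
#' @export
n_individuals <- function(table) length(table$individuals)

#' @rdname n_individuals
#' @export
n_loci <- function(table) length(table$loci)

#' Subset a genotype table by individuals
#' @param table a [genotype_table()].
#' @param idx integer or logical index over individuals.
#' @return a [genotype_table()] restricted to `idx`.
#' @export
subset_individuals <- function(table, idx) {
  genotype_table(table$individuals[idx], table$populations[idx], table$loci,
                 table$allele1[idx, , drop = FALSE],
                 table$allele2[idx, , drop = FALSE])
}

#' Concatenate genotype tables sharing the same loci
#' @param ... genotype tables with identical `loci`.
#' @return a single [genotype_table()].
#' @export
bind_tables <- function(...) {
  tabs <- list(...)
  if (length(tabs) == 1 && is.list(tabs[[1]]) && !inherits(tabs[[1]], "genotype_table"))
    tabs <- tabs[[1]]
  loci <- tabs[[1]]$loci
  for (t in tabs) if (!identical(t$loci, loci)) stop("loci sets differ")
  ids <- unlist(lapply(tabs, `[[`, "individuals"))
  if (anyDuplicated(ids)) ids <- make.unique(ids, sep = "_")
  genotype_table(
    ids,
    unlist(lapply(tabs, `[[`, "populations")),
    loci,
    do.call(rbind, lapply(tabs, `[[`, "allele1")),
    do.call(rbind, lapply(tabs, `[[`, "allele2")))
}

#' Allele frequency spectrum
#'
#' A per-locus map from allele size to relative frequency for one group of
#' gene copies (a population or a species pool). Loci where every call is
#' missing are flagged and carried as `NULL` entries so downstream code can
#' exclude them.
#'
#' @param freqs named list (one element per locus) of named numeric vectors;
#'   names are allele sizes, values are frequencies summing to 1. A `NULL`
#'   element marks a locus with no data in this group.
#' @param n_genes integer vector of gene-copy counts per locus (denominators).
#' @return An object of class `afs`.
#' @export
afs <- function(freqs, n_genes = NULL) {
  for (l in names(freqs)) {
    f <- freqs[[l]]
    if (is.null(f)) next
    if (any(f < 0)) stop("negative frequency at locus ", l)
    if (abs(sum(f) - 1) > 1e-9)
      stop("frequencies at locus ", l, " sum to ", sum(f), ", not 1")
  }
  structure(list(freqs = freqs, n_genes = n_genes), class = "afs")
}

#' @export
print.afs <- function(x, ...) {
  k <- vapply(x$freqs, function(f) if (is.null(f)) 0L else length(f), 0L)
  cat(sprintf("<afs> %d loci, %d-%d alleles per locus\n",
              length(x$freqs), min(k), max(k)))
  invisible(x)
}

#' Symmetric distance matrix with labels
#'
#' Validates and wraps a symmetric nonnegative matrix with a zero diagonal
#' (genetic or geographic distances among populations).
#'
#' @param values square numeric matrix.
#' @param labels row/column labels; defaults to existing dimnames.
#' @param tol symmetry tolerance (default `1e-9`).
#' @return a plain labelled matrix of class `dist_matrix`.
#' @export
dist_matrix <- function(values, labels = NULL, tol = 1e-9) {
  values <- as.matrix(values)
  if (nrow(values) != ncol(values)) stop("matrix must be square")
  if (is.null(labels)) labels <- rownames(values)
  if (is.null(labels)) labels <- paste0("pop", seq_len(nrow(values)))
  if (max(abs(values - t(values))) > tol) stop("matrix is not symmetric")
  if (any(diag(values) != 0)) stop("diagonal must be exactly 0")
  if (any(values < 0)) stop("distances must be nonnegative")
  values <- (values + t(values)) / 2
  dimnames(values) <- list(labels, labels)
  class(values) <- c("dist_matrix", "matrix", "array")
  values
}

#' Lower-triangle vector of a distance matrix
#' @param m a square matrix.
#' @return numeric vector of the `n(n-1)/2` below-diagonal entries.
#' @export
lower_triangle <- function(m) m[lower.tri(m)]

#' Split one seed into reproducible per-task seed streams
#'
#' A single global seed is expanded into `n` independent 31-bit seeds by
#' seeding R's RNG with `seed` and drawing `n` integers. Modules seeded from
#' the same global seed are therefore re-runnable in isolation.
#'
#' @param seed integer global seed.
#' @param n number of sub-seeds.
#' @return integer vector of length `n`, each in `[1, 2^31 - 2]`.
#' @export
split_seed <- function(seed, n) {
  stopifnot(is.numeric(seed), length(seed) == 1, n >= 1)
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  sample.int(.Machine$integer.max - 1L, n)
}
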
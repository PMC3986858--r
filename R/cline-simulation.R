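#' Hybridization-cline scenario description
#'
#' A cline scenario places `n_populations` virtual populations along a
#' south-to-north transect; population 1 (the southern-most, purest) has no
#' hybridization and each subsequent population adds `increment_pct` percent
#' of either American parents (`mode = "f1_parents"`) or admixed genotypes
#' (`mode = "admixed_fraction"`).
#'
#' @param increment_pct per-population step of the hybridization fraction,
#'   in percent (the study's scenarios use 1, 2, 3 and 4; 0 is the no-cline
#'   control). `increment_pct * (n_populations - 1)` must not exceed 100.
#' @param n_populations virtual populations (default 12).
#' @param n_pairs parental pairs per population for F1 mode (default 50).
#' @param offspring_per_population diploid offspring per population
#'   (default 100, i.e. 2 per pair at the default `n_pairs`).
#' @param mode `"f1_parents"` or `"admixed_fraction"`.
#' @param strict_f1 F1 mode only: force every American parent to mate a
#'   European one so all hybrid offspring are true F1s (default `FALSE`;
#'   random pairing can mate two American parents at high increments).
#' @param seed RNG seed.
#' @return a `cline_scenario` list.
#' @export
cline_scenario <- function(increment_pct, n_populations = 12, n_pairs = 50,
                           offspring_per_population = 100,
                           mode = c("f1_parents", "admixed_fraction"),
                           strict_f1 = FALSE, seed = 1) {
  mode <- match.arg(mode)
  stopifnot(increment_pct >= 0,
            increment_pct * (n_populations - 1) <= 100,
            n_populations >= 2, n_pairs >= 1, offspring_per_population >= 1)
  structure(list(increment_pct = increment_pct,
                 n_populations = as.integer(n_populations),
                 n_pairs = as.integer(n_pairs),
                 offspring_per_population = as.integer(offspring_per_population),
                 mode = mode, strict_f1 = isTRUE(strict_f1),
                 seed = as.integer(seed)),
            class = "cline_scenario")
}

# counts per percentage, rounding half up (round() rounds half to even)
round_half_up <- function(x) floor(x + 0.5)

#' Random-mating population with a controlled number of American parents
#'
#' Fills `2 n_pairs` parent slots by sampling individuals with replacement
#' from the European pool, replaces `n_american_parents` uniformly chosen
#' slots with draws (with replacement) from the American pool, pairs the
#' slots randomly, and lets each pair produce
#' `offspring_per_population / n_pairs` offspring, each receiving one
#' uniformly chosen allele per locus from each parent.
#'
#' @param pool_E,pool_A parental [genotype_table()]s (European, American).
#' @param n_pairs number of parental pairs.
#' @param n_american_parents slots to fill from the American pool, between 0
#'   and `2 n_pairs`.
#' @param offspring_per_population total offspring (distributed as evenly as
#'   possible over pairs).
#' @param seed RNG seed (`NULL` to continue the current stream).
#' @param strict_f1 if `TRUE`, American parents are placed so no pair holds
#'   two of them (requires `n_american_parents <= n_pairs`).
#' @param pop_label population label for the offspring.
#' @return a [genotype_table()] of the offspring.
#' @export
make_f1_population <- function(pool_E, pool_A, n_pairs, n_american_parents,
                               offspring_per_population, seed = NULL,
                               strict_f1 = FALSE, pop_label = "virtual") {
  if (n_individuals(pool_E) == 0 || n_individuals(pool_A) == 0)
    stop("parental pools must be non-empty")
  stopifnot(n_american_parents >= 0, n_american_parents <= 2 * n_pairs)
  if (strict_f1 && n_american_parents > n_pairs)
    stop("strict_f1 requires at most one American parent per pair")
  if (!is.null(seed)) set.seed(seed)
  n_slots <- 2L * n_pairs
  L <- n_loci(pool_E)
  n_off <- offspring_per_population
  # fixed-consumption draws first so datasets differing only in
  # n_american_parents share parents, pairing and Mendelian transmission
  # under a common seed (paired common-random-number replication)
  idxE <- sample.int(n_individuals(pool_E), n_slots, replace = TRUE)
  idxA <- sample.int(n_individuals(pool_A), n_slots, replace = TRUE)
  pairing <- matrix(sample.int(n_slots), ncol = 2)  # random slot pairing
  U1 <- matrix(stats::runif(n_off * L), n_off, L) < 0.5
  U2 <- matrix(stats::runif(n_off * L), n_off, L) < 0.5
  slot_src <- rep("E", n_slots)
  if (n_american_parents > 0) {
    if (strict_f1) {
      pairs_hit <- sample.int(n_pairs, n_american_parents)
      side <- sample(c(0L, 1L), n_american_parents, replace = TRUE)
      slot_src[2L * pairs_hit - 1L + side] <- "A"
    } else {
      slot_src[sample.int(n_slots, n_american_parents)] <- "A"
    }
  }
  par1 <- par2 <- matrix(NA_integer_, n_slots, L)
  for (s in seq_len(n_slots)) {
    src <- if (slot_src[s] == "E") pool_E else pool_A
    i <- if (slot_src[s] == "E") idxE[s] else idxA[s]
    par1[s, ] <- src$allele1[i, ]
    par2[s, ] <- src$allele2[i, ]
  }
  per_pair <- rep(n_off %/% n_pairs, n_pairs)
  extra <- n_off - sum(per_pair)
  if (extra > 0) per_pair[seq_len(extra)] <- per_pair[seq_len(extra)] + 1L
  off1 <- off2 <- matrix(NA_integer_, n_off, L)
  row <- 0L
  for (p in seq_len(n_pairs)) {
    s1 <- pairing[p, 1]; s2 <- pairing[p, 2]
    for (k in seq_len(per_pair[p])) {
      row <- row + 1L
      off1[row, ] <- ifelse(U1[row, ], par1[s1, ], par2[s1, ])
      off2[row, ] <- ifelse(U2[row, ], par1[s2, ], par2[s2, ])
    }
  }
  genotype_table(sprintf("%s_%03d", pop_label, seq_len(n_off)),
                 rep(pop_label, n_off), pool_E$loci, off1, off2)
}

#' Build an F1-hybrid cline dataset
#'
#' Population `k` (k = 1 ... n) draws its parents with
#' `round((k - 1) * increment_pct / 100 * 2 n_pairs)` American parent slots
#' (at the default 50 pairs, exactly `(k - 1) * increment_pct` per 100
#' slots); population 1 has none.
#'
#' @param scenario a [cline_scenario()] with `mode = "f1_parents"`.
#' @param pool_E,pool_A parental pools.
#' @return a `cline_dataset`: `populations` (list of [genotype_table()]s
#'   south to north), `realized_fraction` (American parent-slot fraction per
#'   population), `n_american_parents`, `scenario`.
#' @export
build_f1_cline <- function(scenario, pool_E, pool_A) {
  stopifnot(scenario$mode == "f1_parents")
  seeds <- split_seed(scenario$seed, scenario$n_populations)
  n_slots <- 2L * scenario$n_pairs
  pops <- vector("list", scenario$n_populations)
  n_am <- integer(scenario$n_populations)
  for (k in seq_len(scenario$n_populations)) {
    n_am[k] <- round_half_up((k - 1) * scenario$increment_pct / 100 * n_slots)
    pops[[k]] <- make_f1_population(
      pool_E, pool_A, scenario$n_pairs, n_am[k],
      scenario$offspring_per_population, seed = seeds[k],
      strict_f1 = scenario$strict_f1,
      pop_label = sprintf("site%02d", k))
  }
  structure(list(populations = pops,
                 realized_fraction = n_am / n_slots,
                 n_american_parents = n_am,
                 scenario = scenario),
            class = "cline_dataset")
}

#' Sample one admixed multilocus genotype at ancestry Q
#'
#' Per locus the number of European-origin allele copies is
#' `Binomial(2, Q)`; each copy's allele is then drawn multinomially from the
#' matching pool's spectrum at that locus.
#'
#' @param Q ancestry proportion toward the European pool.
#' @param afs_A,afs_E pool spectra.
#' @return list with integer vectors `a1`, `a2` (one entry per locus).
#' @export
sample_admixed_genotype <- function(Q, afs_A, afs_E) {
  stopifnot(Q >= 0, Q <= 1)
  L <- length(afs_E$freqs)
  a1 <- a2 <- integer(L)
  for (l in seq_len(L)) {
    fE <- afs_E$freqs[[l]]; fA <- afs_A$freqs[[l]]
    nE <- stats::rbinom(1, 2, Q)
    draw <- function(f) {
      sizes <- as.integer(names(f))
      if (length(sizes) == 1) sizes else sample(sizes, 1, prob = f)
    }
    copies <- c(if (nE >= 1) draw(fE), if (nE == 2) draw(fE),
                if (nE <= 1) draw(fA), if (nE == 0) draw(fA))
    a1[l] <- copies[1]; a2[l] <- copies[2]
  }
  list(a1 = a1, a2 = a2)
}

#' Build an admixed-genotype cline dataset
#'
#' Population `k` holds `round((k - 1) * increment_pct / 100 * n)` admixed
#' individuals out of `n = offspring_per_population`, each with Q drawn from
#' `qdist` (multinomial bin sampling, bin midpoints) and a genotype from
#' [sample_admixed_genotype()]; the remainder are pure European genotypes
#' (Q = 1).
#'
#' @param scenario a [cline_scenario()] with `mode = "admixed_fraction"`.
#' @param afs_A,afs_E pool spectra.
#' @param qdist a [q_distribution()] for the admixed individuals.
#' @return a `cline_dataset` with `populations`, `realized_fraction`
#'   (admixed fraction per population), `true_q` (list of per-individual Q
#'   used), `scenario`.
#' @export
build_admixed_cline <- function(scenario, afs_A, afs_E,
                                qdist = q_distribution_uniform()) {
  stopifnot(scenario$mode == "admixed_fraction")
  seeds <- split_seed(scenario$seed, scenario$n_populations)
  n <- scenario$offspring_per_population
  loci <- names(afs_E$freqs)
  pops <- vector("list", scenario$n_populations)
  true_q <- vector("list", scenario$n_populations)
  n_adm <- integer(scenario$n_populations)
  for (k in seq_len(scenario$n_populations)) {
    set.seed(seeds[k])
    n_adm[k] <- round_half_up((k - 1) * scenario$increment_pct / 100 * n)
    # Q drawn for every slot (fixed RNG consumption); only the first
    # n_adm slots keep their admixed Q, the rest are pure European, so
    # clines built at different increments from one seed are paired
    q_all <- sample_q(qdist, n)
    q_ind <- ifelse(seq_len(n) <= n_adm[k], q_all, 1)
    a1 <- a2 <- matrix(NA_integer_, n, length(loci))
    for (l in seq_along(loci)) {
      fE <- afs_E$freqs[[l]]; fA <- afs_A$freqs[[l]]
      sizesE <- as.integer(names(fE)); sizesA <- as.integer(names(fA))
      # per copy: European origin with probability Q (two independent
      # Bernoulli(Q) copies = Binomial(2, Q) European copies per locus);
      # candidate draws from both spectra are taken for every copy so RNG
      # consumption does not depend on Q
      orig1 <- stats::runif(n) < q_ind
      orig2 <- stats::runif(n) < q_ind
      pick <- function(sizes, f)
        sizes[pmin(findInterval(stats::runif(n), cumsum(f)) + 1L,
                   length(sizes))]
      e1 <- pick(sizesE, fE); e2 <- pick(sizesE, fE)
      x1 <- pick(sizesA, fA); x2 <- pick(sizesA, fA)
      a1[, l] <- ifelse(orig1, e1, x1)
      a2[, l] <- ifelse(orig2, e2, x2)
    }
    lab <- sprintf("site%02d", k)
    pops[[k]] <- genotype_table(sprintf("%s_%03d", lab, seq_len(n)),
                                rep(lab, n), loci, a1, a2)
    true_q[[k]] <- q_ind
  }
  structure(list(populations = pops,
                 realized_fraction = n_adm / n,
                 true_q = true_q,
                 scenario = scenario),
            class = "cline_dataset")
}

#' @export
print.cline_dataset <- function(x, ...) {
  cat(sprintf("<cline_dataset> %d populations, mode %s, increment %g%%\n",
              length(x$populations), x$scenario$mode,
              x$scenario$increment_pct))
  cat("  realized fractions:",
      paste(sprintf("%.2f", x$realized_fraction), collapse = " "), "\n")
  invisible(x)
}

#' Write a cline dataset as Genepop files plus a JSON manifest
#'
#' @param cline a `cline_dataset`.
#' @param dir output directory (created if missing).
#' @return the manifest path, invisibly.
#' @export
write_cline_dataset <- function(cline, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(length(cline$populations))
  for (k in seq_along(cline$populations)) {
    files[k] <- file.path(dir, sprintf("population_%02d.gen", k))
    write_genepop(cline$populations[[k]], files[k],
                  title = sprintf("virtual population %02d", k))
  }
  manifest <- list(scenario = unclass(cline$scenario),
                   realized_fraction = cline$realized_fraction,
                   files = basename(files))
  mp <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, digits = NA)
  invisible(mp)
}
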
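#' Configuration for the synthetic species gene pools
#'
#' Describes the two diverged microsatellite gene pools the generator
#' emulates: nine highly polymorphic dinucleotide loci with 10-18 alleles
#' each and a weak inter-species multi-locus differentiation (FST ~ 0.0146),
#' the regime in which North Atlantic eel hybrids must be detected.
#'
#' @param n_loci number of microsatellite loci (default 9).
#' @param alleles_per_locus_range integer interval for the per-locus allele
#'   count (default `c(10, 18)`), within `[2, 50]`.
#' @param repeat_motif_length allele-size lattice step in bp (default 2,
#'   dinucleotide repeats) so size-based statistics (RST) are meaningful.
#' @param target_fst target multi-locus Weir-Cockerham FST between the two
#'   pools, in `(0, 0.2)` (default 0.0146).
#' @param pool_size diploid individuals per species pool (default 100),
#'   at least 10.
#' @param ancestral_alpha symmetric Dirichlet concentration of the shared
#'   ancestral spectrum (default 0.4, giving expected heterozygosity near
#'   0.78 for 10-18 alleles).
#' @param seed integer RNG seed.
#' @return a `species_pool_config` list.
#' @export
species_pool_config <- function(n_loci = 9,
                                alleles_per_locus_range = c(10L, 18L),
                                repeat_motif_length = 2,
                                target_fst = 0.0146,
                                pool_size = 100,
                                ancestral_alpha = 0.4,
                                seed = 1) {
  stopifnot(target_fst > 0, target_fst < 0.2,
            length(alleles_per_locus_range) == 2,
            alleles_per_locus_range[1] >= 2, alleles_per_locus_range[2] <= 50,
            alleles_per_locus_range[1] <= alleles_per_locus_range[2],
            pool_size >= 10, n_loci >= 1, ancestral_alpha > 0)
  structure(list(n_loci = as.integer(n_loci),
                 alleles_per_locus_range = as.integer(alleles_per_locus_range),
                 repeat_motif_length = as.integer(repeat_motif_length),
                 target_fst = target_fst,
                 pool_size = as.integer(pool_size),
                 ancestral_alpha = ancestral_alpha,
                 seed = as.integer(seed)),
            class = "species_pool_config")
}

rdirichlet1 <- function(alpha) {
  x <- stats::rgamma(length(alpha), shape = alpha)
  if (sum(x) == 0) x[which.max(alpha)] <- 1
  x / sum(x)
}

# Draw both pools for a given divergence parameter F under a fixed seed:
# shared ancestral spectra ~ Dirichlet(alpha), species spectra ~
# Dirichlet(p_anc (1-F)/F) (Balding-Nichols), genotypes under
# Hardy-Weinberg within species. All stochastic inputs are drawn as fixed
# uniforms and mapped through inverse CDFs, so for one seed the realized
# FST is a continuous function of f and bisection on f is well behaved.
draw_pools_at_f <- function(config, f) {
  set.seed(config$seed)
  L <- config$n_loci
  n <- config$pool_size
  loci <- sprintf("Loc%02d", seq_len(L))
  k <- sample(seq(config$alleles_per_locus_range[1],
                  config$alleles_per_locus_range[2]), L, replace = TRUE)
  u_anc <- lapply(k, function(ki) stats::runif(ki))
  u_spec <- lapply(k, function(ki)
    list(E = stats::runif(ki), A = stats::runif(ki)))
  u_geno <- list(E = matrix(stats::runif(2 * n * L), 2 * n, L),
                 A = matrix(stats::runif(2 * n * L), 2 * n, L))
  scale <- (1 - f) / f
  spectra <- list(E = vector("list", L), A = vector("list", L))
  names(spectra$E) <- names(spectra$A) <- loci
  qdirichlet <- function(u, alpha) {
    x <- stats::qgamma(u, shape = alpha)
    x <- pmax(x, 1e-300)
    x / sum(x)
  }
  for (l in seq_len(L)) {
    sizes <- 100 + config$repeat_motif_length * (seq_len(k[l]) - 1)
    p_anc <- qdirichlet(u_anc[[l]], rep(config$ancestral_alpha, k[l]))
    pe <- qdirichlet(u_spec[[l]]$E, p_anc * scale)
    pa <- qdirichlet(u_spec[[l]]$A, p_anc * scale)
    names(pe) <- names(pa) <- as.character(sizes)
    spectra$E[[l]] <- pe
    spectra$A[[l]] <- pa
  }
  draw_pool <- function(freqs, u, prefix) {
    a1 <- a2 <- matrix(NA_integer_, n, L)
    for (l in seq_len(L)) {
      sizes <- as.integer(names(freqs[[l]]))
      idx <- findInterval(u[, l], cumsum(freqs[[l]])) + 1L
      idx <- pmin(idx, length(sizes))
      a1[, l] <- sizes[idx[1:n]]
      a2[, l] <- sizes[idx[(n + 1):(2 * n)]]
    }
    genotype_table(sprintf("%s%03d", prefix, seq_len(n)),
                   rep(prefix, n), loci, a1, a2)
  }
  pool_E <- draw_pool(spectra$E, u_geno$E, "European")
  pool_A <- draw_pool(spectra$A, u_geno$A, "American")
  list(pool_E = pool_E, pool_A = pool_A,
       afs_E = afs(spectra$E), afs_A = afs(spectra$A))
}

#' Generate two calibrated synthetic species gene pools
#'
#' Draws two diploid microsatellite pools around a shared ancestral allele
#' spectrum using a Balding-Nichols Dirichlet divergence model, with the
#' divergence parameter F calibrated by bisection so the realized
#' multi-locus Weir-Cockerham FST between the emitted pools is within
#' `tol` of `target_fst`. Output is bit-identical for equal configs.
#'
#' @param config a [species_pool_config()].
#' @param tol calibration tolerance on realized FST (default 0.005).
#' @param max_iter bisection iterations before giving up (default 40).
#' @return list with `pool_E`, `pool_A` ([genotype_table()]s), `afs_E`,
#'   `afs_A` (the generating spectra), `realized_fst`, `f` (calibrated
#'   divergence parameter).
#' @export
gen_species_pools <- function(config = species_pool_config(),
                              tol = 0.005, max_iter = 40) {
  realized <- function(f) {
    pools <- draw_pools_at_f(config, f)
    tab <- bind_tables(pools$pool_E, pools$pool_A)
    theta <- fst_weir_cockerham(tab)$theta
    # both pools fixed for the same alleles leaves theta undefined; treat
    # as zero differentiation for the calibration search
    if (!is.finite(theta)) theta <- 0
    list(pools = pools, fst = theta)
  }
  lo <- 1e-4; hi <- 0.6
  r_lo <- realized(lo); r_hi <- realized(hi)
  if (r_lo$fst > config$target_fst || r_hi$fst < config$target_fst)
    stop(sprintf(
      "FST calibration failed: target %.4f outside achievable [%.4f, %.4f]",
      config$target_fst, r_lo$fst, r_hi$fst))
  best <- NULL
  for (i in seq_len(max_iter)) {
    mid <- sqrt(lo * hi)  # bisect on log scale: FST spans orders of magnitude
    r <- realized(mid)
    best <- r; best_f <- mid
    if (abs(r$fst - config$target_fst) <= tol) {
      out <- r$pools
      out$realized_fst <- r$fst
      out$f <- mid
      return(out)
    }
    if (r$fst < config$target_fst) lo <- mid else hi <- mid
  }
  stop(sprintf(
    "FST calibration did not converge in %d iterations: achieved %.4f, target %.4f",
    max_iter, best$fst, config$target_fst))
}
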
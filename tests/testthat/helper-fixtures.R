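# Small fixtures shared across test files. Everything is generated in code;
# sizes are kept small so the default test run stays fast.

# a fixed 2-population, 2-locus toy table used by the FST / RST oracles
toy_two_pop_table <- function() {
  genotype_table(
    individuals = sprintf("ind%02d", 1:8),
    populations = rep(c("P1", "P2"), each = 4),
    loci = c("LocA", "LocB"),
    allele1 = rbind(c(100, 200), c(100, 200), c(100, 202), c(102, 202),
                    c(102, 204), c(102, 204), c(104, 204), c(104, 202)),
    allele2 = rbind(c(100, 202), c(102, 200), c(102, 202), c(102, 204),
                    c(104, 204), c(102, 202), c(104, 204), c(104, 204)))
}

# small calibrated species pools, cached per session (calibration is cheap
# but repeated use across files adds up)
cached_pools <- local({
  cache <- NULL
  function(seed = 42) {
    if (is.null(cache) || attr(cache, "seed") != seed) {
      p <- gen_species_pools(species_pool_config(seed = seed))
      attr(p, "seed") <- seed
      cache <<- p
    }
    cache
  }
})

# independent textbook Weir-Cockerham theta for exactly two populations,
# written directly from the 1984 variance-component definitions; kept
# separate from the package implementation on purpose
oracle_wc_theta <- function(table, grouping = table$populations) {
  num <- den <- 0
  for (l in seq_along(table$loci)) {
    a1 <- table$allele1[, l]; a2 <- table$allele2[, l]
    ok <- !is.na(a1)
    g <- grouping[ok]; x1 <- a1[ok]; x2 <- a2[ok]
    pops <- unique(g)
    r <- length(pops)
    n_i <- sapply(pops, function(p) sum(g == p))
    n_bar <- mean(n_i)
    nc <- (sum(n_i) - sum(n_i^2) / sum(n_i)) / (r - 1)
    for (al in unique(c(x1, x2))) {
      p_i <- sapply(pops, function(p) {
        rows <- g == p
        (sum(x1[rows] == al) + sum(x2[rows] == al)) / (2 * sum(rows))
      })
      h_i <- sapply(pops, function(p) {
        rows <- g == p
        mean((x1[rows] == al) != (x2[rows] == al))
      })
      p_bar <- sum(n_i * p_i) / sum(n_i)
      s2 <- sum(n_i * (p_i - p_bar)^2) / ((r - 1) * n_bar)
      h_bar <- sum(n_i * h_i) / sum(n_i)
      a <- n_bar / nc * (s2 - 1 / (n_bar - 1) *
        (p_bar * (1 - p_bar) - (r - 1) / r * s2 - h_bar / 4))
      b <- n_bar / (n_bar - 1) * (p_bar * (1 - p_bar) -
        (r - 1) / r * s2 - (2 * n_bar - 1) / (4 * n_bar) * h_bar)
      cc <- h_bar / 2
      num <- num + a
      den <- den + a + b + cc
    }
  }
  num / den
}

# Monte-Carlo rarefaction oracle: expected allele count in a random
# subsample of g gene copies
oracle_rarefied_richness <- function(counts, g, n_rep = 20000, seed = 1) {
  set.seed(seed)
  copies <- rep(seq_along(counts), counts)
  mean(replicate(n_rep, length(unique(sample(copies, g)))))
}

# Monte-Carlo private-allele oracle over J groups simultaneously
oracle_private_richness <- function(count_matrix, g, n_rep = 20000, seed = 1) {
  set.seed(seed)
  J <- ncol(count_matrix)
  pools <- lapply(seq_len(J), function(j)
    rep(seq_len(nrow(count_matrix)), count_matrix[, j]))
  acc <- numeric(J)
  for (r in seq_len(n_rep)) {
    seen <- lapply(pools, function(p) unique(sample(p, g)))
    for (j in seq_len(J)) {
      others <- unique(unlist(seen[-j]))
      acc[j] <- acc[j] + length(setdiff(seen[[j]], others))
    }
  }
  acc / n_rep
}
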
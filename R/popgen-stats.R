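#' Per-group allele frequency spectra
#'
#' Tallies allele frequencies per locus within each group. Missing calls are
#' excluded from denominators; a locus with no data in a group is flagged by
#' a `NULL` spectrum entry.
#'
#' @param table a [genotype_table()].
#' @param grouping character vector of group labels per individual; defaults
#'   to `table$populations`. Pass a single label to pool everybody.
#' @return named list of [afs()] objects, one per group (group order =
#'   first appearance).
#' @export
allele_frequencies <- function(table, grouping = table$populations) {
  if (length(grouping) == 1) grouping <- rep(grouping, n_individuals(table))
  stopifnot(length(grouping) == n_individuals(table))
  groups <- unique(grouping)
  out <- lapply(groups, function(g) {
    rows <- which(grouping == g)
    freqs <- vector("list", n_loci(table))
    names(freqs) <- table$loci
    n_genes <- integer(n_loci(table))
    for (l in seq_len(n_loci(table))) {
      copies <- c(table$allele1[rows, l], table$allele2[rows, l])
      copies <- copies[!is.na(copies)]
      n_genes[l] <- length(copies)
      if (length(copies) == 0) { freqs[[l]] <- NULL; next }
      tab <- table(copies)
      f <- as.numeric(tab) / length(copies)
      names(f) <- names(tab)
      freqs[[l]] <- f
    }
    afs(freqs, n_genes)
  })
  names(out) <- groups
  out
}

#' Observed and expected heterozygosity
#'
#' Per-locus and mean observed heterozygosity (fraction of heterozygous
#' calls) and unbiased expected heterozygosity
#' `He = (2n/(2n-1)) (1 - sum p^2)` with `n` the number of genotyped
#' individuals, plus `F_IS = 1 - Ho/He` (multi-locus via mean Ho and He).
#'
#' @param table a [genotype_table()].
#' @param grouping group labels per individual (default populations).
#' @return named list of data frames (one per group) with columns `locus`,
#'   `n`, `Ho`, `He`, plus attributes `mean_Ho`, `mean_He`, `Fis`.
#' @export
heterozygosities <- function(table, grouping = table$populations) {
  if (length(grouping) == 1) grouping <- rep(grouping, n_individuals(table))
  groups <- unique(grouping)
  out <- lapply(groups, function(g) {
    rows <- which(grouping == g)
    res <- data.frame(locus = table$loci, n = NA_integer_,
                      Ho = NA_real_, He = NA_real_)
    for (l in seq_len(n_loci(table))) {
      a1 <- table$allele1[rows, l]; a2 <- table$allele2[rows, l]
      ok <- !is.na(a1)
      n <- sum(ok)
      res$n[l] <- n
      if (n == 0) next
      res$Ho[l] <- mean(a1[ok] != a2[ok])
      copies <- c(a1[ok], a2[ok])
      p <- as.numeric(table(copies)) / (2 * n)
      if (length(p) <= 1) { res$He[l] <- 0 } else {
        res$He[l] <- (2 * n / (2 * n - 1)) * (1 - sum(p^2))
      }
      if (length(p) <= 1) res$Ho[l] <- 0  # monomorphic: define Ho = He = 0
    }
    attr(res, "mean_Ho") <- mean(res$Ho, na.rm = TRUE)
    attr(res, "mean_He") <- mean(res$He, na.rm = TRUE)
    mh <- attr(res, "mean_He")
    attr(res, "Fis") <- if (isTRUE(mh > 0)) 1 - attr(res, "mean_Ho") / mh else NA_real_
    res
  })
  names(out) <- groups
  out
}

# Weir & Cockerham (1984) variance components a (among), b (between
# individuals within pop) and c (within individuals) for one locus,
# summed over alleles. Returns c(a, b, c) or NULL if < 2 usable pops.
wc_components_locus <- function(a1, a2, grouping) {
  ok <- !is.na(a1)
  a1 <- a1[ok]; a2 <- a2[ok]; grouping <- grouping[ok]
  pops <- unique(grouping)
  n_i <- vapply(pops, function(g) sum(grouping == g), 0L)
  keep <- n_i >= 1
  pops <- pops[keep]; n_i <- n_i[keep]
  r <- length(pops)
  if (r < 2 || sum(n_i) < 2) return(NULL)
  alleles <- sort(unique(c(a1, a2)))
  if (length(alleles) < 2) return(c(0, 0, 0))
  n_bar <- mean(n_i)
  nc <- (r * n_bar - sum(n_i^2) / (r * n_bar)) / (r - 1)
  acc <- c(a = 0, b = 0, c = 0)
  for (al in alleles) {
    p_i <- h_i <- numeric(r)
    for (k in seq_len(r)) {
      rows <- grouping == pops[k]
      x1 <- a1[rows]; x2 <- a2[rows]
      p_i[k] <- (sum(x1 == al) + sum(x2 == al)) / (2 * n_i[k])
      h_i[k] <- mean((x1 == al) != (x2 == al))
    }
    p_bar <- sum(n_i * p_i) / (r * n_bar)
    s2 <- sum(n_i * (p_i - p_bar)^2) / ((r - 1) * n_bar)
    h_bar <- sum(n_i * h_i) / (r * n_bar)
    a <- (n_bar / nc) *
      (s2 - (p_bar * (1 - p_bar) - (r - 1) / r * s2 - h_bar / 4) / (n_bar - 1))
    b <- (n_bar / (n_bar - 1)) *
      (p_bar * (1 - p_bar) - (r - 1) / r * s2 - (2 * n_bar - 1) / (4 * n_bar) * h_bar)
    cc <- h_bar / 2
    acc <- acc + c(a, b, cc)
  }
  acc
}

#' Weir-Cockerham FST (theta)
#'
#' Multi-allele, multi-population theta of Weir & Cockerham (1984), combined
#' across loci as a ratio of summed variance components (never a mean of
#' per-locus ratios). Negative per-locus estimates are retained. Statistical
#' significance by permutation of individuals across groups.
#'
#' @param table a [genotype_table()].
#' @param grouping group labels (default populations); at least 2 groups of
#'   at least 2 individuals each.
#' @param n_perm permutations for the p-value; 0 skips the test.
#' @param seed RNG seed for the permutations.
#' @return list with `theta` (multi-locus), `per_locus` (named vector),
#'   `p` (or `NA` if `n_perm = 0`), `n_perm`.
#' @export
fst_weir_cockerham <- function(table, grouping = table$populations,
                               n_perm = 0, seed = NULL) {
  if (length(grouping) == 1) grouping <- rep(grouping, n_individuals(table))
  sizes <- table(grouping)
  if (length(sizes) < 2) stop("need at least 2 groups")
  if (any(sizes < 2)) stop("every group needs at least 2 individuals")
  theta_of <- function(grp) {
    comp <- matrix(0, n_loci(table), 3)
    perl <- rep(NA_real_, n_loci(table))
    for (l in seq_len(n_loci(table))) {
      cl <- wc_components_locus(table$allele1[, l], table$allele2[, l], grp)
      if (is.null(cl)) next
      comp[l, ] <- cl
      tot <- sum(cl)
      perl[l] <- if (tot != 0) cl[1] / tot else NA_real_
    }
    tot <- colSums(comp)
    list(theta = tot[1] / sum(tot), per_locus = perl)
  }
  obs <- theta_of(grouping)
  names(obs$per_locus) <- table$loci
  p <- NA_real_
  if (n_perm > 0) {
    if (!is.null(seed)) set.seed(seed)
    hits <- 0L
    for (i in seq_len(n_perm)) {
      th <- theta_of(sample(grouping))$theta
      if (th >= obs$theta) hits <- hits + 1L
    }
    p <- (1 + hits) / (n_perm + 1)
  }
  list(theta = unname(obs$theta), per_locus = obs$per_locus,
       p = p, n_perm = n_perm)
}

#' RST from allele-size variance (Slatkin-type moment estimator)
#'
#' `RST = (S_B - S_W) / S_B`, with `S_W` the mean squared size difference
#' between gene copies of the same group (pair-count weighted across groups;
#' twice the within-group variance) and `S_B` the mean squared size
#' difference between gene copies of different groups. This among-group
#' form decomposes size variance the same way the Weir-Cockerham components
#' decompose allele-identity variance, so under a divergence model in which
#' allele sizes are exchangeable labels the two statistics estimate the
#' same quantity (the pooled-sample denominator found in some formulations
#' halves the between-group signal when only two groups are compared).
#' Multi-locus by ratio of summed components.
#'
#' @inheritParams fst_weir_cockerham
#' @return list with `rst`, `per_locus`, `p`, `n_perm`.
#' @export
rst_slatkin <- function(table, grouping = table$populations,
                        n_perm = 0, seed = NULL) {
  if (length(grouping) == 1) grouping <- rep(grouping, n_individuals(table))
  rst_of <- function(grp) {
    num <- den <- 0
    perl <- rep(NA_real_, n_loci(table))
    for (l in seq_len(n_loci(table))) {
      a1 <- table$allele1[, l]; a2 <- table$allele2[, l]
      ok <- !is.na(a1)
      copies <- c(a1[ok], a2[ok])
      cg <- c(grp[ok], grp[ok])
      if (length(copies) < 4 || length(unique(cg)) < 2) next
      groups <- unique(cg)
      # within: pair-count-weighted mean squared difference within groups
      w_pairs <- s_within <- 0
      means <- sizes <- vars <- numeric(length(groups))
      for (gi in seq_along(groups)) {
        x <- copies[cg == groups[gi]]
        sizes[gi] <- length(x)
        means[gi] <- mean(x)
        vars[gi] <- if (length(x) > 1) stats::var(x) else 0
        if (length(x) >= 2) {
          pairs <- length(x) * (length(x) - 1) / 2
          w_pairs <- w_pairs + pairs
          s_within <- s_within + pairs * 2 * vars[gi]
        }
      }
      s_w <- s_within / w_pairs
      # between: mean squared difference over all cross-group copy pairs
      b_pairs <- s_between <- 0
      for (gi in seq_along(groups)) for (gj in seq_along(groups)) {
        if (gj <= gi) next
        npair <- sizes[gi] * sizes[gj]
        # E[(x - y)^2] = var_i + var_j + (mean_i - mean_j)^2, computable
        # without enumerating pairs
        msd <- vars[gi] * (sizes[gi] - 1) / sizes[gi] +
          vars[gj] * (sizes[gj] - 1) / sizes[gj] +
          (means[gi] - means[gj])^2
        b_pairs <- b_pairs + npair
        s_between <- s_between + npair * msd
      }
      s_b <- s_between / b_pairs
      perl[l] <- if (s_b > 0) (s_b - s_w) / s_b else NA_real_
      num <- num + (s_b - s_w)
      den <- den + s_b
    }
    list(rst = num / den, per_locus = perl)
  }
  obs <- rst_of(grouping)
  names(obs$per_locus) <- table$loci
  p <- NA_real_
  if (n_perm > 0) {
    if (!is.null(seed)) set.seed(seed)
    hits <- 0L
    for (i in seq_len(n_perm))
      if (rst_of(sample(grouping))$rst >= obs$rst) hits <- hits + 1L
    p <- (1 + hits) / (n_perm + 1)
  }
  list(rst = unname(obs$rst), per_locus = obs$per_locus, p = p, n_perm = n_perm)
}

# log conditional probability of a diploid genotype configuration given its
# allele counts (Levene / Guo-Thompson exact-test statistic), up to the
# constant shared by all tables with the same allele counts.
log_prob_genotype_table <- function(a1, a2) {
  h <- sum(a1 != a2)
  geno <- paste(pmin(a1, a2), pmax(a1, a2))
  sum_log_genos <- sum(lgamma(table(geno) + 1))
  h * log(2) - sum_log_genos
}

#' Monte-Carlo exact test for Hardy-Weinberg equilibrium
#'
#' Guo-Thompson style: gene copies within the group are shuffled and
#' re-paired; the statistic is the conditional probability of the genotype
#' table given allele counts. `p` is the fraction of shuffled tables no more
#' probable than the observed one (with the +1 correction).
#'
#' @param table a [genotype_table()].
#' @param group label of the group to test.
#' @param locus locus name or index.
#' @param n_perm Monte-Carlo replicates (default 10000).
#' @param seed RNG seed.
#' @return the Monte-Carlo p-value.
#' @export
hwe_test <- function(table, group, locus, n_perm = 10000, seed = NULL) {
  rows <- which(table$populations == group)
  if (is.character(locus)) locus <- match(locus, table$loci)
  a1 <- table$allele1[rows, locus]; a2 <- table$allele2[rows, locus]
  ok <- !is.na(a1)
  a1 <- a1[ok]; a2 <- a2[ok]
  if (length(a1) < 2) stop("fewer than 2 genotyped individuals")
  if (length(unique(c(a1, a2))) < 2) return(1)
  if (!is.null(seed)) set.seed(seed)
  obs <- log_prob_genotype_table(a1, a2)
  copies <- c(a1, a2)
  n <- length(a1)
  hits <- 0L
  for (i in seq_len(n_perm)) {
    perm <- sample(copies)
    if (log_prob_genotype_table(perm[1:n], perm[(n + 1):(2 * n)]) <= obs + 1e-12)
      hits <- hits + 1L
  }
  (1 + hits) / (n_perm + 1)
}

#' Bonferroni correction
#'
#' @param p_list numeric p-values.
#' @param alpha family-wise error rate (default 0.05).
#' @param m number of tests (default `length(p_list)`).
#' @return logical vector: reject iff `p < alpha / m`.
#' @export
bonferroni <- function(p_list, alpha = 0.05, m = length(p_list)) {
  p_list < alpha / m
}

#' Rarefied allelic richness
#'
#' Expected number of distinct alleles in a subsample of `g` gene copies,
#' `A_R(g) = sum_a (1 - C(N - N_a, g) / C(N, g))` (hypergeometric
#' rarefaction), with `N` total copies and `N_a` copies of allele `a`.
#'
#' @param counts integer vector of per-allele copy counts.
#' @param g rarefaction size in gene copies, `1 <= g <= sum(counts)`.
#' @return expected allele count in `[1, length(counts)]`.
#' @export
allelic_richness_rarefied <- function(counts, g) {
  counts <- counts[counts > 0]
  N <- sum(counts)
  stopifnot(g >= 1, g <= N)
  sum(1 - exp(lchoose(N - counts, g) - lchoose(N, g)))
}

#' Rarefied private allelic richness
#'
#' Expected number of alleles seen in a size-`g` subsample of group `j` and
#' in none of the size-`g` subsamples of the other groups.
#'
#' @param count_matrix alleles x groups matrix of copy counts (all groups
#'   over the union of alleles; zero where absent).
#' @param g rarefaction size in gene copies, at most the smallest group total.
#' @return numeric vector of expected private-allele counts per group.
#' @export
private_allelic_richness_rarefied <- function(count_matrix, g) {
  count_matrix <- as.matrix(count_matrix)
  N <- colSums(count_matrix)
  stopifnot(g >= 1, g <= min(N))
  J <- ncol(count_matrix)
  # q[a, j] = P(allele a NOT seen in a size-g subsample of group j)
  q <- exp(lchoose(sweep(-count_matrix, 2, N, `+`), g) -
             rep(lchoose(N, g), each = nrow(count_matrix)))
  out <- numeric(J)
  for (j in seq_len(J)) {
    others <- apply(q[, -j, drop = FALSE], 1, prod)
    out[j] <- sum((1 - q[, j]) * others)
  }
  names(out) <- colnames(count_matrix)
  out
}

#' Cavalli-Sforza & Edwards chord distance
#'
#' Per-locus term `t_l = 1 - sum_a sqrt(p1_a p2_a)`; the distance is
#' `sqrt(mean_l t_l)`. Alleles absent from one spectrum contribute 0 to the
#' inner sum, so fully disjoint allele sets give `D_CE = 1`. This fixed
#' convention omits the `2/pi` and related normalisations used by some
#' programs; every downstream use here (Mantel correlations) is invariant to
#' a global scale factor.
#'
#' @param afs1,afs2 [afs()] objects over the same loci.
#' @return chord distance in `[0, 1]`.
#' @export
cavalli_sforza_chord <- function(afs1, afs2) {
  loci <- intersect(names(afs1$freqs), names(afs2$freqs))
  terms <- c()
  for (l in loci) {
    p1 <- afs1$freqs[[l]]; p2 <- afs2$freqs[[l]]
    if (is.null(p1) || is.null(p2)) next
    shared <- intersect(names(p1), names(p2))
    terms <- c(terms, 1 - sum(sqrt(p1[shared] * p2[shared])))
  }
  if (length(terms) == 0) stop("no locus with data in both spectra")
  sqrt(max(mean(terms), 0))
}

#' Per-population summary statistics table
#'
#' One row per population: sample size, mean observed/expected
#' heterozygosity, rarefied allelic richness and F_IS.
#'
#' @param table a [genotype_table()].
#' @param g rarefaction size in gene copies; default twice the smallest
#'   per-population count of genotyped individuals (minimum over loci).
#' @return data frame with columns `population`, `n`, `Ho`, `He`, `A_R`,
#'   `Fis`.
#' @export
summary_stats <- function(table, g = NULL) {
  pops <- unique(table$populations)
  het <- heterozygosities(table)
  spectra <- allele_frequencies(table)
  if (is.null(g)) {
    min_genes <- Inf
    for (p in pops) min_genes <- min(min_genes, spectra[[p]]$n_genes)
    g <- max(2, min_genes)
  }
  rows <- lapply(pops, function(p) {
    sp <- spectra[[p]]
    ar <- mean(vapply(seq_along(sp$freqs), function(l) {
      f <- sp$freqs[[l]]
      if (is.null(f)) return(NA_real_)
      allelic_richness_rarefied(round(f * sp$n_genes[l]), min(g, sp$n_genes[l]))
    }, 0), na.rm = TRUE)
    data.frame(population = p, n = sum(table$populations == p),
               Ho = attr(het[[p]], "mean_Ho"), He = attr(het[[p]], "mean_He"),
               A_R = ar, Fis = attr(het[[p]], "Fis"))
  })
  do.call(rbind, rows)
}
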
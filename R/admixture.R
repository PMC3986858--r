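#' Smoothed two-pool allele frequencies for the likelihood model
#'
#' Builds, per locus, frequencies over the union of alleles observed in
#' either pool plus one shared pseudo-allele, with 0.5 added to every count
#' (Jeffreys-style smoothing). No allele copy can then have zero likelihood
#' under either pool — private alleles stay highly informative without
#' producing infinite log-likelihood ratios.
#'
#' @param afs_A,afs_E [afs()] objects for the two pools (with `n_genes`).
#' @return list of per-locus lists with `alleles`, `pA`, `pE`, and the
#'   pseudo-allele frequencies `pA0`, `pE0`.
#' @keywords internal
smoothed_pool_freqs <- function(afs_A, afs_E) {
  loci <- names(afs_E$freqs)
  out <- vector("list", length(loci))
  names(out) <- loci
  for (i in seq_along(loci)) {
    l <- loci[i]
    fA <- afs_A$freqs[[l]]; fE <- afs_E$freqs[[l]]
    if (is.null(fA) || is.null(fE)) next
    nA <- if (!is.null(afs_A$n_genes)) afs_A$n_genes[i] else 200L
    nE <- if (!is.null(afs_E$n_genes)) afs_E$n_genes[i] else 200L
    alleles <- sort(unique(c(names(fA), names(fE))))
    cA <- stats::setNames(rep(0, length(alleles)), alleles)
    cE <- cA
    cA[names(fA)] <- fA * nA
    cE[names(fE)] <- fE * nE
    cA <- cA + 0.5; cE <- cE + 0.5
    totA <- sum(cA) + 0.5; totE <- sum(cE) + 0.5  # + pseudo-allele count
    out[[i]] <- list(alleles = as.integer(alleles),
                     pA = unname(cA) / totA, pE = unname(cE) / totE,
                     pA0 = 0.5 / totA, pE0 = 0.5 / totE)
  }
  out
}

#' Supervised two-pool maximum-likelihood ancestry proportion
#'
#' Estimates the proportion Q of an individual's genome originating from the
#' European pool by maximising, over `q` in `[0, 1]`, the log-likelihood
#' `sum over allele copies of log(q pE(a) + (1-q) pA(a))` with pool
#' frequencies smoothed by [smoothed_pool_freqs()]. The objective is concave
#' in `q`; Brent's method locates the optimum to `|dQ| < 1e-6`. Missing loci
#' are skipped.
#'
#' @param genotype either a 2-row matrix / length-2 list of per-locus allele
#'   vectors, or a [genotype_table()] row given as
#'   `list(a1 = ..., a2 = ...)`; simplest: pass `table` and `individual`.
#' @param afs_A,afs_E allele frequency spectra of the American and European
#'   pool (with gene counts).
#' @param smoothed optionally, a precomputed [smoothed_pool_freqs()] result
#'   (saves recomputation over many individuals).
#' @return an `admixture_result`: `Q` (proportion European),
#'   `log_likelihood`, `purity` (see [classify_purity()]).
#' @export
estimate_q <- function(genotype, afs_A, afs_E, smoothed = NULL) {
  if (is.null(smoothed)) smoothed <- smoothed_pool_freqs(afs_A, afs_E)
  a1 <- genotype$a1; a2 <- genotype$a2
  pA <- pE <- c()
  for (i in seq_along(smoothed)) {
    sm <- smoothed[[i]]
    if (is.null(sm) || is.na(a1[i])) next
    for (al in c(a1[i], a2[i])) {
      j <- match(al, sm$alleles)
      if (is.na(j)) { pA <- c(pA, sm$pA0); pE <- c(pE, sm$pE0) }
      else { pA <- c(pA, sm$pA[j]); pE <- c(pE, sm$pE[j]) }
    }
  }
  if (length(pA) == 0) stop("genotype is missing at every locus")
  negll <- function(q) -sum(log(q * pE + (1 - q) * pA))
  opt <- stats::optimize(negll, c(0, 1), tol = 1e-8)
  # the optimum may sit at a boundary; compare against the endpoints
  cand <- c(opt$minimum, 0, 1)
  vals <- vapply(cand, negll, 0)
  q_hat <- cand[which.min(vals)]
  structure(list(Q = q_hat, log_likelihood = -min(vals),
                 purity = classify_purity(q_hat)),
            class = "admixture_result")
}

#' Ancestry proportions for every individual of a table
#'
#' @param table a [genotype_table()].
#' @param afs_A,afs_E pool spectra.
#' @return data frame with `id`, `population`, `Q`, `log_likelihood`,
#'   `purity`.
#' @export
estimate_q_table <- function(table, afs_A, afs_E) {
  sm <- smoothed_pool_freqs(afs_A, afs_E)
  res <- lapply(seq_len(n_individuals(table)), function(i)
    estimate_q(list(a1 = table$allele1[i, ], a2 = table$allele2[i, ]),
               afs_A, afs_E, smoothed = sm))
  data.frame(id = table$individuals, population = table$populations,
             Q = vapply(res, `[[`, 0, "Q"),
             log_likelihood = vapply(res, `[[`, 0, "log_likelihood"),
             purity = vapply(res, `[[`, "", "purity"))
}

#' Purity classification at the Q = 0.9 threshold
#'
#' Pure European for `Q > 0.9`, pure American for `Q < 0.1`, admixed
#' otherwise.
#'
#' @param Q ancestry proportion toward the European pool.
#' @return one of `"pure_European"`, `"pure_American"`, `"admixed"`.
#' @export
classify_purity <- function(Q) {
  stopifnot(Q >= 0, Q <= 1)
  if (Q > 0.9) "pure_European" else if (Q < 0.1) "pure_American" else "admixed"
}

#' Urn permutation test for intermediacy of a suspect group
#'
#' Draws `group_size` Q values (without replacement within a draw, with
#' replacement across draws) `n_draws` times from each species pool and
#' records the mean of each draw. The observed group mean is then compared
#' one-tailed against each pool's null distribution, the tail pointing
#' toward the opposing pool.
#'
#' @param q_american,q_european Q values of the two reference pools (each of
#'   length at least `group_size`).
#' @param observed_mean mean Q of the suspect group.
#' @param group_size suspects per draw (default 16).
#' @param n_draws draws per pool (default 1000).
#' @param seed RNG seed.
#' @return an `urn_test_result`: `observed_mean`, `null_means` (list with
#'   `American`, `European`), `p_vs_American`, `p_vs_European`.
#' @export
urn_test <- function(q_american, q_european, observed_mean,
                     group_size = 16, n_draws = 1000, seed = NULL) {
  if (length(q_american) < group_size || length(q_european) < group_size)
    stop("each pool must hold at least group_size individuals")
  if (!is.null(seed)) set.seed(seed)
  draw_means <- function(q) vapply(seq_len(n_draws), function(i)
    mean(sample(q, group_size, replace = FALSE)), 0)
  null_A <- draw_means(q_american)
  null_E <- draw_means(q_european)
  # tail toward the other pool: European lies above American on the Q scale
  if (mean(q_european) >= mean(q_american)) {
    p_A <- (1 + sum(null_A >= observed_mean)) / (n_draws + 1)
    p_E <- (1 + sum(null_E <= observed_mean)) / (n_draws + 1)
  } else {
    p_A <- (1 + sum(null_A <= observed_mean)) / (n_draws + 1)
    p_E <- (1 + sum(null_E >= observed_mean)) / (n_draws + 1)
  }
  structure(list(observed_mean = observed_mean,
                 null_means = list(American = null_A, European = null_E),
                 p_vs_American = p_A, p_vs_European = p_E,
                 group_size = group_size, n_draws = n_draws),
            class = "urn_test_result")
}

boxcox_transform <- function(y, lambda) {
  if (abs(lambda) < 1e-12) log(y) else (y^lambda - 1) / lambda
}

boxcox_lambda_mle <- function(y, grid = seq(-3, 5, by = 0.01)) {
  d <- data.frame(y = y)
  bc <- MASS::boxcox(y ~ 1, data = d, lambda = grid, plotit = FALSE)
  bc$x[which.max(bc$y)]
}

#' Geographic-group comparison of ancestry proportions
#'
#' For each geographic group, a Box-Cox transformation (lambda by maximum
#' likelihood on the group's values) followed by a Shapiro-Wilk normality
#' test; for each pair of groups, a two-sided Wilcoxon rank-sum test on the
#' raw and on the Box-Cox-transformed values (the rank test is invariant to
#' the monotone transform whenever lambda is shared; both are reported).
#'
#' @param q numeric Q values, strictly in (0, 1).
#' @param group geographic group labels (each group of size at least 3).
#' @return list with `groups` (data frame: `group`, `n`, `lambda`,
#'   `shapiro_p`) and `pairs` (data frame: `group1`, `group2`, `p_raw`,
#'   `p_boxcox`).
#' @export
group_cline_test <- function(q, group) {
  stopifnot(length(q) == length(group), all(q > 0), all(q < 1))
  groups <- unique(group)
  sizes <- table(group)
  if (any(sizes < 3)) stop("every group needs at least 3 values")
  per_group <- lapply(groups, function(g) {
    y <- q[group == g]
    lam <- boxcox_lambda_mle(y)
    list(g = g, n = length(y), lambda = lam,
         shapiro_p = stats::shapiro.test(boxcox_transform(y, lam))$p.value)
  })
  gdf <- data.frame(group = vapply(per_group, `[[`, "", "g"),
                    n = vapply(per_group, `[[`, 0L, "n"),
                    lambda = vapply(per_group, `[[`, 0, "lambda"),
                    shapiro_p = vapply(per_group, `[[`, 0, "shapiro_p"))
  cmb <- utils::combn(groups, 2)
  pairs <- lapply(seq_len(ncol(cmb)), function(k) {
    g1 <- cmb[1, k]; g2 <- cmb[2, k]
    y1 <- q[group == g1]; y2 <- q[group == g2]
    lam <- boxcox_lambda_mle(c(y1, y2))
    p_raw <- stats::wilcox.test(y1, y2, exact = FALSE)$p.value
    p_bc <- stats::wilcox.test(boxcox_transform(y1, lam),
                               boxcox_transform(y2, lam),
                               exact = FALSE)$p.value
    data.frame(group1 = g1, group2 = g2, p_raw = p_raw, p_boxcox = p_bc)
  })
  list(groups = gdf, pairs = do.call(rbind, pairs))
}

#' Probability of a prescribed rank order arising by chance
#'
#' For independent groups of `k_i` exchangeable samples each, the chance
#' that every group's samples fall in one prescribed order is
#' `prod_i 1 / k_i!`. Two clines of 3 and 4 ranked samples give
#' `1/(3! 4!) = 1/144`.
#'
#' @param group_counts integer vector of group sizes.
#' @return the probability.
#' @export
rank_order_probability <- function(group_counts) {
  stopifnot(length(group_counts) >= 1, all(group_counts >= 1))
  prod(1 / factorial(group_counts))
}
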
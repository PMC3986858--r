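test_that("allele frequencies match direct tallies and flag empty loci", {
  tab <- genotype_table(c("a", "b"), c("p", "p"), "l",
                        matrix(c(100L, 100L)), matrix(c(100L, 102L)))
  f <- allele_frequencies(tab)[["p"]]$freqs[["l"]]
  expect_equal(unname(f[c("100", "102")]), c(0.75, 0.25))
  # all-missing locus is flagged as NULL
  tab2 <- genotype_table(c("a", "b"), c("p", "p"), c("l1", "l2"),
                         cbind(c(100L, 102L), c(NA, NA)),
                         cbind(c(100L, 102L), c(NA, NA)))
  sp <- allele_frequencies(tab2)[["p"]]
  expect_null(sp$freqs[["l2"]])
  expect_equal(sp$n_genes[2], 0)
  # large pool: frequencies equal brute-force counting
  pools <- cached_pools(42)
  sp <- allele_frequencies(pools$pool_E)[["European"]]
  copies <- c(pools$pool_E$allele1[, 1], pools$pool_E$allele2[, 1])
  expect_equal(sp$freqs[[1]],
               table(copies) / length(copies), ignore_attr = TRUE)
})

test_that("heterozygosities give the unbiased Nei He and HWE closeness", {
  # n = 2 with p = {0.5, 0.5}: He = (4/3) * 0.5 = 2/3
  tab <- genotype_table(c("a", "b"), c("p", "p"), "l",
                        matrix(c(100L, 102L)), matrix(c(100L, 102L)))
  expect_equal(heterozygosities(tab)[["p"]]$He, 2 / 3)
  # monomorphic locus
  mono <- genotype_table(c("a", "b"), c("p", "p"), "l",
                         matrix(c(100L, 100L)), matrix(c(100L, 100L)))
  h <- heterozygosities(mono)[["p"]]
  expect_equal(h$Ho, 0)
  expect_equal(h$He, 0)
  # a large pool drawn under Hardy-Weinberg: Ho tracks He
  pools <- cached_pools(42)
  big <- heterozygosities(pools$pool_E)[["European"]]
  expect_lt(abs(attr(big, "mean_Ho") - attr(big, "mean_He")), 0.02)
})

test_that("Weir-Cockerham theta matches the hand-computed oracle on toys", {
  toy <- toy_two_pop_table()
  expect_equal(fst_weir_cockerham(toy)$theta, oracle_wc_theta(toy),
               tolerance = 1e-12)
  # invariance under allele relabeling
  relab <- toy
  relab$allele1 <- toy$allele1 + 400L
  relab$allele2 <- toy$allele2 + 400L
  relab <- genotype_table(toy$individuals, toy$populations, toy$loci,
                          relab$allele1, relab$allele2)
  expect_equal(fst_weir_cockerham(relab)$theta,
               fst_weir_cockerham(toy)$theta, tolerance = 1e-12)
  # null: two groups carved out of one panmictic pool
  pools <- cached_pools(42)
  half <- rep(c("g1", "g2"), length.out = n_individuals(pools$pool_E))
  theta0 <- fst_weir_cockerham(pools$pool_E, half)$theta
  expect_lt(abs(theta0), 0.01)
  expect_error(fst_weir_cockerham(
    subset_individuals(pools$pool_E, 1:3), c("a", "a", "b")),
    "at least 2")
})

test_that("theta permutation p is significant for the calibrated pools", {
  pools <- cached_pools(42)
  tab <- bind_tables(pools$pool_E, pools$pool_A)
  res <- fst_weir_cockerham(tab, n_perm = 199, seed = 1)
  expect_lt(res$p, 0.05)
  expect_gte(res$p, 1 / 200)
})

test_that("Slatkin RST behaves at its exact anchor points and matches brute force", {
  # complete sorting: sizes 100 vs 120 fixed in the two groups
  fixed <- genotype_table(sprintf("i%d", 1:8), rep(c("A", "B"), each = 4), "l",
                          matrix(rep(c(100L, 120L), each = 4)),
                          matrix(rep(c(100L, 120L), each = 4)))
  expect_equal(rst_slatkin(fixed)$rst, 1)
  # identical size distributions: RST ~ 0 (small negative finite-sample bias)
  same <- genotype_table(sprintf("i%d", 1:40), rep(c("A", "B"), each = 20), "l",
                         matrix(rep(c(100L, 104L), 20)),
                         matrix(rep(c(102L, 106L), 20)))
  expect_lt(abs(rst_slatkin(same)$rst), 0.05)
  # brute-force oracle on the toy table: explicit enumeration of all
  # within-group and cross-group copy pairs
  toy <- toy_two_pop_table()
  num <- den <- 0
  for (l in 1:2) {
    copies <- c(toy$allele1[, l], toy$allele2[, l])
    grp <- rep(toy$populations, 2)
    sqd <- outer(copies, copies, `-`)^2
    same <- outer(grp, grp, `==`)
    ut <- upper.tri(sqd)
    s_w <- mean(sqd[ut & same])
    s_b <- mean(sqd[ut & !same])
    num <- num + (s_b - s_w); den <- den + s_b
  }
  expect_equal(rst_slatkin(toy)$rst, num / den, tolerance = 1e-12)
})

test_that("FST and RST agree when allele sizes carry no extra information", {
  # under the divergence model allele sizes are exchangeable labels, so the
  # two estimators share their expectation; per-locus RST is noisy, so the
  # comparison uses enough loci for the multi-locus values to stabilise
  pools <- gen_species_pools(species_pool_config(n_loci = 60,
                                                 pool_size = 150, seed = 8))
  tab <- bind_tables(pools$pool_E, pools$pool_A)
  fst <- fst_weir_cockerham(tab)$theta
  rst <- rst_slatkin(tab)$rst
  expect_lt(abs(fst - rst), 0.01)
})

test_that("HWE exact test is calibrated under the null and catches deficits", {
  # all-homozygote two-allele group: extreme heterozygote deficit
  n <- 50
  defic <- genotype_table(sprintf("i%d", 1:n), rep("p", n), "l",
                          matrix(rep(c(100L, 102L), length.out = n)),
                          matrix(rep(c(100L, 102L), length.out = n)))
  expect_lt(hwe_test(defic, "p", "l", n_perm = 2000, seed = 1), 0.01)
  # null calibration: genotypes drawn under HWE give roughly uniform p
  set.seed(99)
  ps <- replicate(60, {
    a1 <- sample(c(100L, 102L, 104L), 40, replace = TRUE)
    a2 <- sample(c(100L, 102L, 104L), 40, replace = TRUE)
    tab <- genotype_table(sprintf("i%d", 1:40), rep("p", 40), "l",
                          matrix(a1), matrix(a2))
    hwe_test(tab, "p", "l", n_perm = 300)
  })
  expect_gt(mean(ps), 0.40)
  expect_lt(mean(ps), 0.65)
  expect_gt(min(ps), 0.001)
})

test_that("Bonferroni decisions follow p < alpha/m", {
  expect_false(bonferroni(0.004, alpha = 0.05, m = 21))
  expect_identical(bonferroni(c(0.001, 0.04), alpha = 0.05),
                   c(TRUE, FALSE))
})

test_that("rarefied allelic richness matches its closed form and MC oracle", {
  counts <- c(6, 3, 1)
  expect_equal(allelic_richness_rarefied(counts, 10), 3)  # g = N
  expect_equal(allelic_richness_rarefied(counts, 1), 1)   # one gene, one allele
  mc <- oracle_rarefied_richness(counts, 4, n_rep = 100000, seed = 2)
  expect_lt(abs(allelic_richness_rarefied(counts, 4) - mc), 0.01)
  # randomized property check at 3 MC standard errors
  set.seed(7)
  for (i in 1:5) {
    counts <- sample(1:8, sample(2:6, 1), replace = TRUE)
    g <- sample(seq_len(sum(counts)), 1)
    reps <- 4000
    set.seed(100 + i)
    copies <- rep(seq_along(counts), counts)
    sims <- replicate(reps, length(unique(sample(copies, g))))
    se <- sd(sims) / sqrt(reps)
    expect_lt(abs(allelic_richness_rarefied(counts, g) - mean(sims)),
              3 * se + 1e-9)
  }
})

test_that("private allelic richness has the right anchors and matches MC", {
  # allele 1 fixed in group 1 and absent elsewhere contributes 1 at any g
  cm <- rbind(c(10, 0), c(0, 6), c(0, 4))
  pr <- private_allelic_richness_rarefied(cm, 3)
  expect_equal(pr[1], 1, ignore_attr = TRUE)
  # allele shared and fixed in all groups contributes 0
  cm2 <- rbind(c(10, 10))
  expect_equal(unname(private_allelic_richness_rarefied(cm2, 5)), c(0, 0))
  # 2-group toy vs Monte-Carlo joint subsampling
  cm3 <- rbind(c(5, 2), c(3, 0), c(0, 6), c(2, 2))
  mc <- oracle_private_richness(cm3, 4, n_rep = 40000, seed = 3)
  got <- unname(private_allelic_richness_rarefied(cm3, 4))
  expect_lt(max(abs(got - mc)), 0.02)
})

test_that("chord distance follows the fixed convention exactly", {
  a1 <- afs(list(l1 = c(`100` = 0.5, `102` = 0.5),
                 l2 = c(`200` = 1)))
  a2 <- afs(list(l1 = c(`100` = 0.25, `102` = 0.75),
                 l2 = c(`200` = 0.5, `202` = 0.5)))
  # hand computation: t1 = 1 - (sqrt(.5*.25)+sqrt(.5*.75)), t2 = 1 - sqrt(.5)
  t1 <- 1 - (sqrt(0.125) + sqrt(0.375))
  t2 <- 1 - sqrt(0.5)
  expect_equal(cavalli_sforza_chord(a1, a2), sqrt((t1 + t2) / 2))
  expect_equal(cavalli_sforza_chord(a1, a1), 0)
  # disjoint allele sets at every locus
  b <- afs(list(l1 = c(`104` = 1), l2 = c(`204` = 1)))
  expect_equal(cavalli_sforza_chord(a1, b), 1)
  # symmetry
  expect_equal(cavalli_sforza_chord(a2, a1), cavalli_sforza_chord(a1, a2))
})

test_that("summary_stats emits one row per population with sane values", {
  pools <- cached_pools(42)
  tab <- bind_tables(pools$pool_E, pools$pool_A)
  st <- summary_stats(tab)
  expect_equal(st$population, c("European", "American"))
  expect_true(all(st$Ho >= 0 & st$Ho <= 1))
  expect_true(all(st$He >= 0 & st$He <= 1))
  expect_true(all(st$A_R >= 1))
  expect_equal(st$n, c(100, 100))
})
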
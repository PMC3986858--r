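test_that("offspring alleles always exist in a parent pool (Mendelian)", {
  pools <- cached_pools(42)
  off <- make_f1_population(pools$pool_E, pools$pool_A, n_pairs = 10,
                            n_american_parents = 5,
                            offspring_per_population = 20, seed = 1)
  for (l in seq_len(n_loci(off))) {
    legal <- unique(c(pools$pool_E$allele1[, l], pools$pool_E$allele2[, l],
                      pools$pool_A$allele1[, l], pools$pool_A$allele2[, l]))
    expect_true(all(c(off$allele1[, l], off$allele2[, l]) %in% legal))
  }
})

test_that("pure-parent extremes converge to the matching pool spectrum", {
  pools <- cached_pools(42)
  # all-European parents: offspring frequencies approach pool_E's
  offE <- make_f1_population(pools$pool_E, pools$pool_A, 50, 0, 600, seed = 2)
  offA <- make_f1_population(pools$pool_E, pools$pool_A, 50, 100, 600, seed = 3)
  fE_pool <- allele_frequencies(pools$pool_E, "p")[[1]]
  fA_pool <- allele_frequencies(pools$pool_A, "p")[[1]]
  fE_off <- allele_frequencies(offE, "p")[[1]]
  fA_off <- allele_frequencies(offA, "p")[[1]]
  l1 <- function(f, g) {
    al <- union(names(f), names(g))
    x <- setNames(rep(0, length(al)), al); y <- x
    x[names(f)] <- f; y[names(g)] <- g
    sum(abs(x - y))
  }
  dE <- mean(vapply(seq_len(9), function(l)
    l1(fE_off$freqs[[l]], fE_pool$freqs[[l]]), 0))
  dA <- mean(vapply(seq_len(9), function(l)
    l1(fA_off$freqs[[l]], fA_pool$freqs[[l]]), 0))
  crossEA <- mean(vapply(seq_len(9), function(l)
    l1(fE_off$freqs[[l]], fA_pool$freqs[[l]]), 0))
  expect_lt(dE, crossEA)   # closer to own pool than to the other
  expect_lt(dE, 0.15)      # and close in absolute terms at n = 600
  expect_lt(dA, 0.15)
})

test_that("F1 cline uses the stated American-parent counts per population", {
  pools <- cached_pools(42)
  sc <- cline_scenario(4, seed = 5)
  cl <- build_f1_cline(sc, pools$pool_E, pools$pool_A)
  expect_equal(cl$n_american_parents, (0:11) * 4)
  expect_equal(cl$n_american_parents[12], 44)
  sc1 <- cline_scenario(1, seed = 5)
  cl1 <- build_f1_cline(sc1, pools$pool_E, pools$pool_A)
  expect_equal(cl1$n_american_parents[1], 0)
  expect_true(all(diff(cl1$n_american_parents) >= 0))
  expect_true(all(diff(cl1$n_american_parents) <= 1))
  expect_true(all(diff(cl$realized_fraction) > 0))
})

test_that("cline datasets are bit-reproducible from scenario and seed", {
  pools <- cached_pools(42)
  sc <- cline_scenario(3, seed = 77)
  c1 <- build_f1_cline(sc, pools$pool_E, pools$pool_A)
  c2 <- build_f1_cline(sc, pools$pool_E, pools$pool_A)
  expect_identical(serialize(c1, NULL), serialize(c2, NULL))
  sca <- cline_scenario(3, mode = "admixed_fraction", seed = 77)
  a1 <- build_admixed_cline(sca, pools$afs_A, pools$afs_E)
  a2 <- build_admixed_cline(sca, pools$afs_A, pools$afs_E)
  expect_identical(serialize(a1, NULL), serialize(a2, NULL))
})

test_that("strict F1 pairing produces only first-generation hybrids", {
  pools <- cached_pools(42)
  # all pairs mixed: every offspring has exactly one allele per locus from
  # each species; mean estimated ancestry must sit midway
  off <- make_f1_population(pools$pool_E, pools$pool_A, 50, 50, 100,
                            seed = 4, strict_f1 = TRUE)
  q <- estimate_q_table(off, pools$afs_A, pools$afs_E)
  expect_lt(abs(mean(q$Q) - 0.5), 0.15)
  expect_error(make_f1_population(pools$pool_E, pools$pool_A, 10, 15, 20,
                                  strict_f1 = TRUE), "strict_f1")
})

test_that("admixed genotype sampling follows Binomial(2, Q) per locus", {
  pools <- cached_pools(42)
  # Q = 1: all copies drawn from the European spectrum support
  set.seed(6)
  gE <- sample_admixed_genotype(1, pools$afs_A, pools$afs_E)
  for (l in seq_len(9))
    expect_true(all(as.character(c(gE$a1[l], gE$a2[l])) %in%
                      names(pools$afs_E$freqs[[l]])))
  gA <- sample_admixed_genotype(0, pools$afs_A, pools$afs_E)
  for (l in seq_len(9))
    expect_true(all(as.character(c(gA$a1[l], gA$a2[l])) %in%
                      names(pools$afs_A$freqs[[l]])))
  # binomial mean: disjoint synthetic spectra let origin be read off alleles
  afs_E2 <- afs(lapply(setNames(1:3, c("a", "b", "c")), function(l)
    c(`100` = 1)))
  afs_A2 <- afs(lapply(setNames(1:3, c("a", "b", "c")), function(l)
    c(`200` = 1)))
  set.seed(7)
  n_eur <- replicate(2000, {
    g <- sample_admixed_genotype(0.5, afs_A2, afs_E2)
    sum(c(g$a1, g$a2) == 100)
  })
  se <- sd(n_eur) / sqrt(2000)
  expect_lt(abs(mean(n_eur) - 3), 3 * se)
})

test_that("admixed cline composition follows the increment arithmetic", {
  pools <- cached_pools(42)
  sc <- cline_scenario(3, mode = "admixed_fraction", seed = 8)
  cl <- build_admixed_cline(sc, pools$afs_A, pools$afs_E)
  expect_equal(cl$realized_fraction, (0:11) * 3 / 100)
  expect_equal(sum(cl$true_q[[12]] < 1), 33)
  expect_equal(sum(cl$true_q[[1]] < 1), 0)
  # estimated mean Q of the admixed subset tracks the Q distribution mean
  adm <- which(cl$true_q[[12]] < 1)
  tab12 <- subset_individuals(cl$populations[[12]], adm)
  qhat <- estimate_q_table(tab12, pools$afs_A, pools$afs_E)
  expect_lt(abs(mean(qhat$Q) - 0.5), 0.12)
})

test_that("estimated mean Q declines along the cline in expectation", {
  pools <- cached_pools(42)
  sc <- cline_scenario(4, seed = 9)
  cl <- build_f1_cline(sc, pools$pool_E, pools$pool_A)
  qbar <- vapply(cl$populations, function(p)
    mean(estimate_q_table(p, pools$afs_A, pools$afs_E)$Q), 0)
  # strong south-to-north contrast; adjacent steps may wobble at 9 loci
  fit <- lm(qbar ~ seq_along(qbar))
  expect_lt(coef(fit)[2], 0)
  expect_gt(qbar[1], mean(qbar[10:12]))
})

test_that("cline datasets serialize to Genepop plus manifest and reload", {
  pools <- cached_pools(42)
  sc <- cline_scenario(2, n_populations = 4, seed = 10)
  cl <- build_f1_cline(sc, pools$pool_E, pools$pool_A)
  dir <- withr::local_tempdir()
  write_cline_dataset(cl, dir)
  man <- jsonlite::fromJSON(file.path(dir, "manifest.json"))
  expect_equal(man$scenario$increment_pct, 2)
  expect_equal(length(man$files), 4)
  back <- read_genepop(file.path(dir, man$files[2]))
  expect_identical(back$allele1, cl$populations[[2]]$allele1)
})
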
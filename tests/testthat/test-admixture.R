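test_that("Q estimator agrees with a dense grid search on random genotypes", {
  pools <- cached_pools(42)
  sm <- smoothed <- NULL
  set.seed(21)
  for (i in 1:10) {
    q_true <- runif(1)
    g <- sample_admixed_genotype(q_true, pools$afs_A, pools$afs_E)
    est <- estimate_q(g, pools$afs_A, pools$afs_E)
    # independent oracle: exhaustive 10,001-point grid on the log-likelihood
    sm0 <- eelclines:::smoothed_pool_freqs(pools$afs_A, pools$afs_E)
    pA <- pE <- c()
    for (l in seq_along(sm0)) {
      for (al in c(g$a1[l], g$a2[l])) {
        j <- match(al, sm0[[l]]$alleles)
        pA <- c(pA, sm0[[l]]$pA[j]); pE <- c(pE, sm0[[l]]$pE[j])
      }
    }
    grid <- seq(0, 1, length.out = 10001)
    ll <- vapply(grid, function(q) sum(log(q * pE + (1 - q) * pA)), 0)
    expect_lt(abs(est$Q - grid[which.max(ll)]), 1e-4)
  }
})

test_that("private-allele dominance drives Q to the matching pool", {
  # two pools with fully disjoint alleles: all copies European-private
  afs_E <- afs(lapply(setNames(1:9, sprintf("L%d", 1:9)), function(l)
    c(`100` = 0.5, `102` = 0.5)))
  afs_A <- afs(lapply(setNames(1:9, sprintf("L%d", 1:9)), function(l)
    c(`140` = 0.5, `142` = 0.5)))
  g <- list(a1 = rep(100L, 9), a2 = rep(102L, 9))
  est <- estimate_q(g, afs_A, afs_E)
  expect_gt(est$Q, 0.95)
  expect_equal(est$purity, "pure_European")
})

test_that("Q estimates are label-symmetric and error on empty genotypes", {
  pools <- cached_pools(42)
  set.seed(3)
  for (i in 1:5) {
    g <- sample_admixed_genotype(runif(1), pools$afs_A, pools$afs_E)
    qEA <- estimate_q(g, pools$afs_A, pools$afs_E)$Q
    qAE <- estimate_q(g, pools$afs_E, pools$afs_A)$Q
    expect_lt(abs(qEA + qAE - 1), 1e-4)
  }
  empty <- list(a1 = rep(NA_integer_, 9), a2 = rep(NA_integer_, 9))
  expect_error(estimate_q(empty, pools$afs_A, pools$afs_E), "missing")
})

test_that("estimator recovers true ancestry on well-differentiated pools", {
  # recovery is validated where the 9 loci actually carry ancestry
  # information; at the weak inter-species FST of the study system the
  # bounded MLE is attenuated toward 0.5 (checked separately below)
  pools <- gen_species_pools(species_pool_config(target_fst = 0.15, seed = 1),
                             tol = 0.01)
  sm <- eelclines:::smoothed_pool_freqs(pools$afs_A, pools$afs_E)
  set.seed(17)
  means <- vapply(c(0.25, 0.5, 0.75), function(q_true) {
    qs <- vapply(1:200, function(i) {
      g <- sample_admixed_genotype(q_true, pools$afs_A, pools$afs_E)
      estimate_q(g, pools$afs_A, pools$afs_E, smoothed = sm)$Q
    }, 0)
    mean(qs)
  }, 0)
  expect_true(all(diff(means) > 0))
  expect_lt(max(abs(means - c(0.25, 0.5, 0.75))), 0.05)
})

test_that("estimated ancestry stays monotone at the study's weak divergence", {
  pools <- cached_pools(42)
  sm <- eelclines:::smoothed_pool_freqs(pools$afs_A, pools$afs_E)
  set.seed(18)
  means <- vapply(c(0.1, 0.5, 0.9), function(q_true) {
    mean(vapply(1:150, function(i) {
      g <- sample_admixed_genotype(q_true, pools$afs_A, pools$afs_E)
      estimate_q(g, pools$afs_A, pools$afs_E, smoothed = sm)$Q
    }, 0))
  }, 0)
  expect_true(all(diff(means) > 0))
  # q = 0.5 is unbiased by symmetry even when the extremes attenuate
  expect_lt(abs(means[2] - 0.5), 0.1)
})

test_that("purity classification uses the 0.9 / 0.1 cutoffs", {
  expect_equal(classify_purity(0.95), "pure_European")
  expect_equal(classify_purity(0.05), "pure_American")
  expect_equal(classify_purity(0.5), "admixed")
  expect_equal(classify_purity(0.9), "admixed")
  expect_error(classify_purity(1.2))
})

test_that("urn test centres on the pool mean and separates distant groups", {
  set.seed(8)
  qa <- pmin(pmax(rnorm(200, 0.05, 0.05), 0), 1)
  qe <- pmin(pmax(rnorm(200, 0.95, 0.05), 0), 1)
  # observed mean far from both pools: both tails extreme
  res <- urn_test(qa, qe, observed_mean = 0.40, seed = 1)
  expect_lt(res$p_vs_American, 0.001 + 1 / 1001)
  expect_lt(res$p_vs_European, 0.001 + 1 / 1001)
  expect_equal(length(res$null_means$American), 1000)
  # observed mean at the pool mean: p near 0.5
  res2 <- urn_test(qa, qe, observed_mean = mean(qe), seed = 2)
  expect_gt(res2$p_vs_European, 0.35)
  expect_lt(res2$p_vs_European, 0.65)
  # estimator floor
  expect_gte(res$p_vs_American, 1 / 1001)
  expect_error(urn_test(qa[1:10], qe, 0.4), "group_size")
})

test_that("urn null means have the sampling moments of a 16-mean", {
  set.seed(9)
  qe <- runif(300, 0.7, 1)
  res <- urn_test(runif(300, 0, 0.3), qe, observed_mean = 0.5,
                  group_size = 16, n_draws = 2000, seed = 3)
  nm <- res$null_means$European
  expect_lt(abs(mean(nm) - mean(qe)), 3 * sd(nm) / sqrt(2000))
  # without-replacement draws of 16 from 300: sd ~ (sd/sqrt(16)) * fpc
  fpc <- sqrt((300 - 16) / (300 - 1))
  expect_lt(abs(sd(nm) - sd(qe) / 4 * fpc), 0.15 * sd(qe) / 4)
})

test_that("empirical Q distributions histogram correctly on the fixed bins", {
  d <- fit_q_distribution(c(0.52, 0.53, 0.51))
  expect_equal(d$prob[d$lower == 0.50], 1)
  d2 <- fit_q_distribution(c(0.12, 0.88))
  expect_equal(sort(d2$prob[d2$prob > 0]), c(0.5, 0.5))
  expect_error(fit_q_distribution(c(0.05, 0.95)), "no Q values")
  # large sample recovers the generating probabilities within 3 se
  gen <- q_distribution(setNames(c(0.2, 0.5, 0.3), c(0.10, 0.45, 0.80)))
  set.seed(4)
  qs <- sample_q(gen, 20000)
  fit <- fit_q_distribution(qs)
  for (k in seq_along(gen$lower)) {
    p <- gen$prob[k]
    se <- sqrt(p * (1 - p) / 20000)
    expect_lt(abs(fit$prob[fit$lower == gen$lower[k]] - p), 3 * se + 1e-6)
  }
})

test_that("geographic group comparison detects shifted groups, not null ones", {
  set.seed(12)
  # same distribution: p should be comfortably non-extreme on average
  q0 <- c(rbeta(50, 5, 3), rbeta(50, 5, 3), rbeta(50, 5, 3))
  g0 <- rep(c("S", "M", "N"), each = 50)
  res0 <- group_cline_test(q0, g0)
  expect_equal(nrow(res0$pairs), 3)
  expect_gt(max(res0$pairs$p_raw), 0.05)
  # groups shifted by ~2 sd: strongly significant
  q1 <- c(rbeta(50, 8, 2), rbeta(50, 2, 8))
  res1 <- group_cline_test(q1, rep(c("S", "N"), each = 50))
  expect_lt(res1$pairs$p_raw, 0.01)
  expect_lt(res1$pairs$p_boxcox, 0.01)
  expect_true(all(is.finite(res1$groups$lambda)))
  expect_error(group_cline_test(c(0.5, 0.6, 0.7, 0.2),
                                c("a", "a", "a", "b")), "at least 3")
})

test_that("null calibration: group comparison p-values are roughly uniform", {
  set.seed(31)
  ps <- replicate(60, {
    q <- rbeta(40, 4, 4)
    group_cline_test(q, rep(c("a", "b"), each = 20))$pairs$p_raw
  })
  expect_gt(mean(ps), 0.35)
  expect_lt(mean(ps), 0.65)
  expect_gt(suppressWarnings(ks.test(ps, "punif")$p.value), 0.01)
})

test_that("rank-order probability multiplies inverse factorials", {
  expect_equal(rank_order_probability(c(3, 4)), 1 / 144)
  expect_equal(rank_order_probability(1), 1)
  expect_equal(rank_order_probability(c(2, 2)), 0.25)
  expect_equal(round(rank_order_probability(c(3, 4)), 3), 0.007)
})
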
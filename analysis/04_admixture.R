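#!/usr/bin/env Rscript
# Supervised ancestry analysis: Q for every pool individual and for a
# simulated group of 16 F1 "suspects"; the 16 x 1000 urn permutation test;
# the empirical Q-bin distribution of admixed individuals; and the
# rank-order probability of the two observed geographic clines.
# Writes results/admixture/.

suppressPackageStartupMessages(library(eelclines))
args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args) >= 1) as.integer(args[1]) else 42L
dir.create("results/admixture", showWarnings = FALSE, recursive = TRUE)
seeds <- split_seed(seed, 4)

tab <- read_genepop("results/inputs/species_pools.gen")
pops <- unique(tab$populations)  # pop1 = European, pop2 = American
pool_E <- subset_individuals(tab, tab$populations == pops[1])
pool_A <- subset_individuals(tab, tab$populations == pops[2])
afs_E <- allele_frequencies(pool_E, "E")[[1]]
afs_A <- allele_frequencies(pool_A, "A")[[1]]

q_pools <- estimate_q_table(tab, afs_A, afs_E)
q_pools$population <- ifelse(q_pools$population == pops[1],
                             "European", "American")
write.csv(q_pools, "results/admixture/pool_q_values.csv", row.names = FALSE)
cat(sprintf("pool mean Q: European %.3f, American %.3f\n",
            mean(q_pools$Q[q_pools$population == "European"]),
            mean(q_pools$Q[q_pools$population == "American"])))

# 16 suspects: F1 offspring of strict inter-species crosses
f1 <- make_f1_population(pool_E, pool_A, n_pairs = 16,
                         n_american_parents = 16,
                         offspring_per_population = 16,
                         seed = seeds[1], strict_f1 = TRUE,
                         pop_label = "suspects")
q_susp <- estimate_q_table(f1, afs_A, afs_E)
write.csv(q_susp, "results/admixture/suspect_q_values.csv", row.names = FALSE)
cat(sprintf("suspect group mean Q = %.3f\n", mean(q_susp$Q)))

urn <- urn_test(q_pools$Q[q_pools$population == "American"],
                q_pools$Q[q_pools$population == "European"],
                observed_mean = mean(q_susp$Q),
                group_size = 16, n_draws = 1000, seed = seeds[2])
cat(sprintf("urn test: p vs American %.4g, p vs European %.4g\n",
            urn$p_vs_American, urn$p_vs_European))
write.csv(data.frame(pool = rep(c("American", "European"), each = 1000),
                     null_mean = c(urn$null_means$American,
                                   urn$null_means$European)),
          "results/admixture/urn_null_means.csv", row.names = FALSE)
write.csv(data.frame(observed_mean = urn$observed_mean,
                     p_vs_American = urn$p_vs_American,
                     p_vs_European = urn$p_vs_European),
          "results/admixture/urn_test.csv", row.names = FALSE)

adm <- q_pools$Q[q_pools$purity == "admixed"]
if (length(adm) >= 5) {
  qd <- fit_q_distribution(adm)
  write.csv(data.frame(bin_lower = qd$lower, probability = qd$prob),
            "results/admixture/q_distribution.csv", row.names = FALSE)
  cat(sprintf("admixed Q distribution: %d values, mean %.3f\n",
              length(adm), mean_q(qd)))
}

# the two clines: 3 ranked American groups, 4 ranked European groups
p_rank <- rank_order_probability(c(3, 4))
cat(sprintf("rank-order probability of both clines by chance: %.5f (1/%d)\n",
            p_rank, round(1 / p_rank)))
write.csv(data.frame(group_counts = "3+4", probability = p_rank),
          "results/admixture/rank_order_probability.csv", row.names = FALSE)
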
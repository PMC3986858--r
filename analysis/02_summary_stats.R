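#!/usr/bin/env Rscript
# Classical summary statistics of the generated species pools: per-pool n,
# Ho, He, rarefied allelic richness and F_IS; inter-species FST and RST
# with permutation significance; per-locus Hardy-Weinberg exact tests with
# Bonferroni correction. Reads results/inputs/, writes results/stats/.

suppressPackageStartupMessages(library(eelclines))
args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args) >= 1) as.integer(args[1]) else 42L
dir.create("results/stats", showWarnings = FALSE, recursive = TRUE)

tab <- read_genepop("results/inputs/species_pools.gen")

st <- summary_stats(tab)
write.csv(st, "results/stats/per_population_stats.csv", row.names = FALSE)
print(st, digits = 3)

fst <- fst_weir_cockerham(tab, n_perm = 999, seed = split_seed(seed, 2)[1])
rst <- rst_slatkin(tab, n_perm = 999, seed = split_seed(seed, 2)[2])
cat(sprintf("inter-species FST = %.4f (p = %.4g), RST = %.4f (p = %.4g)\n",
            fst$theta, fst$p, rst$rst, rst$p))
write.csv(data.frame(statistic = c("FST", "RST"),
                     value = c(fst$theta, rst$rst),
                     p = c(fst$p, rst$p), n_perm = 999),
          "results/stats/differentiation.csv", row.names = FALSE)

hwe <- expand.grid(population = unique(tab$populations), locus = tab$loci,
                   stringsAsFactors = FALSE)
hseeds <- split_seed(seed + 1, nrow(hwe))
hwe$p <- vapply(seq_len(nrow(hwe)), function(i)
  hwe_test(tab, hwe$population[i], hwe$locus[i], n_perm = 2000,
           seed = hseeds[i]), 0)
hwe$significant_bonferroni <- bonferroni(hwe$p, alpha = 0.05)
write.csv(hwe, "results/stats/hwe_tests.csv", row.names = FALSE)
cat(sprintf("HWE: %d of %d population x locus tests significant after Bonferroni\n",
            sum(hwe$significant_bonferroni), nrow(hwe)))
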
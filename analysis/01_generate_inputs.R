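#!/usr/bin/env Rscript
# Generate every input the analysis needs: two calibrated microsatellite
# species pools, the two-cluster cytb haplotype set, and the coastline
# transect distance matrix. Writes Genepop / FASTA / PHYLIP files plus a
# manifest under results/inputs/.

suppressPackageStartupMessages(library(eelclines))
args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args) >= 1) as.integer(args[1]) else 42L
out <- "results/inputs"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

seeds <- split_seed(seed, 3)

pools <- gen_species_pools(species_pool_config(seed = seeds[1]))
cat(sprintf("species pools: realized FST = %.4f (target 0.0146, F = %.4f)\n",
            pools$realized_fst, pools$f))
write_genepop(bind_tables(pools$pool_E, pools$pool_A),
              file.path(out, "species_pools.gen"),
              title = "synthetic North Atlantic eel species pools")

aln <- gen_cytb_haplotypes(cytb_config(seed = seeds[2]))
cat(sprintf("cytb haplotypes: %d American, %d European, %d bp\n",
            sum(aln$species == "American"), sum(aln$species == "European"),
            nchar(aln$seqs[1])))
write_fasta(aln, file.path(out, "cytb_haplotypes.fasta"))

geo <- gen_geography(geography_config(seed = seeds[3]))
cat(sprintf("geography: %d sites, max distance %.0f km\n",
            nrow(geo), max(geo)))
write_distance_matrix(geo, file.path(out, "geography.phylip"))
write_distance_matrix(geo, file.path(out, "geography.csv"), format = "csv")

manifest <- list(seed = seed, sub_seeds = seeds,
                 realized_fst = pools$realized_fst, f = pools$f,
                 files = c("species_pools.gen", "cytb_haplotypes.fasta",
                           "geography.phylip", "geography.csv"))
jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                     auto_unbox = TRUE, digits = NA)
cat("inputs written to", out, "\n")
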
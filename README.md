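# eelclines

Can a latitudinal cline of inter-species hybridization, by itself, generate
an isolation-by-distance (IBD) signal in an otherwise panmictic species?

The two North Atlantic eels — the European eel (*Anguilla anguilla*) and
the American eel (*A. rostrata*) — hybridize at low rates, and their
hybrids accumulate toward northern latitudes (Iceland above all). European
eel microsatellite surveys have repeatedly reported weak but significant
IBD along the European coastline. `eelclines` implements, as a tested R
package plus a numbered analysis workflow, the computational machinery to
ask whether a south-to-north hybridization cline alone explains such a
signal:

* **Synthetic study system** — two diploid microsatellite species pools
  (9 loci, 10–18 alleles each, mean observed heterozygosity ≈ 0.78)
  generated under a Balding–Nichols divergence model and calibrated by
  bisection so the realized inter-species Weir–Cockerham
  F<sub>ST</sub> matches the study system's 0.0146 (± 0.005); a
  two-cluster cytochrome *b* haplotype set in which only the American
  cluster carries the diagnostic HinfI site (`G^ANTC`); and a
  12-site coastline transect distance matrix.
* **Species diagnosis** — in-silico HinfI RFLP (American iff ≥ 1 cut
  site) and a deterministic Hamming-distance minimum-spanning haplotype
  network.
* **Supervised admixture** — per-individual ancestry proportion *Q*
  toward the European pool by concave maximum likelihood over two known
  pool spectra (smoothed counts), purity classification at the *Q* = 0.9 /
  0.1 cutoffs, a 16 × 1000 urn permutation test for group intermediacy,
  Q-bin distributions (0.05-wide bins on [0.10, 0.90]), geographic-group
  comparisons (Box-Cox, Shapiro–Wilk, Wilcoxon), and the rank-order
  probability of two jointly ordered clines (1/(3!·4!) = 1/144).
* **Cline simulation** — 12 virtual populations whose hybridization rises
  by 1–4% per step, built either by Mendelian matings with a growing
  share of American parents (F1 mode) or by binomial/multinomial sampling
  of admixed genotypes at drawn *Q* values (admixed mode).
* **IBD readout** — Cavalli-Sforza & Edwards chord distances among
  populations, Mantel tests (one-tailed permutation), replicate
  aggregation, linear (*r*) and exponential (*b*) regressions on the
  gene-flow level, and inversion of the *r* fit to state how much gene
  flow a target IBD correlation requires (for 12 populations: mean hybrid
  fraction = 5.5 × increment, maximum = 11 × increment).
* **Summary statistics** — Ho/He, F<sub>ST</sub>/R<sub>ST</sub> with
  permutation p-values, Monte-Carlo exact Hardy–Weinberg tests with
  Bonferroni correction, rarefied allelic and private-allele richness.

File formats: Genepop (2/3-digit, lossless round trip), FASTA
(via Biostrings), PHYLIP-style square and CSV distance matrices, YAML/JSON
configs.

## Worked example

```r
library(eelclines)

# calibrated species pools
pools <- gen_species_pools(species_pool_config(seed = 42))
pools$realized_fst
#> [1] 0.01448377

# a 4%-per-step F1 hybridization cline over 12 virtual populations
cl  <- build_f1_cline(cline_scenario(4, seed = 1),
                      pools$pool_E, pools$pool_A)
geo <- gen_geography(geography_config())       # 12 sites, 500 km apart
mantel_test(genetic_distance_matrix(cl), geo, n_perm = 999, seed = 1)
#> <mantel_result> r = 0.5449, b = 6.44e-06, p = 0.001 (999 permutations)

# the full experiment: increments 0-4%, 20 paired replicates each
ex <- run_ibd_experiment(increments = c(0, 1, 2, 3, 4),
                         mode = "f1_parents", pools = pools,
                         geography = geo, n_replicates = 20,
                         n_perm = 999, seed = 1)
round(ex$summary$mean_r, 3)
#> [1] -0.010  0.075  0.237  0.419  0.596
```

Mean Mantel *r* climbs from ≈ 0 (no cline; the IBD null) to ≈ 0.60 at a
4%-per-step cline — a hybridization gradient alone manufactures a strong
IBD signal. The admixed-genotype mode (`mode = "admixed_fraction"`)
reproduces the same ordering at roughly half the per-step effect, since an
admixed genotype carries about half the foreign alleles of an F1's
American parent share.

The numbered scripts under `analysis/` run the whole workflow
(`01_generate_inputs.R` → `05_cline_ibd.R`), printing what each step found
and writing tables under `results/`:

```sh
Rscript analysis/01_generate_inputs.R 42
Rscript analysis/02_summary_stats.R   42
Rscript analysis/03_species_id.R
Rscript analysis/04_admixture.R       42
Rscript analysis/05_cline_ibd.R       42
```

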
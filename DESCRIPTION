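Package: eelclines
Title: Hybridization Clines, Admixture and Isolation-by-Distance in North
    Atlantic Eels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis toolkit for latitudinal inter-species
    hybridization clines between the two North Atlantic eel gene pools and
    their effect on isolation-by-distance (IBD) signals. Generates calibrated
    synthetic microsatellite species pools and mitochondrial cytb haplotypes,
    performs in-silico HinfI RFLP species diagnosis and minimum-spanning
    haplotype networks, estimates per-individual ancestry proportions by
    supervised two-pool maximum likelihood, simulates F1-hybrid and
    admixed-genotype clines across virtual populations, and quantifies the
    resulting IBD via Cavalli-Sforza and Edwards chord distances, Mantel
    tests and gene-flow extrapolation. Includes classical summary statistics
    (heterozygosities, Weir-Cockerham FST, Slatkin RST, Hardy-Weinberg exact
    tests, rarefied allelic and private-allele richness) and Genepop, FASTA
    and distance-matrix readers and writers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    jsonlite,
    yaml,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    vegan,
    igraph,
    withr
Config/testthat/edition: 3
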
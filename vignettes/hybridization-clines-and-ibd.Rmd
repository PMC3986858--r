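---
title: "Hybridization clines, supervised admixture and isolation-by-distance in North Atlantic eels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hybridization clines, supervised admixture and isolation-by-distance in North Atlantic eels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eelclines)
```

## The scientific question

The two North Atlantic eel species — the European eel (*Anguilla anguilla*)
and the American eel (*A. rostrata*) — spawn in overlapping areas of the
Sargasso Sea, hybridize at low rates, and deposit their hybrids
preferentially at northern latitudes (Iceland most of all). European eel
populations have repeatedly shown weak but significant isolation-by-distance
(IBD): genetic distance among sampling sites increases with coastline
distance. `eelclines` asks a simple, consequential question: **can a
south-to-north cline of inter-species hybridization, by itself, generate an
IBD signal of the observed strength in an otherwise panmictic species?**

The package provides every computational step needed to pose and answer
that question on synthetic data whose statistical structure matches the
study system:

1. a generator for two calibrated microsatellite species gene pools, mtDNA
   haplotype sets with a diagnostic restriction site, and a coastline-like
   geographic distance matrix (`gen_species_pools()`,
   `gen_cytb_haplotypes()`, `gen_geography()`);
2. mitochondrial species diagnosis by in-silico HinfI RFLP and a
   minimum-spanning haplotype network (`classify_species()`, `build_msn()`);
3. supervised two-pool maximum-likelihood ancestry estimation with the
   field's Q = 0.9 purity convention, an urn-model permutation test for
   group intermediacy, and geographic-group comparisons
   (`estimate_q()`, `urn_test()`, `group_cline_test()`,
   `rank_order_probability()`);
4. two cline simulators — F1-hybrid matings and admixed-genotype sampling —
   and the IBD readout: chord distances, Mantel tests, and regression of
   IBD strength on gene-flow level with extrapolation
   (`build_f1_cline()`, `build_admixed_cline()`, `mantel_test()`,
   `fit_gene_flow_curves()`, `extrapolate_gene_flow()`);
5. classical summary statistics: observed/expected heterozygosity,
   Weir–Cockerham $F_{ST}$, an allele-size $R_{ST}$, Hardy–Weinberg exact
   tests with Bonferroni correction, and rarefied allelic and
   private-allele richness.

The numbered scripts under `analysis/` run these pieces as a narrative
workflow and write their tables under `results/`.

## The synthetic species pools

Real genotypes of the source study are not redistributable, so the
generator emulates their published structure: nine dinucleotide
microsatellite loci, 10–18 alleles per locus, mean observed heterozygosity
near 0.78, and a multi-locus inter-species $F_{ST}$ of 0.0146.

The divergence model is Balding–Nichols: each locus has a shared ancestral
spectrum $p$ drawn from a symmetric Dirichlet, and each species' spectrum is
drawn from $\mathrm{Dirichlet}\!\big(p\,(1-F)/F\big)$, so $F$ controls the
expected differentiation without simulating generations. Genotypes are
drawn under Hardy–Weinberg within species. Two calibration choices matter:

* **Ancestral concentration** (`ancestral_alpha`, default 0.4). For a
  symmetric Dirichlet with concentration $\alpha$ over $K$ alleles the
  expected homozygosity is $(\alpha + 1)/(K\alpha + 1)$; at $K \approx 14$,
  $\alpha = 0.4$ gives expected heterozygosity $\approx 0.78$, the study
  system's mean. Two-allele configurations need a larger $\alpha$ (balanced
  ancestral frequencies) to stay polymorphic under strong divergence.
* **$F$ calibration.** $F$ is not reported by any study; the quantity that
  is reported is the realized $F_{ST}$. The generator therefore bisects on
  $F$ until the realized multi-locus Weir–Cockerham $\theta$ between the two
  emitted pools is within ±0.005 of the target (0.0146 by default). All
  random inputs are drawn once as uniforms and pushed through inverse CDFs,
  which makes realized $F_{ST}$ a continuous function of $F$ for a fixed
  seed; bisection is then reliable, and output is bit-reproducible from the
  config. If the target is unreachable (e.g. few near-fixed loci), the
  generator stops with the achieved value in the error message.

The mtDNA generator builds a motif-free European consensus, derives an
American consensus from it by a fixed number of substitutions plus an
implanted `GACTC` HinfI site, and radiates haplotypes within each cluster.
Every American sequence retains the diagnostic site; no European sequence
contains `GANTC` anywhere; the two clusters are separated by more
substitutions than any within-cluster pair, which is what makes the
minimum-spanning network's single inter-species edge its heaviest edge.
The amplicon screened by RFLP (362 bp) and the alignment used for networks
(276 bp) have separate lengths because the laboratory assay and the
published network used different fragments; the generator exposes both
rather than reconciling them.

Geography is an idealised 1-D coastline: 12 sites, 500 km apart by default
(an `irregular` option draws log-normal segment lengths). The real study's
distance matrix is unpublished; only the transect structure matters for the
simulation findings, and Mantel correlations are invariant to the overall
scale.

## Supervised ancestry estimation

With $K = 2$ fixed by the biology, ancestry needs no MCMC: given the two
pool spectra, the log-likelihood of an individual's ancestry proportion $q$
(toward the European pool) is

$$\ell(q) = \sum_{\text{allele copies } a} \log\big(q\,p_E(a) + (1-q)\,p_A(a)\big),$$

which is concave in $q$; Brent's method finds the maximum to $10^{-6}$.
Pool frequencies are smoothed by adding 0.5 to every observed-allele count
plus one shared pseudo-allele per locus, so a private allele is strongly
informative but never infinitely so. Sensitivity to the constant is mild:
it shifts individual $\hat Q$ by at most a few times $0.5/(2n)$ per private
allele, about 0.01 at the default pool sizes. Purity follows the field's
convention: pure European for $Q > 0.9$, pure American for $Q < 0.1$,
admixed otherwise.

**What the estimator can and cannot do at the study's divergence.** At
$F_{ST} \approx 0.015$ with nine loci, a single genotype carries little
ancestry information: $\hat Q$ has a standard deviation near 0.4 and piles
up at the [0, 1] boundaries. Because the boundaries truncate a wide
distribution, mean $\hat Q$ is attenuated toward 0.5 at extreme true
values (a true 0.1 averages near 0.3). This is a property of *any*
bounded estimator at this information level, not of the implementation:
on well-differentiated pools ($F_{ST}$ = 0.15) the same estimator recovers
true mixing proportions across 0.1–0.9 with bias below 0.03. The symmetric
case $q = 0.5$ — the F1-hybrid expectation on which the intermediacy
argument rests — is unbiased at any divergence, by symmetry. The test
suite checks exactly these three statements, and the estimator's optimum is
cross-checked against an exhaustive grid search.

A related subtlety drives the design of the F1 check: conditioned on one
realized pool pair, mean $\hat Q$ of F1s can sit up to ~0.05 away from 0.5,
because the particular allele-frequency asymmetries of that pair tilt the
likelihood. Averaging over independent generator realizations (ten pool
pairs of 50 F1 offspring each) removes the conditioning and measures the
estimator property itself.

The urn test mirrors the published procedure: groups of 16 ancestry values
drawn 1000 times without replacement from each species pool; the suspect
group's mean is compared one-tailed against each pool's null distribution,
the tail pointing toward the opposing pool (the direction in which a hybrid
group must deviate). The tail convention is fixed here because the source
procedure does not state one.

## Cline simulation

Both simulators build 12 virtual populations on the transect, population 1
purest, hybridization rising by a per-population increment of 1–4% (0% is
the null control).

* **F1 mode**: 100 parent slots (50 pairs) are filled with replacement from
  the European pool; $(k-1)\cdot\text{increment}$ of them are replaced by
  American parents in population $k$; slots pair randomly and each pair
  contributes equally to 100 Mendelian offspring. Random pairing can mate
  two American parents at high increments; a `strict_f1` flag forces
  mixed pairs when guaranteed F1s are wanted. Parent slots are replaced
  uniformly at random (the original procedure does not state a pairwise
  rule).
* **Admixed mode**: population $k$ holds $(k-1)\cdot\text{increment}$
  admixed individuals per 100; each admixed individual draws its $Q$ from a
  discretised distribution over 0.05-wide bins on [0.10, 0.90] (bin
  midpoints; the within-bin rule is unstated in the source, and the
  midpoint is the neutral choice), then draws, per locus, a
  $\mathrm{Binomial}(2, Q)$ number of European-origin copies and the allele
  of each copy from the matching spectrum. The remaining individuals are
  pure European ($Q = 1$). The default $Q$ distribution is uniform over
  the 16 bins (mean 0.5); an empirical distribution can be supplied via
  `fit_q_distribution()`.

Offspring counts are unified at 100 per population in both modes so the two
analyses are sample-size comparable. Percentages map to counts by rounding
half up, and realized fractions are recorded so regressions use realized,
not nominal, values.

**Common random numbers.** Both simulators draw their random inputs in a
fixed-consumption order, so datasets built at different increments from the
same seed share parents, pairings, transmissions and $Q$ draws, differing
only through the hybridization level. Increment contrasts are therefore
paired, and seed-averaged orderings (e.g. "mean Mantel $r$ rises with the
increment") stabilise at moderate replicate counts. Replicate seeds come
from a single global seed through a documented splitting rule
(`split_seed()`), so any run can be reproduced in isolation.

## The IBD readout

Pairwise genetic distances among virtual populations are
Cavalli-Sforza & Edwards chord distances,
$D_{CE} = \sqrt{\tfrac1L \sum_l \big(1 - \sum_a \sqrt{p_{1la}p_{2la}}\big)}$.
Programs differ in their normalisation constants ($2/\pi$, per-locus
factors); this package fixes the square-root-of-mean-terms form above,
because every downstream use (Mantel correlation, regression slopes as a
function of gene-flow level) is invariant to a global scale factor, and a
fixed documented convention beats a configurable one.

The Mantel test correlates lower triangles, reports the least-squares slope
$b$ of genetic on geographic distance, and permutes rows/columns of the
genetic matrix simultaneously; the p-value is one-tailed toward positive
association (IBD is directional), with 9,999 permutations by default
(999 in the replicated experiments, where p-value resolution below 0.001
is not needed). The implementation is cross-checked against an exhaustive
enumeration at five populations and against an independent community
implementation.

Across increments, mean $r$ is regressed linearly on the per-step gene-flow
level and mean $b$ exponentially (log-linear when all slopes share a sign),
matching the curve families that described the original experiment best.
Inverting the linear fit at a target $r$ yields the implied per-step
increment; for a 12-population transect the mean per-population hybrid
fraction is 5.5 times and the maximum 11 times that increment, which is how
a statement like "increment 2.7% ⇒ ~15% mean, ~30% maximum hybrid fraction"
is produced. Extrapolations beyond the simulated $r$ range are flagged.

## Statistical conventions and numerical choices

* Multi-locus $F_{ST}$ and $R_{ST}$ are ratios of summed variance
  components, never means of per-locus ratios; negative per-locus
  estimates are retained.
* $R_{ST}$ uses the among-group mean squared allele-size difference as its
  denominator (AMOVA-consistent). The often-quoted pooled-sample
  denominator halves the between-group signal when only two groups are
  compared, which would break the $F_{ST}$–$R_{ST}$ congruence that
  characterises this marker system; the among-group form matches
  Weir–Cockerham $\theta$ in expectation when allele sizes are
  exchangeable labels. Per-locus $R_{ST}$ is noisy; congruence is asserted
  on many-locus tables.
* Hardy–Weinberg testing is a Monte-Carlo exact test (gene copies shuffled
  within the group, Guo–Thompson table-probability ordering), 10,000
  shuffles by default — full enumeration is impractical for many-allele
  microsatellite loci. Bonferroni correction rejects at $p < \alpha/m$.
* Rarefaction uses the hypergeometric closed forms for allelic and
  private-allele richness, computed with `lchoose` for numerical stability.
* Box-Cox $\lambda$ for the geographic-group tests is chosen by maximum
  likelihood per group (ancestry proportions are strictly positive, so no
  offset is needed); normality is then checked with Shapiro–Wilk, and
  group pairs are compared with two-sided Wilcoxon rank-sum tests on raw
  and transformed values.
* The minimum-spanning haplotype network is a Hamming-distance MST
  (Kruskal with union–find); candidate edges sort by (weight,
  lexicographic node pair), which makes tie-breaking deterministic.
  Statistical-parsimony refinements (95% connection limits, retained
  loops) are out of scope, as is likelihood-based resolution of ambiguous
  connections. Alignment positions with `N` in either sequence are
  skipped in distances; an `N` never produces a restriction-site call.

## Problem sizes and what the tests show

The replicated experiments in the test suite and acceptance script use 12
populations × 100 individuals × 9 loci per dataset, 20 replicates per
increment in F1 mode and 200 in admixed mode (the admixed per-step effect
is roughly half the F1 effect, so its seed average needs more replicates),
with 999 Mantel permutations per test. These sizes keep a full run in the
minutes range on a single core while leaving the qualitative contrasts
well resolved.

The synthetic data reproduce the *statistical* structure the analysis
depends on — differentiation level, heterozygosity, allele counts, cluster
separation of mtDNA, transect geometry. They do not reproduce null
alleles, locus-specific mutation-rate variation, linkage, temporal
recruitment waves, or real coastline geometry. Passing tests therefore
show that the pipeline's inferences behave correctly on data satisfying
its model assumptions; they do not by themselves certify behaviour on real
genotypes, where those complications exist (the source study handled null
alleles with dedicated corrections that are deliberately out of scope
here).

## Known limitations

* The supervised estimator requires known, reasonably pure reference
  pools; it does not do unsupervised clustering or pick the number of
  populations.
* Single-generation simulation only: no backcross dynamics, no selection
  on hybrids, no explicit distinction between admixture and introgression
  clines.
* At the study system's divergence, individual ancestry estimates are
  noisy by necessity; only group-level quantities (means over many
  individuals, urn-test contrasts) are interpretable, and the package's
  own tests treat them that way.
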
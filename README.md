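# rangediv

Range-wide population-genetics analysis for co-dominant markers: given
microsatellite genotypes, mitochondrial haplotypes and site metadata sampled
across a species' distribution, `rangediv` quantifies how genetic variation
is distributed over the range and which biogeographic factors shape it. It
was built for the kind of study where a patchily distributed organism (e.g.
a passively dispersed freshwater invertebrate) is sampled at 60–80 sites and
the analyst must disentangle range expansion, geographic and environmental
marginality, dispersal barriers, habitat size, biotic interactions and the
mating system as drivers of local diversity.

## What it computes

**Per-site diversity.** Unbiased expected heterozygosity
H_E = n/(n−1)·(1 − Σp_i²) per locus (unweighted mean over loci), and
allelic / haplotype richness standardized by hypergeometric rarefaction,
E[A_g] = Σ_i [1 − C(N−N_i, g)/C(N, g)], to a common number of gene copies
(default g = 14, twice the seven-individual inclusion floor).

**Differentiation.** Weir–Cockerham (1984) variance-components θ (overall,
per locus, pairwise), haplotype-frequency AMOVA F_ST for mtDNA, the
linearization F/(1−F), haversine geographic distances, a Mantel permutation
test for isolation by distance, a minimum spanning tree of the linearized
matrix, and permutation contrasts of mean pairwise F_ST between population
classes.

**Mating system.** The identity-disequilibrium estimator g2 (standardized
excess of joint heterozygosity across locus pairs — independent of allele
frequencies, hence robust to null alleles), a per-locus permutation test of
g2 = 0, and the selfing rate from the equilibrium relation
g2 = s/((1−s)(4−s)) for unlinked loci.

**Bottlenecks.** The heterozygosity-excess test: per-locus observed gene
diversity is compared against its coalescent mutation-drift equilibrium
distribution conditional on the observed allele count under a two-phase
mutation model (90% single-step, geometric multi-step of variance 12 by
default), summarized by a one-tailed Wilcoxon signed-rank test. Applied
only to populations with an estimated selfing rate of zero.

**Predictors and model selection.** Distance to the range margin (convex
hull of the sampled sites), environmental marginality (distance from the
origin of the retained axes of a correlation-matrix PCA of climate
variables), 85%-quantile contrast groupings, the refugial/Holocene merge
rule (permutation tests per diversity measure), and all-subsets OLS model
selection with Gaussian AIC (or AICc) and Akaike weights over the full
candidate set.

**Synthetic data.** A forward-time metapopulation simulator (mixed mating,
two-phase microsatellite mutation, maternal infinite-alleles mtDNA,
distance-independent jump dispersal, founder-effect range expansion,
bottleneck events) provides ground truth for every stage; `scenario_null()`
and `scenario_range_expansion()` package the calibration and
range-expansion study conditions.

## Worked example

```r
library(rangediv)

sim <- simulate_metapopulation(scenario_range_expansion(), seed = 42)
cfg <- pipeline_config(seed = 1, n_perm_mantel = 999, n_perm_contrast = 999,
                       n_perm_selfing = 499, n_perm_merge = 999,
                       heq_reps = 500)
bundle <- run_pipeline(sim$geno, sim$sites, sim$haps, cfg)
cat(bundle$log, sep = "\n")
```

```
diversity: 55 sites included
selfing: inferred for 17 of 55 sites
bottleneck: tested 21 non-selfing sites, 2 significant
differentiation: overall theta=0.4171 mantel r=0.0250 p=0.3070
predictors: ref+hol merged
modelsel: responses He_t,A,s,Hmt
contrasts: done
```

The log already tells the story of this scenario: strong overall
differentiation (θ = 0.417) with no isolation by distance (Mantel
p = 0.31), partial selfing in roughly a third of the populations, and the
refugial and Holocene classes statistically indistinguishable (merged).
The expansion-class contrast shows the founder-effect signature:

```r
ct <- bundle$contrasts$exp
cat(sprintf("mean F_ST within exp = %.3f, rest = %.3f, diff = %.3f, p = %.4f\n",
            ct$mean_within, ct$mean_rest, ct$diff, ct$p_one_sided))
#> mean F_ST within exp = 0.539, rest = 0.370, diff = 0.169, p = 0.0010

head(as.data.frame(bundle$models$He_t)[, c("model", "df", "pct_var", "weight")], 3)
#>            model df pct_var weight
#> 1     lim_km+exp  2    42.9 0.107
#> 2 bio+lim_km+exp  3    44.5 0.084
#> 3        bio+exp  2    41.6 0.055
```

Recently founded populations are ~0.17 F_ST units more differentiated among
themselves than the rest of the range (permutation p = 0.001), and every
top-ranked model for arcsine-transformed H_E contains the expansion
predictor. `report(bundle, "out/")` writes the per-site diversity table,
distance matrices, MST edge list, grouped-deviation summary,
model-selection tables and contrast summaries as CSV.

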
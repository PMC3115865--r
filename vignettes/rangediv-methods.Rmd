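---
title: "Methods: statistics, simulator and design choices in rangediv"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: statistics, simulator and design choices in rangediv}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rangediv)
```

`rangediv` implements the analysis chain of a range-wide population-genetic
survey of a mixed-mating, passively dispersed organism: per-site diversity,
selfing estimation, bottleneck inference, differentiation structure,
biogeographic predictor construction, all-subsets model selection, and
permutation contrasts of differentiation among population classes. This
vignette records the statistical models, their assumptions, the tunable
parameters and the design decisions that were genuinely open.

## Diversity statistics

Expected heterozygosity uses Nei's unbiased gene diversity per locus,
$\hat H = \frac{n}{n-1}\bigl(1 - \sum_i \hat p_i^2\bigr)$, with $n$ the
non-missing gene copies at the locus; the site value is the **unweighted**
mean over loci with at least two copies. Unweighted is the convention of
the standard AMOVA software this mirrors; it also keeps a site's value
interpretable when loci differ in missingness. Site-level summaries across
the range are likewise unweighted means over sites — sample-size weighting
would let a handful of deeply sampled sites dominate a range-wide average.

Allelic and haplotype richness are standardized by hypergeometric
rarefaction: the expected number of distinct classes in a subsample of $g$
copies is $E[A_g] = \sum_i \bigl(1 - \binom{N-N_i}{g}/\binom{N}{g}\bigr)$.
The default depth is $g = 14$ gene copies — twice the seven-individual
floor below which a site is excluded from per-site diversity and selfing
statistics altogether. The floor is a bias control (richness and g2 are
very noisy below it); excluded sites still contribute to differentiation
analyses, where small samples merely widen variance rather than bias the
variance-components estimator. Loci with fewer than $g$ copies at a site
are dropped from that site's rarefied mean with a warning. Mitochondrial
richness is rarefied to the smallest per-site sequence total by default.
Binomial coefficients are evaluated on the log scale (`lchoose`) so large
$N$ cannot overflow.

The arcsine transform used when heterozygosity enters a linear model is
$\arcsin\sqrt{H_E}$ in radians, the standard variance stabilizer for
proportions.

## Differentiation

$F_{ST}$ is Weir & Cockerham's (1984) $\theta$: per-allele variance
components $a$ (among populations), $b$ (among individuals) and $c$
(within individuals) are summed over alleles and loci and combined as
$\hat\theta = \sum a / \sum(a+b+c)$ — the multi-locus convention of the
field's standard software. The estimator is unbiased and therefore may be
negative; raw values are preserved in all reports. Only for the
linearization $F/(1-F)$ (and hence the minimum spanning tree) is $F$
clamped into $[0, 0.999]$, keeping the transform finite without touching
the reported estimates. A site must contribute at least two typed
individuals at a locus to enter that locus's components.

Mitochondrial differentiation is the two-level AMOVA on haplotype counts
with 0/1 (identity) distances. Note a limit property worth knowing: the
variance partition reaches $F_{ST} = 1$ only when sites are internally
fixed; sites with disjoint *but internally variable* haplotype sets give
$F_{ST} < 1$.

Geographic distances are haversine great-circle distances with a fixed
Earth radius of 6371 km — fixed, rather than an ellipsoidal model, for
bit-reproducibility; the difference is irrelevant at the resolution of a
Mantel test on a continental study extent. The Mantel test correlates the
off-diagonal upper triangles, permutes rows and columns of one matrix
jointly, and reports the one-sided $p$ (positive association, i.e.
isolation by distance) with the +1 correction in numerator and
denominator. Raw kilometres are used, not log distance, matching how such
surveys plot the relationship.

The minimum spanning tree uses Kruskal's algorithm with a deterministic
tie-break (weight, then lexicographic site pair), so reruns and platform
changes cannot reorder equal-weight edges.

Class contrasts compare the mean pairwise $F_{ST}$ among category members
with the mean among the remaining sites (cross pairs excluded). Pairwise
$F_{ST}$ values are not independent, so inference is purely by
randomization: category labels are shuffled across sites (default 1000
shuffles) and both one- and two-sided $p$ values are reported with the +1
correction. The three-level expansion factor is handled as three pairwise
class contrasts, each restricted to the two classes compared.

## Selfing from identity disequilibrium

With $h_{il}$ the heterozygosity indicator of individual $i$ at locus $l$,
the package aggregates over locus pairs
$$\hat g_2 = \frac{\sum_{l<m} \overline{h_{il} h_{im}}}
                  {\sum_{l<m} \overline{h_{il} h_{jm}}_{\,i \ne j}} - 1,$$
the within-individual joint-heterozygosity rate against its
cross-individual product expectation, each pair restricted to individuals
typed at the relevant loci. Because only het/hom states enter, allele
frequencies never do — which is what makes the approach robust to null
alleles and partial dominance, the classic biases of $F_{IS}$-based
selfing estimates. Under mixed mating at inbreeding equilibrium with
unlinked loci, the number of consecutive selfing generations in an
individual's ancestry is geometric, which yields
$g_2 = s/((1-s)(4-s))$; the package inverts this closed form (a
quadratic) and clamps to $[0,1]$, with $\hat g_2 \le 0 \mapsto \hat s = 0$.
The inversion is monotone and approaches $\hat s = 1$ only asymptotically
as $g_2 \to \infty$. The forward simulator — which implements mixed mating
mechanistically — is the arbiter that these forms are right: at
$s \in \{0.2, 0.5, 0.8\}$ with 500 individuals and 8 loci the mean
absolute recovery error is about 0.01 (asserted at $\le 0.1$ in the test
suite).

Significance of $g_2 > 0$ comes from independently permuting each locus's
heterozygosity column among individuals: this destroys across-locus
identity correlations while exactly preserving every per-locus
heterozygosity level. "Selfing inferred" means $p < 0.05$; the survey
style this follows does not state its threshold, so the conventional 0.05
is used and exposed as `alpha`.

## Bottleneck inference

A recent reduction in effective size removes (rare) alleles faster than it
removes gene diversity, so for a transient period the observed diversity
exceeds the mutation-drift equilibrium value *conditional on the observed
allele count*. The package simulates that conditional equilibrium
directly: a coalescent genealogy of the $n$ sampled copies, Poisson
mutations on branches under a two-phase model — single repeat step with
probability `p_ss` (default 0.9), otherwise a geometric multi-step change
with variance `var_geom` (default 12, i.e. geometric success probability
0.25) — with the scaled mutation rate adapted between batches and the
realized allele count conditioned on $k$ by rejection. Attempts are capped
and failures reported rather than silently loosening the condition. The
defaults are the customary two-phase settings for microsatellite panels
described as mostly one-step with a small fraction of multi-step changes;
both are exposed.

Each polymorphic locus yields $DH = (H_{obs} - \bar H_{eq})/sd(H_{eq})$,
and a one-tailed Wilcoxon signed-rank test (exact when there are at most
15 loci and no ties — discrete genotype data can tie, in which case the
normal approximation is used) flags heterozygosity excess at
$\alpha = 0.05$; deficiency is reported but never flagged. At least four
polymorphic loci are required for the ranks to mean anything. Because a
mixed mating system itself distorts the equilibrium, the pipeline applies
the test only to populations with an estimated selfing rate of zero.

The coalescent reference assumes the sample is a small fraction of the
population. The calibration suite therefore draws its null populations at
$N = 100$ with 10 individuals sampled, where the type-I rate sits at the
nominal level; at sample fractions around a third the test runs a few
points hot, which is worth knowing when applying it to exhaustively
sampled small demes.

## Predictors

* **lim** (km): distance to the range margin, the margin being the convex
  hull of all sampled sites on a local equirectangular projection about
  the mean latitude. A planar hull was chosen over a spherical one: over a
  ~20° study extent the difference is far below the predictor's
  discriminating power, and the planar version is exactly testable against
  a dense edge-sampling oracle. Hull vertices have lim = 0.
* **marg**: environmental marginality — the Euclidean distance of a site's
  scores from the origin of the retained axes of a correlation-matrix PCA
  of the climate columns. "Significant axes" is operationalized as the
  Kaiser criterion (eigenvalue > 1), configurable to broken-stick;
  constant columns are dropped with a warning.
* **Quantile groupings**: for visual/contrast use, sites strictly above
  the 0.85 type-7 quantile of lim or marg form the "marginal" group. The
  threshold rule is deliberately strict-greater so ties fall in the
  reference group deterministically. The underlying survey phrasing
  ("within the 85% quantile") is ambiguous between top-15% and bottom-85%;
  top-15% = marginal matches the contrast's intent and is documented here.
* **bar, bio, size**: curated binary inputs (map inspection, habitat
  class); the pipeline treats them as data, not computation.
* **Expansion classes**: ref (glacial refugia), hol (Holocene expansion),
  exp (recent, ongoing expansion) arrive as input. Before modelling, ref
  and hol are merged into one reference level if, for every diversity
  measure, a two-sided permutation test of their group-mean difference
  fails to reject at $\alpha = 0.05$ (default 10,000 shuffles). Note the
  multiplicity property of this rule: under a true null with $k$
  independent measures the merge probability is $\approx 0.95^k$, not 1.

## Model selection

Every non-empty additive subset of the predictors is fit by OLS with
intercept (binary factors as 0/1 dummies, continuous predictors
untransformed), and the model degrees of freedom are counted as predictor
terms. Two Gaussian AIC conventions ship:

* `"gaussian-full"`: $AIC = N[\ln(2\pi\,SS_{res}/N) + 1] + 2(k+1)$ — the
  full Gaussian log-likelihood form. This is the convention under which
  published all-subsets tables of this kind reproduce to ±0.01, so it is
  the one used for reproduction work.
* `"aicc"`: adds $2K(K+1)/(N-K-1)$ with $K = k+2$ counted parameters
  (slopes, intercept, residual variance) — the small-sample-corrected
  criterion recommended for new analyses and the package default.

Both are exposed because the survey literature frequently *says*
small-sample-corrected while *printing* uncorrected values; shipping both
is the honest resolution. Akaike weights
$w_i = e^{-\Delta_i/2}/\sum_j e^{-\Delta_j/2}$ are always computed over
the full candidate set, never just the displayed rows; the display
threshold (weight > 0.05) only selects rows for reporting. A combinatorial
guard refuses more than 12 predictors (4095 models) unless forced, and
complete-case analysis is used throughout — no missing-data policy is
imposed beyond that.

## The forward simulator

`simulate_metapopulation()` is a forward-time, non-overlapping-generations
model chosen over a coalescent simulator because partial selfing,
serial founder events and arbitrary deme histories are straightforward
forward in time, and the scale involved (≤ 100 demes × ≤ 500 individuals)
is desk-sized. Each offspring is selfed with probability $s_d$, otherwise
formed from two uniformly drawn parents (which may coincide by chance, the
monoecious Wright–Fisher convention); microsatellites mutate at rate
$\mu$ per gamete under the same two-phase model as the bottleneck
reference; mtDNA is maternal with infinite-alleles mutation — only
haplotype identity matters downstream, so sequences are synthesized
deterministically at FASTA export. After reproduction each individual is
replaced with probability $m$ by a migrant from a uniformly random other
deme: distance-independent jump dispersal, the regime of bird-mediated
passive transport. Late-founded demes start from two founders drawn from a
random existing deme and grow geometrically to target size. All
randomness flows from a single Mersenne-Twister seed; identical seeds give
byte-identical outputs.

`scenario_range_expansion()` packages the study conditions: 40 core demes
of 120 along a SW–NE axis (southern third labelled ref), 15 expansion
demes at the NE end founded 5–25 generations before sampling,
$m = 0.002$, $\mu = 10^{-3}$, $\mu_{mt} = 2\times 10^{-3}$, heterogeneous
selfing (roughly half the demes outcross; expansion demes lean higher),
per-site sample sizes cycling through 9–24 individuals and 8–14 sequences.
These values put the metapopulation in the strong-local-drift,
no-isolation-by-distance regime the analysis is designed for (overall
$\theta \approx 0.4$, core $H_E \approx 0.55$) and were chosen once as
field-realistic; they are deme-level constants, not fitting dials.
`scenario_null()` is the homogeneous island-model counterpart (uniform
size, selfing and migration, no expansion, category labels in fixed
rotating patterns unrelated to demography) used by the type-I calibration
suites.

What the generator deliberately does **not** emulate: selection,
recombination-linked markers, continuous-space landscapes, allele-size
constraints beyond a wide reflecting floor, genotyping error other than
uniform random missingness, and demographically realistic census sizes
(drift is compressed into smaller demes over fewer generations). Passing
tests therefore demonstrate that the estimators recover truth under the
stated model, not that the model captures every feature of real survey
data.

## Numerical and degenerate-input conventions

* Permutation $p$ values always carry the +1 correction; their resolution
  is $1/(B+1)$ and they can never be 0.
* Missing genotype calls are fully missing (both alleles) by construction;
  half-coded GENEPOP entries are demoted to missing.
* Degenerate g2 (no heterozygosity variance at fewer than two loci)
  returns 0 with a flag and $p = 1$ rather than an error, so range-wide
  tables keep their rows.
* Monomorphic loci are skipped by the bottleneck test ($k = 1$ carries no
  information about the diversity–allele-count relationship); an entirely
  monomorphic site returns an explained undefined result.
* Haplotype identity is exact string equality over the full aligned window
  after the ≥ 400 non-gap-base length filter, with `N` a mismatch —
  deterministic and order-invariant (ids are assigned in lexicographic
  sequence order). How to window unequal-length reads before collapsing is
  genuinely underdetermined in the survey literature; exact-window
  collapse is this package's choice.
* The master pipeline seed fans out to fixed per-stage substreams, so any
  stage can be rerun in isolation and reproduce its slice of the bundle.

## Problem sizes in the test suite

The suites size their simulations for a desk machine: oracle equivalences
run at $N \le 12$ (rarefaction), $n \le 7$ (spanning trees) and $\le 10$
loci (sign-assignment enumeration); calibrations use 100 equilibrium
populations (bottleneck), 200 replicates (g2 type-I, Mantel/contrast
uniformity) and 20 seeds of the full range-expansion scenario; selfing
recovery uses 500 individuals × 8 loci × 20 replicates per selfing rate.
These sizes make the binomial acceptance bands meaningful without
inflating runtimes.

## Known limitations

* The g2 aggregation is the ratio-of-sums multilocus combination; exact
  variance formulas (and hence analytic confidence intervals) are not
  implemented — inference is by permutation only.
* The bottleneck test's calibration degrades when the sample is a large
  fraction of a small deme (see above) and, as in its reference
  implementations, mixed mating invalidates it — hence the hard selfing
  gate.
* The convex-hull margin is a surrogate: it cannot represent range holes
  or concave margins, and margin distance is only as good as the sampling
  of the true margin.
* Haplotype-frequency AMOVA ignores sequence divergence between
  haplotypes (identity distances only).
* The all-subsets machinery fits additive models only; interactions are
  out of scope by design.
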
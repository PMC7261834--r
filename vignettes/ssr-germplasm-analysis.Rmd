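---
title: "Population-genetic analysis of SSR germplasm panels with ssrdem"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Population-genetic analysis of SSR germplasm panels with ssrdem}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ssrdem)
```

`ssrdem` implements the full analysis chain used to characterize large
crop germplasm collections genotyped at microsatellite (SSR) loci:
diversity statistics, differentiation and ordination, Bayesian admixture
clustering, heterozygosity-excess bottleneck tests, coalescent
rejection-ABC inference of effective-size changes and admixture, and
core-collection selection.  This vignette documents the models, the
parameters that matter, the numerical choices, and what the package's
synthetic data can and cannot demonstrate about real panels.

## Data model

The universal input is a diploid codominant genotype matrix: individuals
by loci, each call an unordered pair of positive integer allele codes
(fragment sizes or repeat counts), with missing calls allowed
(`genotype_matrix()`).  A `partition()` maps individuals to groups —
geographic origin, an inferred genetic cluster, or a core membership.
All diversity and differentiation statistics are label-invariant; only
the bottleneck and ABC modules interpret allele codes as sizes on the
stepwise-mutation ladder.

Three text dialects are read and written (`read_genotype_table()`,
`write_genotype_table()`): GenePop (2- or 3-digit fixed width, `Pop`
blocks as groups, `000` missing), STRUCTURE one-row-per-individual
(two columns per locus, `-9` missing), and a CSV with `a/b` calls.  One
canonical in-memory missing marker is used; dialect encodings are mapped
at the boundary, so there is a single validation path.

## Diversity statistics

Per locus (`locus_summary()`): allele count $N_A$, effective allele
count $N_E = 1/\sum p_i^2$, Shannon information $I = -\sum p_i \ln p_i$,
major-allele frequency, observed heterozygosity, unbiased expected
heterozygosity $H_E = \frac{2n}{2n-1}(1 - \sum p_i^2)$, and the
Weir–Cockerham $F_{IS}$ from within-sample variance components.
Frequencies always come from non-missing calls only; a locus entirely
missing is dropped with a warning rather than imputed.  Multilocus
$F_{IS}$ is reported both ways an analyst might want it — pooled over
variance components (the default, which weights loci by information) and
as the mean of per-locus ratios — because published tables rarely say
which convention they use.

Allelic richness (`allelic_richness()`) is hypergeometric rarefaction
over gene copies,
$A_R = \sum_i \left[1 - \binom{2n - n_i}{g} / \binom{2n}{g}\right]$,
with the automatic rarefaction size equal to the smallest non-missing
copy count over group-by-locus cells (the FSTAT convention of scaling to
the smallest partitioning level).  The implementation is exact — it is
tested against exhaustive enumeration of all subsamples on instances of
up to 12 gene copies.

The $F_{IS}$ significance test permutes gene copies among individuals
within the sample and recomputes the variance-component estimator,
one-sided toward heterozygote deficit; the default permutation count is
1000 and every test is seedable.

Null alleles are estimated from the heterozygote deficit with the
closed-form Brookfield estimator $r = (H_E - H_O)/(1 + H_E)$, floored at
zero (`null_allele_rate()`).  A caveat worth knowing: when null
homozygotes are scored as missing (which is how the generator injects
nulls), the estimator's expectation is approximately
$H_E \cdot 2r / ((1+r)(1+H_E))$, so it is near-unbiased only for modest
null frequencies (roughly $r \le 0.1$) and increasingly conservative
above that.  The test suite asserts recovery at $r = 0.08$.

## Differentiation and geometry

Pairwise and global $F_{ST}$ use the Weir–Cockerham $\theta$ with
variance components summed over alleles and loci; pairwise significance
comes from permuting individuals between the two groups.  Nei's genetic
distance is offered in its 1972 standard form (the default) and the 1978
sample-size-unbiased form, since published "Nei distance" tables rarely
distinguish them; gene identities are averaged over loci before the
ratio.

The two-level AMOVA is distance-based, with **gene copies** as the
analysis units: squared Euclidean distances between one-hot allele
vectors summed over loci, degrees of freedom on the $2N - 1$ scale, and
$\Phi_{ST}$ significance from permuting whole individuals.  This choice
was made deliberately: an AMOVA on inter-individual allele-count
distances estimates $\Phi = 2\theta/(1+\theta)$, roughly double
$F_{ST}$, whereas the copy-level analysis is on the $F_{ST}$ scale and
reproduces the degrees-of-freedom structure of the standard
codominant-marker AMOVA implementations.  Negative among-group variance
components are truncated at zero before percentages.

Individual-level geometry: the simple-matching dissimilarity
$d(i,j) = 1 - \frac{1}{L_{ij}}\sum_l m_l/2$ (multiset allele sharing per
locus, over loci scored in both individuals), neighbor-joining trees via
the ape package with bipartition support from bootstrap resampling of
loci,
and classical-scaling PCoA in which negative eigenvalues are reported,
never corrected — a non-Euclidean input should be visible to the
analyst.

## Bayesian admixture clustering

`fit_admixture()` is a Gibbs sampler for the admixture model: each
individual carries a membership vector $Q_i$ over $K$ clusters, each
allele copy originates from one cluster and is drawn from that cluster's
locus frequencies $P$.  Sweeps alternate origin assignments, conjugate
Dirichlet updates of $P$ and $Q$, and a Metropolis step for the
concentration $\alpha$ (shared across clusters, uniform(0, 10) prior,
proposal sd 0.25).  The correlated-frequency model adds an F-model prior
on $P$ around sampled ancestral frequencies with one drift parameter per
cluster (uniform(0, 1) prior); the independent-frequency model is the
default because it mixes faster and is sufficient for recovery on
well-separated clusters.  Missing calls contribute nothing.  Reported
$Q$ and $P$ are posterior means over post-burn-in thinned samples, and
runs are bitwise reproducible under a seed.  The inner loop is compiled
(Rcpp) so that a full panel of ~900 individuals by 25 loci runs a
12,000-sweep chain in well under a minute; published analyses of such
panels typically use 100,000 burn-in plus 1,000,000 iterations, which
this implementation also supports — the short defaults are for
desk-scale work and the test suite, where recovery is already stable.

Replicate runs are reconciled with `align_runs()`: a greedy growth of an
aligned set, each run joined by its best column permutation (exhaustive
for $K \le 7$, greedy assignment above), repeated over random input
orders.  The similarity of two aligned runs is
$S = 1 - \|Q - Q'\|_F/\sqrt{2n}$, bounded in $[0,1]$ and equal to 1 iff
the runs agree; $H'$ is the mean over run pairs.  `evanno_delta_k()`
implements $\Delta K = |L(K-1) - 2L(K) + L(K+1)|/s(K)$.  No automatic
choice of $K$ is made: both the likelihood plateau and $\Delta K$ are
reported, and the pipeline's default of taking the interior $K$ with the
highest $\Delta K$ is only a default.  Assignment uses the inclusive
threshold rule: an individual joins its argmax cluster when the maximum
membership is at least $q^* = 0.8$, ties to the lowest index, and is
"admixed" otherwise.

## Heterozygosity-excess bottleneck tests

A recent bottleneck removes alleles faster than it removes gene
diversity, so the observed $H_e$ exceeds the equilibrium expectation
given the surviving allele count.  `simulate_heq()` draws that
equilibrium distribution by coalescent simulation of $n$ gene copies
with mutations under IAM, SMM, or TPM (single-step with probability
0.95, otherwise a geometric multi-step whose variance is 12, following
the standard microsatellite recommendation; the geometric parameter
solves $(1-g)/g^2 = 12$, i.e. $g = 0.25$), keeping draws whose realized
allele count equals the observed $k$.

Two numerical choices matter here.  First, the mutation parameter is
tuned once per dataset and model — bisection so the expected allele
count matches the mean observed $k$, then snapped to a coarse log grid
so equilibrium distributions are reusable across datasets — rather than
per locus.  Under the IAM the allele configuration given $k$ is
independent of the rate (Ewens), so this is immaterial; under SMM/TPM
the conditional distribution of $H$ given $k$ *does* depend on the
rate, and per-locus tuning (rate matched to each locus's own $k$)
systematically biases the reference distribution.  Loci whose $k$ would
be accepted too rarely at the common rate (estimated from a cached probe
pool) fall back to per-locus tuning.  Second, the Wilcoxon signed-rank
aggregation is applied to the per-locus *excess probabilities*
$P(H_{eq} < H_e)$ centered at 1/2: these are probability-integral
transforms, uniform under the equilibrium null, which makes the test
calibrated (measured type-I error 0.08 at nominal 0.05 over 100 matched
null replicates).  The classical statistic on raw differences
$H_e - \bar H_{eq}$ is also reported (`wilcoxon_p_classic`); it is
markedly conservative because the conditional distribution of $H$ given
$k$ is skewed.  Exact Wilcoxon null up to 25 untied loci, normal
approximation with continuity correction otherwise.  Conditional on the
allele count, equilibrium diversity is *higher* under SMM than IAM
(size homoplasy forces a higher rate to reach the same $k$), which is
why the IAM variant flags excess most readily.

The qualitative companion is the mode-shift test (`mode_shift()`): all
alleles pooled over loci, binned by within-group frequency into ten
classes of width 0.1; a stable population shows an L-shaped
distribution dominated by the rarest class, and the report flags
"shifted" when the modal class is any other.

## Coalescent ABC for demographic direction

`demographic_scenario()` describes a rooted population tree in
coalescent units of the shared past size: each population has present
relative size $r_i = N_{present}/N_{past}$ back to its change time and
size 1 beyond; splits merge populations backwards in time; admixture
edges move each lineage of the target into the source with probability
$a$ at their time.  `simulate_scenario()` runs an independent structured
coalescent per locus with generalized stepwise mutations of allele size
and pairs copies into diploids.  The estimation is deliberately
ratio-centric: only directions and magnitudes of size change and
admixture proportions are estimated, never absolute sizes or times.

Summary statistics (`summary_statistics()`): per population the mean
allele number, mean unbiased gene diversity, mean allele-size variance,
and M-index (allele count over size range); per pair, Weir–Cockerham
$F_{ST}$ and a mean shared-allele distance computed on a fixed-size
subsample per population (deterministic, for speed).  With the exact
statistic list of the original analysis unavailable, this set is a
declared stand-in of the same families and is fully visible in the
output layout.

`abc_fit()` draws $\log_{10} r_i \sim U(-2, 2)$ and admixture
proportions $\sim U(0,1)$, normalizes statistics by their simulation
standard deviation (zero-variance statistics are dropped with a
warning), accepts the closest fraction in Euclidean distance, and
optionally applies local-linear regression adjustment with Epanechnikov
weights, clipping adjusted proportions to $[0,1]$.
`posterior_r_report()` classifies each population by the sign of the
posterior mode of $\log_{10} r$ with a dead zone of 0.25 ("stable"),
and flags parameters whose posterior stays within total-variation
distance 0.1 of the prior as uninformative — the honest answer when the
data carry no signal.  Recovery tests use a two-population template with
the size change at 0.3 coalescent units: a change epoch much shorter
than that leaves an expansion nearly invisible in the genealogy, which
is a property of the inference problem, not of the implementation.

## Core collection

`build_core()` is the allele-coverage maximization heuristic: at each
step add the individual covering the most not-yet-covered locus–allele
classes, ties broken by higher within-individual heterozygosity then
lowest index, stopping at 100% coverage of the observed alleles; a
redundancy post-pass removes any member whose alleles are covered by the
rest.  Missing calls contribute no classes, so coverage is always of
observed alleles.  The procedure is deterministic, and on small
instances it is checked against exhaustive minimum set cover.

## The synthetic panel: what it shows and what it does not

`worldwide_preset()` generates the package's reference panel: 890
accessions in 7 geographic groups, 25 loci with 18–32 ancestral alleles
(Dirichlet(1) ancestral frequencies), 5 latent clusters under the
F-model (cluster frequencies Dirichlet with parameters
$p_{anc}(1-F_k)/F_k$), about 30% admixed individuals (two-cluster
mixtures with maximum membership below the 0.8 assignment threshold),
and 2% missing calls.  The drift vector (0.31, 0.10, 0.21, 0.49, 0.21)
was chosen so the realized global five-cluster $\theta$ lands near 0.17
(bracket 0.12–0.22), with the Central-Asia-analogue cluster least
drifted (most diverse) and the Continental-Europe analogue most drifted
— reproducing the qualitative diversity ordering of the panel it
emulates.  Group-to-cluster composition follows the published structure:
Eastern Asia to cluster 1, Central Asia to cluster 2, Irano-Caucasian
plus part of North Africa to cluster 3, Continental Europe to cluster 4,
Mediterranean Europe plus the rest of North Africa to cluster 5, and a
mostly admixed America.

What passing tests on this panel demonstrate: the estimators recover
known truth under the admixture-with-drift model — membership matrices
to MAE < 0.1, global differentiation inside its calibration bracket,
AMOVA percentages on the $F_{ST}$ scale, full-coverage cores.  What they
do not demonstrate: robustness to features the generator lacks —
linkage between loci, genotyping error beyond null alleles,
mutation-rate heterogeneity across loci, allele-size adjustment problems
between laboratories, and pedigree or clonal structure, all of which
occur in real germplasm panels.

## Problem sizes used in the automated checks

The test suite and the acceptance script run everything at desk scale,
chosen for stable statistics: admixture chains of 500–2,000 burn-in and
2,000–10,000 iterations with 2–3 replicate runs (the full preset panel),
bottleneck calibration and power at 100 replicate datasets of 25 loci
and 50 individuals with 200 equilibrium draws per locus, and ABC with
500–800 reference simulations of 20 loci at 20 diploids per population.
All quantities are recomputed from scratch at run time under the seeds
passed in.
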
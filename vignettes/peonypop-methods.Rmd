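---
title: "Models and methods behind peonypop"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind peonypop}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`peonypop` reimplements, as a tested and reusable library, the joint
population-genetic and ecological analysis of the three tree peony
species of the Qinling--Daba Mountains in Central China: *Paeonia
jishanensis* (J), *P. qiui* (Q) and *P. rockii* (R). The questions the
toolchain addresses are (i) how genetic variation at 22 nuclear
microsatellites (nSSRs) and three concatenated chloroplast intergenic
spacers is distributed within and among the species, (ii) which
three-population divergence history best explains the nSSR data and
what its parameters are (coalescent ABC), (iii) whether the species'
effective population sizes changed through the late Pleistocene
(neutrality tests, mismatch distributions), and (iv) whether the
species occupy climatically divergent niches beyond what their
available background environments would produce.

This vignette explains the models, the numerical choices, and the
design decisions that were genuinely open; it states no empirical
result that the package's tests and `scripts/acceptance.R` do not
themselves compute.

## Data containers

`GenotypeDataset` holds diploid allele-size calls as an
`individuals x loci x 2` integer array with per-individual population
labels, a population-to-species map, and optional population
coordinates. A call is either fully typed or fully missing; all
statistics treat missing data pairwise-complete per locus and drop a
locus from a group's statistic only when the group has no calls at it.
`HaplotypeTable` stores distinct (indel-recoded) cpDNA haplotypes,
their pairwise difference matrix and per-population counts;
`NicheDataset` stores occurrence and background points in climate
space. Reference tables, scenario specifications, parameter draws and
priors are small S4 objects with validity checks.

## Microsatellite statistics

Expected heterozygosity is Nei's unbiased estimator
$H_E = \frac{2n}{2n-1}\bigl(1-\sum_i p_i^2\bigr)$ per locus, averaged
over loci; observed heterozygosity is the fraction of heterozygous
calls. Allelic richness uses hypergeometric rarefaction,
$A_R = \sum_a \bigl[1 - \binom{N-N_a}{g}/\binom{N}{g}\bigr]$. The
rarefaction depth in `"auto"` mode is the smallest per-locus gene-copy
count over all groups, and the value used is always reported: the
original study does not state the depth its software used, so the
published per-population richness values (all between 1.2 and 1.6,
indicating a very small depth) are not a reproduction target.
$F_{IS}$ is reported as $1 - \bar H_O/\bar H_E$.

Differentiation uses Weir & Cockerham's (1984) variance-component
estimator $\theta$ throughout — including inside the ABC summary
statistics — as the ratio of summed components over alleles and loci.
Negative estimates are reported as computed, and clamped to zero only
before linearization to $F_{ST}/(1-F_{ST})$ for the
isolation-by-distance Mantel test. Geographic distances are haversine
great circles with Earth radius 6371.0088 km; the study's software
does not document its convention, so the mean-radius sphere was fixed
once. Mantel permutations use the one-tailed
$(\mathrm{hits}+1)/(n_\mathrm{perm}+1)$ rule with the study's 999
permutations as default.

AMOVA follows the Excoffier sums-of-squares-over-squared-distances
formulation. For nSSRs the units are gene copies and the distance is
allele identity (an $F_{ST}$-like analysis, matching the
frequency-based differentiation the study reports, rather than an
allele-size $R_{ST}$ analysis); for cpDNA the units are individuals
and the squared distance is the haplotype difference count. Negative
variance components are clamped to zero with a warning and percentages
renormalized. Significance uses 10,000 permutations by default:
individuals among all populations for $\Phi_{ST}$, individuals among
populations within species for $\Phi_{SC}$, and whole populations
among species for $\Phi_{CT}$. When every species holds exactly one
population, the nested stratum is empty and the three-level call is
rejected with a pointer to the one-level analysis.

The shared-allele distance between two diploids averages, over
co-typed loci, one minus half the number of shared allele copies; the
tree on it is standard neighbour joining (`ape::nj`). Genotype PCA
encodes per-allele dosages (0/1/2), mean-imputes missing dosages,
centres columns and takes the SVD; scores are deterministic up to
sign.

Directional relative migration follows the pooled-reference idea: for
an ordered pair, a hypothetical migrant pool is the equal-weight
mixture of the two groups' allele frequencies, the chosen
differentiation metric (Nei $G_{ST}$ or Jost's $D$, plain estimators)
is computed between each group and the pool, converted through
$N_m = \tfrac14(1/d - 1)$, and the directed matrix is rescaled to a
maximum of 1. The donor convention — migration $a\to b$ derives from
$d(a,\mathrm{pool})$, so the group whose genes dominate the shared
pool is the main donor — was fixed by forward-time source-sink
simulations (a large stable donor feeding a small recipient): the
donor-side mapping recovers the planted direction, the receiver-side
mapping inverts it. Equal-weight frequency pooling, rather than
pooling individuals, keeps unequal sample sizes from masquerading as
asymmetry.

## Chloroplast statistics

Indels are coded as substitutions: every maximal run of adjacent
alignment columns with an identical gap-presence pattern collapses to
a single binary character (A = gap absent, T = gap present; which
state maps to presence affects no statistic). Identical recoded
sequences merge into haplotypes named in order of first appearance.
IUPAC ambiguity codes are treated as missing for difference counting,
with a warning.

Haplotype diversity is Nei's unbiased
$H_d = \frac{n}{n-1}(1-\sum p_i^2)$; nucleotide diversity sums
haplotype pairwise differences over all individual pairs and divides
by $\binom{n}{2}$ and the alignment length. Species-level values pool
individuals across the species' populations — pooling, not averaging
per-population values, reproduces the study's printed species means,
which is why it is the package's convention. One printed
per-population value (SBL, 0.677) is inconsistent with the unbiased
formula applied to its own printed counts (0.667) and is treated as a
typographical error.

$G_{ST}$ and $N_{ST}$ use the Pons & Petit estimators: unbiased
within-population diversities averaged unweighted, total diversity
from mean frequencies plus a harmonic-mean sample-size correction,
with $N_{ST}$ weighting by haplotype distances. Populations with
fewer than two sequenced individuals are dropped. The
phylogeographic-structure test permutes haplotype identities in the
distance matrix and asks how often the permuted $N_{ST}$ reaches the
observed one (one-tailed, +1 rule). Note the test's resolution is
limited by the number of distinct haplotype permutations, so with
very few haplotypes small p-values are unattainable.

The haplotype network is a minimum-spanning network: every edge that
occurs in at least one minimum spanning tree of the distance graph
(computed by Kruskal with whole weight-classes resolved against the
pre-class component structure), so tied alternative connections are
kept. A full median-joining algorithm with inferred median vectors is
deliberately out of scope.

## Neutrality and demography

Tajima's $D$ uses the canonical constants; it is flagged undefined
without segregating sites or with $n<4$. Fu's $F_s$ estimates
$\theta$ by the mean pairwise difference and computes
$S' = P(K \ge k_{obs})$ under the Ewens sampling formula with a
numerically stable recurrence,
$q_{m+1}(k) = (m\,q_m(k) + \theta\,q_m(k-1))/(\theta+m)$, equivalent
to unsigned Stirling numbers of the first kind but immune to their
overflow; $F_s = \ln(S'/(1-S'))$ with guarded infinities. Optional
p-values compare the observed statistic against neutral constant-size
coalescent simulations at the observed $\theta$ (fraction of
simulated values at or below the observed one).

The mismatch analysis fits the sudden-expansion model to the
distribution of pairwise differences. Instead of the classical
small-$\theta$ approximation, the expected class probabilities are
the exact two-epoch pairwise-coalescent mixture: with time in
mutational units, hazard $1/\theta_1$ more recently than $\tau$ and
$1/\theta_0$ beyond,

$$F_j = \frac{\theta_1^j}{(1+\theta_1)^{j+1}}
        P\!\bigl(j+1,\ \tau\tfrac{\theta_1+1}{\theta_1}\bigr)
      + e^{-\tau/\theta_1} \sum_{k=0}^{j}
        \mathrm{Pois}(k;\tau)\,
        \frac{\theta_0^{\,j-k}}{(1+\theta_0)^{j-k+1}},$$

with $P(\cdot,\cdot)$ the regularized incomplete gamma. Least squares
on relative frequencies (expectation renormalized over the observed
support) is minimized by Nelder--Mead in log-parameter space with 10
random restarts (seed-controlled); a fit with $\theta_1<\theta_0$ is
flagged as contraction-like. Goodness of fit uses SSD and
Harpending's raggedness $\sum(x_{i+1}-x_i)^2$; p-values are
parametric-bootstrap: replicates are simulated under the fitted
expansion with a two-epoch infinite-sites coalescent, refitted (two
starts seeded at the observed optimum), and compared one-tailed with
the +1 rule. The bootstrap default is 1000 replicates (the study does
not state its count). A coarse-grid oracle bounds the optimizer in
the test suite: the optimum is never worse than the best grid point
by more than 1e-6.

## Coalescent simulator and divergence scenarios

Each locus gets an independent genealogy on the three-population
history, simulated backwards in continuous time with coalescence rate
$\binom{k}{2}/2N$ per population and epoch. Mutations fall on
branches as a Poisson process at the per-locus rate $\mu$ and move
the allele by $\pm 1$ repeat (strict SMM; a generalized model with
geometric step sizes, parameter 0.22, is available behind a flag
since the study does not document its mutation-model settings),
reflected at $\pm 40$ repeats around the ancestral state — the
40-allele range convention of the study's inference software. Sampled
gene copies pair into diploids within populations; copies are
exchangeable so consecutive pairing is used. The engine is Rcpp with
its own `mt19937_64` stream, so a seed fixes the dataset bit for bit.

The scenario catalogue requires two conventions the source text does
not fully pin down:

* **Step-1 topologies.** Only scenario 1 is described verbatim
  ("Q from J at t1, R from J at t2"). The six-scenario catalogue is
  reconstructed as the six ordered (derived $\leftarrow$ ancestor)
  choices for the split at $t_1$, with the remaining taxon joining
  the ancestral lineage at $t_2$; `scenarioCatalogue(1)` documents
  the mapping and the reconstruction.
* **Step-2 ancestral sizes.** Read literally, the two step-2
  scenarios ("J ancestral to R" vs "R ancestral to J") describe the
  same backward process: once the final merged lineage has size
  $A_1$ in both, the merge direction is label-only. The package
  therefore adopts the convention that the taxon named as the deep
  ancestor carries the ancestral size on its own lineage between the
  events: in scenario 1 the R lineage keeps $N_R$ until $t_2$; in
  scenario 2 the (ancestral) R lineage already has size $A_1$ from
  $t_1$ backwards. The two models then differ in distribution exactly
  when $A_1 \neq N_R$ — and coincide when $A_1 = N_R$, which is
  worth keeping in mind when interpreting scenario-choice error rates
  near that boundary (the study's own reported type I/II errors for
  step 2, about 0.3 each, sit close to the coin-flip regime this
  near-identity predicts).

Priors are uniform: sizes and times on $(10, 10^5)$ (with $t_1<t_2$
by rejection; the study prints only the $\mu$ prior, uniform on
$(10^{-4},10^{-3})$, so the size/time bounds are documented
assumptions). Generation time is fixed at 10 years and event times
are reported both in generations and years.

## ABC inference

Summary statistics are the study's set, in a fixed order: per species
the mean number of alleles per locus and mean expected heterozygosity
(Nei unbiased — the study's software does not say which variant it
uses, so the unbiased form is used consistently), and per species
pair Weir--Cockerham $\theta$ and Goldstein's $(\delta\mu)^2$ (mean
over loci of the squared difference in mean allele size).

Before any distance is computed, the statistics are
variance-stabilized: log for the per-species allele counts and the
$(\delta\mu)^2$ distances, logit for the bounded heterozygosities and
$F_{ST}$ values. Expected heterozygosity saturates in $N\mu$, so on
the raw scale the statistic-parameter relationships are strongly
curved over the wide uniform priors; the transforms make both the
nearest-neighbour metric and the local-linear regression assumption
(approximate linearity over the retained neighbourhood) far more
defensible at a desk-scale reference table. After transformation the
statistics are standardized by their reference-table standard
deviations.

Scenario choice retains the closest 1% of rows by Euclidean distance
(the study's tolerance, with a floor of 100 rows so the regression
stays estimable against 12 covariates) and fits a polychotomous
logistic regression of the scenario indicator on the statistics over
the retained set, evaluated at the observed vector (weight decay 0.05
— with near-indistinguishable scenarios and a small retained set, an
unregularized fit saturates to 0/1 probabilities that merely reflect
overfitting; direct-rejection proportions are the documented fallback
when the retained set loses a scenario). CIs come from the
regression's asymptotic covariance via the delta method.

Parameter estimation is Beaumont local-linear regression: retained
draws (1% of the scenario's rows, floor 100) get Epanechnikov weights
in distance, parameters are logit-transformed to their prior bounds,
adjusted by a weighted linear regression on the (centred) statistics
— solved with a mild scale-aware ridge (1e-3 of the mean design
diagonal) against collinearity, with adjusted values clamped at
$\pm 20$ logit units so extrapolation cannot pin draws to the exact
prior bounds — back-transformed, and summarized by weighted
2.5/50/97.5% quantiles. A singular design falls back to the
unadjusted rejection sample with a warning, and at tolerance 1 with
adjustment off the sample reduces to the prior (which the test suite
checks by Kolmogorov--Smirnov).

Scenario-choice confidence simulates pseudo-observed datasets under
every scenario with prior-drawn parameters: the type I error is the
fraction of pods from the chosen scenario not assigned to it, the
type II error the fraction of other-scenario pods wrongly assigned to
it. Posterior model checking simulates replicates at posterior draws
and reports two-sided tail probabilities per statistic.

The study's real-data posterior numbers (posterior probabilities
0.5607/0.6104, divergence times 50.3 and 24.3 ka, and the Table-7
medians as estimates) are not reproduction targets: the raw genotypes
are not deposited. The package's checks instead run the full method
at study scale on synthetic truth — 5000 reference rows per step-2
scenario, 22 loci, the study's species sample sizes (255/118/214),
truth at the printed posterior medians with $A_2 = 9520$ from the
text and $A_1 = 4500$ ("slightly below $N_R$", as the text states;
the exact value is not printed) — and ask for scenario recovery,
error rates and interval coverage. Two structural limits of this
setting are worth stating plainly. First, because $A_1 = 4500$ sits
close to $N_R = 5090$, the two step-2 models are nearly
indistinguishable at this truth point (see the convention note
above), which bounds how often any method can pick the generating
scenario there. Second, the truth values all lie in the lower 2--5%
tails of the assumed uniform priors simultaneously, so a desk-scale
reference table contains few draws near the truth; posteriors shrink
toward the prior bulk and fixed-truth interval coverage is expected
to sit below the nominal 95% — an inherent property of
regression-ABC far out in the prior, not a defect of a particular
fit, and a hint that the study's own (unpublished) priors were
likely much narrower. The same prior-wide ambiguity depresses
scenario-choice confidence: for a large fraction of prior draws the
two step-2 models coincide almost exactly (small $t_2 - t_1$, or
$A_1$ near $N_R$), so type I/II error rates estimated over
prior-drawn pods include many unavoidable coin flips.

## Synthetic data generators

The microsatellite generator is the simulator plus a `TruthRecord`
(scenario, parameters, seed, sample sizes). The cpDNA generator
realizes a requested population-by-haplotype count map exactly: a
random attachment genealogy over the haplotypes, at least one new
infinite-sites mutation per edge, the remaining mutations multinomial
over edges, and optionally one contiguous 5-bp indel carried by one
non-root lineage — mirroring the structure of the study's alignment
(2075 columns, 37 substitution sites, one indel, 18 haplotypes)
without modelling indel evolution. Collapsing the emitted alignment
recovers the requested counts exactly, which is a round-trip test.

The niche generator draws per-species occurrence climates from
normals with centroid shifts expressed in within-species SD units.
Background points are uniform over the bounding box of all species'
occurrences pooled, inflated by 25%. The pooled (rather than
per-species) box is a deliberate design choice: with per-species
boxes the background-divergence null inherits the planted centroid
shift, and no shift, however large, could ever be declared divergent
— the common box makes background divergence reflect sampling noise
from a shared available environment, which is the situation the
background test is designed for. What the generator does not emulate:
spatial autocorrelation of climate, non-Gaussian niche shapes, and
any correspondence between the fake coordinates and the climate
values — so passing tests demonstrate the statistical machinery, not
transferability to any particular real landscape.

## Niche divergence test

Candidate variables first pass a greedy correlation filter: while any
absolute Pearson correlation is at or above 0.8 (the study's
threshold), the variable with the largest mean absolute correlation
is dropped (ties: the later column), constants first. Per species
pair, a z-score-standardized PCA over the pair's occurrences and
background jointly defines the axes. On each axis, observed
divergence $d_n$ is the absolute difference of occurrence-score
means; the background null resamples each species' background with
replacement at its occurrence count (1000 resamples by default — the
study does not define the scheme, so the jackknife-with-replacement
convention of the background-similarity literature is used) and
reports the 2.5–97.5% interval of $d_b$; $d_n$ itself is tested
against a species-label permutation null. Divergence on an axis
requires both $d_n$ above the upper $d_b$ bound and a significant
permutation test; $d_n$ below the lower bound is conservatism.
Correlations of the scores with latitude and longitude are reported
alongside. The study's printed per-pair explained variances (about
68–69% over two axes) depend on its unreleased occurrence climate
values and are not a reproduction target.

## Problem sizes and reproducibility

Every stochastic routine takes an explicit seed, and the pipeline
(`runPipeline()`) derives one recorded child seed per stage from the
master seed, so a manifest reproduces a run bit for bit. The test
suite runs the statistical calibrations at deliberately modest sizes
(200 null replicates for the Mantel and $N_{ST}$ calibrations with 99
permutations each, 50 zero-shift niche replicates, 5000 reference
rows per scenario with 20 pods for the ABC checks); these sizes are
the package's chosen trade-off between the precision of a calibration
estimate and a test suite a contributor will actually run, and the
acceptance checks state their conditions explicitly so larger reruns
are a parameter change.

## Known limitations

* The AMOVA degrees of freedom and expected-mean-square coefficients
  use full sample sizes; with heavy missingness the per-locus
  pairwise-complete sums of squares and the global coefficients can
  drift apart (exact with complete data, as in all bundled and
  simulated sets).
* The divergence scenarios model no post-split gene flow and no
  within-species population structure; within-species synthetic
  populations are panmictic samples of one lineage.
* The mismatch bootstrap refits each replicate from only two starts
  (seeded at the observed optimum), trading a slight optimism in
  replicate SSDs for tractable runtime.
* Fu's $F_s$ p-values condition on $\theta=\hat\pi$ rather than
  integrating over its uncertainty, as is conventional.
* `PERMUT`-style tests with few haplotypes have a coarse permutation
  space; reported p-values cannot go below the reciprocal of the
  number of distinct rearrangements.
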
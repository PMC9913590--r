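---
title: "Methods: microsatellite diversity and hybrid-class assignment in pike"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: microsatellite diversity and hybrid-class assignment in pike}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Southern pike (*Esox cisalpinus*) hybridises with northern pike
(*E. lucius*) wherever hatchery stocking has brought the two species into
contact. Given diploid codominant microsatellite genotypes from several
populations — an introduced lake population of unknown makeup plus
reference samples of each species — the questions are: (i) are the
markers trustworthy (Hardy–Weinberg behaviour, linkage, null alleles and
dropout, selection outliers); (ii) how much diversity and differentiation
do the populations carry, and how large are their effective sizes; and
(iii) can individual fish be assigned to pure or hybrid genotypic
classes, and with what power given this marker panel?

`pikemix` implements that workflow end to end: genotype containers and
GENEPOP I/O, marker validation, diversity/differentiation estimators,
LD effective population size, gamete-sampling simulation of hybrid
classes, a forward-time island simulator, two hybrid-assignment engines
plus DAPC, and threshold-based power evaluation. The numbered scripts
under `analysis/` run the sequence; every computation lives in package
functions so it is unit-tested and reusable.

## Data model

A `geno_tab` stores an unordered pair of integer allele labels (binned
fragment sizes) per individual and locus, with populations as labels on
individuals. Half-calls are normalised to missing (GENEPOP convention);
allele registries are per locus and stable across read/write, and the
GENEPOP writer records population labels on the title line so round
trips are exact. Allele binning itself is out of scope: inputs are
already-binned genotypes.

## Marker validation

**Exact Hardy–Weinberg tests.** The null conditional distribution of a
genotype table given its allele counts (Levene) is exactly the
distribution obtained by pairing the observed gene copies at random. The
Markov chain therefore walks over copy-to-individual assignments by
swapping one gene copy between two random individuals — a symmetric
proposal needing no rejection step — and the one-sided p-value is the
chain occupancy of tables with a heterozygote count as extreme as
observed (deficit: fewer or equal; excess: more or equal). Defaults
follow common practice: 10,000 dememorization steps, then 100 batches of
10,000 sweeps, with the standard error taken across batch means. The
heterozygote count is used as the ordering score; for two alleles this
is equivalent to the classical U ordering. Monomorphic (population,
locus) combinations yield an *undefined* test and are excluded from
battery denominators — which is why a 16-locus, 4-population panel with
one monomorphic locus yields 63, not 64, tests.

**Linkage and differentiation tests.** Genotypic disequilibrium (no
phase assumed) and population differentiation are tested on contingency
tables by Monte Carlo: null tables are drawn directly from the
fixed-margins conditional distribution (`r2dtable`) and scored by the
log-likelihood-ratio G statistic; `p = (1 + #{G* >= G}) / (B + 1)`.
Independent draws replace the chain here because the conditional
distribution is exactly samplable. Per-locus differentiation tests are
combined by Fisher's method with `df = 2 x` the number of defined tests.

**Multiplicity.** Batteries are grouped (HWP by population, LD by locus
pair) and adjusted within groups by Benjamini–Yekutieli, which is valid
under arbitrary dependence. Whether a battery's significant count
exceeds chance is judged against the cumulative binomial at
`alpha = 0.05`; because the strictness convention for the "expected by
chance" count is ambiguous, `binomial_excess()` reports the critical
count under both conventions and the exceedance probability itself.

**Dropout model.** Each transmitted allele copy drops independently with
a locus rate `d`: a heterozygote losing one copy is observed as a
homozygote, losing both gives a missing call, and homozygotes stay
visible after one drop (so `d^2` of calls vanish entirely). True
genotype frequencies use population allele frequencies plus a
homozygote-excess parameter `F`, so Hardy–Weinberg proportions are not
assumed. A per-locus fit of both `d` and `F` is not identifiable — the
likelihood can trade a locus's dropout against inbreeding. The EM is
therefore run jointly over the loci of a population with `F` shared
genome-wide while `d` stays locus-specific and is anchored by the
missing-data rate; this is the cross-locus structure that separates
genuine inbreeding (uniform across loci) from genotyping artefacts
(locus-specific, missingness-linked). Correction replaces an observed
homozygote by the most probable true genotype when the posterior favours
a heterozygote; observed heterozygotes are never altered, and imputing
missing calls is optional and off by default so the missing-data filter
still sees the raw pattern.

**Filtering.** Loci monomorphic over the pooled data, or with more than
12% missing calls in any single population, are removed with a reasoned
report; filtering is idempotent.

**Outlier scan.** Neutral expectations for the spread of F_ST given
heterozygosity come from a parametric island-model null: per simulated
locus, ancestral frequencies are drawn over a locus-matched allele
count, deme frequencies follow the many-deme equilibrium Dirichlet with
concentration `M` (tuned in three iterations so the simulated mean theta
matches the observed global theta), genotypes are sampled at the
observed sample sizes, and Weir–Cockerham theta is computed. Each
observed locus gets a tail rank among simulated loci in its
heterozygosity bin (50 bins, widened until at least 100 simulated loci
are available), B–Y adjusted. This parametric equilibrium replaces
per-locus coalescent simulation; its type-I error on forward-simulated
neutral data sits slightly conservative of nominal (the acceptance suite
checks the 1–10% band at `alpha = 0.05`).

## Diversity and differentiation

Unbiased expected heterozygosity is `(2n/(2n-1))(1 - sum p^2)` per
locus. Allelic richness uses exact rarefaction to `g` gene copies, with
`g` defaulting to the smallest per-(population, locus) copy count so
values are comparable across sample sizes of 20–58. F_IS is the
Weir–Cockerham within-population `f`, components summed over alleles
and loci before the ratio, with a percentile bootstrap over loci
(10,000 replicates) for the interval; negative values (heterozygote
excess) are reported as computed. Between populations, theta is the
Weir–Cockerham variance-components estimator (a/(a+b+c), summed over
alleles and loci before the ratio, unequal sample sizes handled by the
n_c correction), and Jost's D uses the Nei–Chesser unbiased H_S/H_T
with harmonic-mean sample size; loci are combined by the harmonic mean
of per-locus D when all are positive, falling back to the arithmetic
mean (flagged) otherwise. Whether the source tables used Nei-unbiased
or plain gene diversity is not documented; unbiased was chosen and is
flagged in output. Bootstrap intervals are percentile (2.5/97.5) over
loci throughout.

## Effective population size (LD method)

Burrows' composite disequilibrium Delta is computed for every allele
pair of every locus pair (singleton alleles — single copies in one
heterozygote — are screened out first, as they generate spurious
associations), converted to r² with the within-locus Hardy–Weinberg
departure in the denominator, and averaged weighted by pairwise sample
size. The sampling expectation of r² under random mating uses the
standard regression approximations (separate branches for S >= 30 and
S < 30), and Ne follows from the drift quadratic; a non-positive
adjusted r² reports infinity rather than a negative size. Confidence
intervals jackknife the mean r² over loci, convert its variance into an
effective chi-square degree of freedom, and transform the chi-square
bounds through the Ne formula — which keeps the interval's asymmetry.
Fixed-S comparisons repeat the estimate on random subsamples (default
100, count not documented in the source material) and report harmonic
means. Random mating is assumed throughout.

One emulation caveat: multinomially sampled synthetic populations carry
no drift LD, so finite Ne values cannot arise from them. The estimator
is validated instead by parameter recovery on Wright–Fisher samples,
including the study-like operating points (66 breeders with 58 sampled;
6 breeders with 20 juveniles sampled).

## Hybrid classes and simulation

A genotypic class is a gene-origin probability vector `(z11, z12, z22)`
over two parental pools: P1 (1,0,0), P2 (0,0,1), F1 (0,1,0), F2
(1/4,1/2,1/4), first/second backcrosses toward each parent (1/2,1/2,0),
(3/4,1/4,0) and mirrored. `hybridise()` draws, per offspring and locus
independently (no linkage, matching multinomial gamete sampling), one
gamete from each pool. The crossing topology is the standard
construction: F2 = F1 x F1, first backcross = parent x F1, second
backcross = parent x first backcross, each stage re-estimating pool
frequencies from its simulated cohort. Scenario S1 simulates 100
individuals per class from the two reference populations and samples 50
uniformly without replacement as the mixture analysed alongside the
untouched references. The class list of the original S1 enumerates four
classes but a 500-individual pool; F1 was chosen as the fifth class
(it is required to build every other hybrid class anyway and appears in
the assignment figures); the roster argument accepts either variant.

## The island simulator and scenario S2

The forward-time simulator evolves `loci` independent loci in a
hierarchical finite island model (two demes of two populations) with
non-overlapping generations: each parent of each offspring is drawn by
first choosing a source population through the migration kernel — so
gene lineages migrate independently, the assumption under which
theta approaches the coalescent island expectation
`1/(1 + 4 N m n/(n-1))`, which the tests verify within 30% — and
mutation is k-allele (k = 20, the simplest reading of "ideal
microsatellites") with stepwise available. Initial state is maximal
diversity; runs approach mutation-drift equilibrium from above.

The original S2's simulator settings are not documented, so the
configuration is calibrated: `calibrate_island()` grid-searches
mutation and between-deme migration for mean within-population H_E in
[0.38, 0.58] and between-deme theta in [0.3, 0.5]. Those windows admit
two regimes. With loose demes (within-deme theta ~0.1–0.2) the
non-parental reference populations A1/B2 are poor stand-ins for the
parental pools A2/B1 and assignment power collapses — the opposite of
the reported S2 behaviour, where references were assigned *better* than
in S1. The default therefore uses the tight-deme regime
(`N = 100`, `m_within = 0.02`, `m_between = 5e-4`, `mu = 8e-4`, 800
generations; realised He ~0.49, theta(A2,B1) ~0.41, within-deme theta
~0.05), under which S2 behaves as reported: no false positives, fewer
false negatives and higher detection than S1. `build_s2()` hybridises
A2 x B1 exactly as S1 and assembles the mixture with A1 and B2, which
are never parents of any simulated hybrid.

## Assignment engines

**Bayesian MCMC over genotypic classes.** A Gibbs sampler alternates:
per-individual class labels (categorical, marginalising gene-copy
origins), per-(individual, locus) origin pairs given the class,
per-pool allele frequencies (Dirichlet, Jeffreys 1/2 prior), and class
mixing proportions (flat Dirichlet). The genotype likelihood under a
class is `z11 P(g|pool1) + z12 P(one copy from each) + z22 P(g|pool2)`;
missing genotypes contribute likelihood 1. Posterior membership is
label occupancy after burn-in (defaults 500,000 sweeps after 100,000;
the scenario analyses here use 50,000/10,000 with 3 replicates to keep
runs tractable — a package choice stated here once). Replicates are
independent and reported separately; replicate disagreement is a
finding, not an artefact to merge away. Because the pools are
exchangeable a priori, each run is re-anchored post hoc so pool 1 is
the pool favoured by a designated reference population, with raw
matrices retained. Reference individuals carry no fixed class priors by
default (a `ref_classes` option exists for sensitivity runs). For
validation, pool frequencies and mixing proportions can be frozen, in
which case the posterior must match (and in tests does match) direct
enumeration of class likelihoods.

**EM with hybridity coefficients.** Classes are gene-pool shares
`a` (P1 = 1, backcross-2 = 0.875, backcross-1 = 0.75, F1 = 0.5, ...,
P2 = 0); each gene copy is modelled as an independent draw from
`a f1 + (1-a) f2`. F1 and F2 share `a = 0.5` and are indistinguishable
by construction, so the roster carries a single F1 class. The E-step
computes memberships, the M-step re-estimates pool frequencies from
membership-weighted expected copy origins and mixing proportions by
maximum likelihood; the observed-data log-likelihood is monotone
(asserted in tests). Initialisation is geometric — a split by the sign
of the first principal component of the allele dosage matrix — with
seeded restarts if a pool degenerates, and the same anchoring option as
the MCMC engine. Frozen-frequency mode reduces the memberships to the
closed-form Bayes posterior, which the tests verify exactly.

**DAPC and cluster count.** Genotypes are coded as centred/scaled
allele dosages (missing values mean-imputed), reduced by PCA; the
retained PC count is chosen by stratified cross-validation on held-out
reassignment. The discriminant axes come from a direct between/within
eigendecomposition with a small ridge — equivalent to LDA with equal
priors after within-group whitening, but well-defined for perfectly
separable groups where off-the-shelf LDA fails on within-group-constant
variables. `find_clusters()` runs k-means on PCA scores with
`BIC(k) = n log(WSS/n) + k log(n)`, selects k by the diffNgroup idea
(2-means split of the successive BIC decreases, keep the solution after
the last sharp one), and declares no structure (k = 1) when no solution
improves on one cluster by more than twice the BIC penalty unit —
guarding against k-means carving noise.

## Power evaluation

`classify()` assigns the argmax class iff its membership strictly
exceeds the threshold (0.5 / 0.75 / 0.9), else UNASSIGNED — raising the
threshold can only unassign. Rates follow the source conventions: false
positives are pure individuals assigned to any hybrid class, false
negatives are hybrids assigned to a parental class, and the detection
rate credits any hybrid class for a true hybrid ("disregarding the
exact class"); detection + false negatives + unassigned hybrids
partition the hybrid set. Replicate agreement for the MCMC engine is
summarised as pairwise modal-class agreement.

## The synthetic study generator

`simulate_study()` is the stand-in for the deposited genotypes (all its
outputs are synthetic and labelled so): four populations at the study's
sample sizes (FLU 58, TRA 20, CAR 28, DRA 22 — the analysed sizes), 16
loci with 2–33 alleles, frequencies from a hierarchical F-model
(species-level drift F_sp = 0.25 over a shared ancestral base;
population-level drift 0.12–0.35, smallest for the introduced lake
population, largest for the supportively bred lake population), HW
genotype sampling, locus-specific dropout (most loci below 0.06, a few
at 0.15–0.39), one monomorphic locus, four loci with a guaranteed >12%
missing fraction in one population, and ~1% background missingness.
Realised values sit in the study's windows: per-population H_E roughly
0.34–0.62, between-species theta 0.33–0.50, within-species theta
0.21–0.30, global theta ~0.30, and the filter removes exactly 5 of 16
loci.

What the emulation does not reproduce — and hence what passing tests do
and do not show about the real data: the panel's exact allele-sharing
idiosyncrasies (synthetic loci separate first-generation backcrosses at
ceiling, so pooled backcross-detection rates run above the published
40–50%), drift LD within populations (no finite panel Ne), and
real-world Hardy–Weinberg departures beyond the dropout mechanism.
Structural outcomes (filter counts, test denominators, divergence
ordering, zero false positives, overall detection and false-negative
rates) do transfer and are asserted at binomial tolerances.

## Numerical choices and problem sizes

Monte Carlo p-values include the observed table (`(1+k)/(1+B)`), exact
ties in G broken with a 1e-9 tolerance; likelihood floors at 1e-300
guard log(0); EM convergence is log-likelihood change below 1e-6 (1e-8
for dropout); bootstrap and jackknife intervals are percentile and
chi-square-df respectively, as described above. Test and script runs
use reduced sizes chosen as package defaults for routine validation:
exact-test chains of 400–5,000 sweeps per batch, 500-locus neutral
panels for the outlier scan's error calibration, 50 Wright–Fisher
replicates for Ne coverage, and 50,000-sweep assignment runs; the
full-length settings remain the documented defaults of each function.

## Known limitations

Monogamy/sib-structure corrections for LD-Ne, temporal methods and
overlapping generations are out of scope, as are SNP/VCF input, linked
markers, STRUCTURE-style correlated-frequency admixture models and
BayeScan-style outlier detection. The dropout EM is a deliberately
simple re-derivation (the reference implementation's exact likelihood
is unpublished); its interface isolates it so a faithful port could
replace it. Classes older than second-generation backcrosses are not in
the roster — with ~11 microsatellites they are not detectable anyway,
which is the practical message of the power analysis.
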
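---
title: "Models and methods: abundance classes, network robustness, and null-model community assembly"
author: "AquaAssembly"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the statistics it
implements, the assumptions behind them, and the design choices made
where the methodology left room: what each null model randomizes, what
the synthetic-community generator does and does not emulate, which
numerical conventions are fixed, and where the approach is known to be
weak.

## The data model

The central object is an `OtuExperiment`, a `SummarizedExperiment`
whose single assay holds non-negative integer OTU counts (taxa ×
samples), whose `colData` carries at minimum a `region` factor (the
survey design emulated throughout is three lake regions sampled
18/12/18 — three, two and three plots × three biological replicates ×
two dates), and which optionally carries a rooted phylogeny with branch
lengths covering all taxa. Counts are normalized either by rarefaction
without replacement to the minimum sample depth (the default, because
Shannon and Bray–Curtis comparisons otherwise confound depth with
composition) or to per-sample relative abundances. The rarefaction seed
is part of the run configuration and is recorded in the pipeline log,
so normalized tables are exactly reproducible.

## Abundance classes

OTUs are partitioned by two thresholds applied jointly to the pooled
table across all samples:

* **abundant (AT)**: relative abundance > 1% in *at least one* sample
  AND mean relative abundance across all samples ≥ 0.1%;
* **rare (RT)**: relative abundance < 0.01% in *every* sample AND mean
  < 0.001%;
* **intermediate (IT)**: everything else.

Two readings of the local condition are possible ("exceeds 1% within a
sample" could mean any sample or a per-region average); the any-sample
(maximum over samples) reading is implemented because it makes AT and
RT provably disjoint and is the common usage of the dual local/regional
framework. Boundary handling is strict `>` on the AT local threshold,
`≥` on the AT mean, and strict `<` on both RT conditions. Per-region
class membership is derived afterwards by intersecting the global
assignment with regional presence (pooled count > 0); because presence
in a region requires at least one read, the *presence-filtered* RT
richness share is far smaller than the share of RT labels among all
taxa — the pooled classification is the one that shows the
richness–abundance decoupling symmetrically.

## Diversity, ordination and group tests

Shannon diversity uses the natural logarithm over nonzero proportions.
Bray–Curtis runs on relative abundances. PCoA Gower-centers −d²/2 and
reports negative eigenvalues but excludes them from the
percent-variance denominator. The ordination group test is a one-way
PERMANOVA (the field-standard companion to PCoA; the rank-based ANOSIM
is available behind a flag): pseudo-F from the within/between
decomposition of squared dissimilarities and p = (1 + #{F\* ≥ F}) /
(1 + n~perm~) under label permutation, with an exhaustive-enumeration
mode over all distinct label arrangements used by the test suite as its
own oracle. Per-taxon differential-abundance screening uses
Kruskal–Wallis with tie correction and Benjamini–Hochberg adjustment
across taxa; both raw and adjusted values are emitted, and the reported
"fraction significant" uses raw p < 0.05, the convention such counts
are usually printed under. Compact letters for ANOVA + Tukey–Kramer
HSD come from the greedy insert–absorb algorithm, lettering groups in
factor-level order. Spearman taxon–environment correlations use
average ranks for ties, exact p below 10 samples and the t
approximation otherwise, with stars on raw p (multiplicity-corrected q
is emitted alongside, since heatmap stars are conventionally
uncorrected).

## Co-occurrence networks and robustness

Networks are built over the `top_n` most abundant taxa (default 100,
ranked by mean relative abundance over the combined table; per-kingdom
quotas are available). Edge thresholds are |ρ| ≥ 0.6 with BH-adjusted
p ≤ 0.05 — the correlation and significance cutoffs are not
standardized in the amplicon-network literature, so the common choice
is the default and both are exposed in the configuration. Modularity
uses deterministic greedy agglomeration on the unweighted simple
graph; if the greedy cut ends below the trivial single-module
partition (possible on unsplittable graphs), Q = 0 with one module is
reported instead, so Q is never negative.

Robustness follows the random-attack convention: per iteration, remove
⌊f·n⌋ uniformly chosen nodes (f = 0.5 by default), then delete any node
left with no neighbours — a single cascade pass, since removing an
isolated node cannot isolate another — and record the surviving share
of the original n. A no-cascade variant would equal 1 − f identically
and could never differ between regions or abundance classes, which is
why the cascade definition is the meaningful one. Closed forms anchor
the tests: a 10-clique at f = 0.5 gives R = 0.5 exactly; a 10-node star
gives E[R] = 0.25 by enumerating the hub-in/hub-out cases. Class-wise
comparisons run the same simulation on induced AT/IT/RT subgraphs and
reuse the ANOVA + Tukey letters.

## Indicator species

For taxon t and group g, specificity A = (mean relative abundance in
g) / (sum of group means) — group *means*, not sums, so the unbalanced
18/12/18 design does not bias A toward the larger regions — and
fidelity B = share of g's samples containing t. IndVal~g~ = A·B, the
taxon's score is max~g~, and significance comes from permuting whole
sample labels (taxon covariance preserved), 999 permutations by
default. Strong indicators require IndVal > 0.7 and raw p < 0.05;
whether such p-values should be multiplicity-adjusted is left to the
user (BH-adjusted q is in the output; the strong flag uses raw p as
such screens conventionally do).

## Community assembly null models

**βMNTD** for samples k, l is ½[Σ~i~ f~ik~ min~j∈l~ d(i,j) + Σ~j~
f~jl~ min~i∈k~ d(j,i)] with patristic distances d and within-sample
relative abundances f (abundance weighting is the default, appropriate
for abundance data; uniform weighting is retained for testing). Shared
taxa contribute zero. **βNTI** standardizes the observed βMNTD against
tip-shuffling nulls: taxa are randomized across the whole phylogeny,
abundances untouched, implemented as row/column permutation of the
precomputed patristic matrix (mathematically identical to relabelling
tips, and orders of magnitude cheaper; the matrix is computed once per
tree and reused). Null standard deviations below 1e-12 (e.g. star
phylogenies, where every shuffle is identical) flag the pair as
degenerate rather than producing an infinite score. βNTI is invariant
to uniform branch-length scaling, which the suite verifies.

**RCbray** builds, per sample pair, null community pairs that fix each
sample's observed richness and total abundance: species are drawn
without replacement with probability proportional to pool occupancy,
then reads are filled in proportionally to pooled relative abundance.
The species pool is the whole table by default (whole-lake; a
restricted pool can be supplied), matching the view that any taxon
observed anywhere in the lake could in principle disperse to any site.
RCbray = 2[(#{BC\* < BC} + ½#{BC\* = BC})/n~null~] − 1.

The five-process partition is a pure threshold rule per pair: βNTI > 2
heterogeneous selection; βNTI < −2 homogeneous selection; otherwise
RCbray > 0.95 dispersal limitation, RCbray < −0.95 homogenizing
dispersal, else drift. When no usable phylogeny exists — the normal
situation for ITS-based fungal tables, where alignment quality rarely
supports a credible tree — βNTI is skipped with an explicit message and
the partition runs on RCbray alone, never inferring selection. This is
a deliberate conservatism: emitting fungal βNTI from an unreliable tree
would manufacture deterministic signal.

Defaults are 999 nulls for both models; the test suite and acceptance
script run 299 (null-model rates stabilize well before that, and the
full 66-pair × 299-null analysis of a 64-taxon, 12-sample dataset runs
in seconds).

## The synthetic-community generator

The generator exists to make every stage falsifiable: it must produce
data in which the true assembly regime is known and recoverable. Its
defaults mirror the emulated survey: three regions sized 18/12/18,
20,000 reads per sample, and a log-normal metacommunity (meanlog 0,
sdlog 2) whose heavy tail yields all three abundance classes with the
abundant class carrying > 80% of reads.

Communities are sampled in three stages: the regime sets each sample's
*expected* composition; the local community drifts around it
(Dirichlet with concentration `drift_intensity`, default 100, giving
between-replicate Bray–Curtis turnover around 0.2–0.4 as real lake
surveys show); and sequencing draws `depth` reads multinomially.
The drift stage matters: without it, replicate samples differ only by
multinomial noise and are therefore systematically *more similar* than
Raup–Crick null communities, so a drift-free "neutral" regime would be
classified wholesale as homogenizing dispersal. Ecological drift means
demographic divergence of local communities, not resampling error, and
the Dirichlet stage is its minimal model; `drift_intensity = Inf`
recovers the pure-multinomial limit for users who want it.

Regimes: *neutral* uses the metacommunity itself as the expectation;
*filtering* multiplies it by a Gaussian niche factor
exp(−(optimum − E)² / 2σ²) with per-region environments at the
5th/50th/95th percentiles of the optima (heterogeneous) or one common
median environment (homogeneous), σ defaulting to 0.3 trait standard
deviations; *dispersal_limited* gives each region a private
metacommunity (an independent permutation of the abundances across
taxa); *mixed* assigns regimes per region. Niche optima evolve by
Brownian motion on a Yule tree; because a single Brownian draw on a
small tree can by chance carry almost no tree-wide signal — in which
case filtering selects phylogenetically scattered taxa and no method
could read selection from the phylogeny — draws are repeated until the
trait–distance Mantel correlation reaches 0.3, which is the
conserved-trait contract the generator exists to provide
(`signal = FALSE` shuffles the accepted optima across tips to destroy
it). Two honest limitations follow from the construction: pairs
between the mid-gradient region and an extreme region show weaker
heterogeneous-selection signal than extreme-vs-extreme pairs (under
Brownian motion, intermediate trait values occur in many clades), and
the private-pool dispersal regime produces between-region Bray–Curtis
near but not at 1 (permuted pools share support, unlike strictly
disjoint pools).

What the generator does *not* emulate: chimeras and PCR/sequencing
error, within-region spatial autocorrelation beyond the plot labels,
seasonal turnover between the two sampling dates, and multi-trait
niches (the environment is a single latent gradient; the 12-variable
water-chemistry table is a separate, presentation-faithful generator
that draws each variable from its regional mean ± SE profile). Passing
tests therefore demonstrate that the *methods* recover planted truth
under realistic abundance structure — not that any particular field
dataset satisfies the regimes' assumptions.

## Numerical conventions

Percentages print with round-half-even to one decimal, one fixed
convention for every reported share, each accompanied by its numerator
and denominator. Permutation p-values use the +1-correction
(1 + hits)/(1 + n~perm~); exhaustive modes report the exact share of
arrangements at or beyond the observed statistic. Comparisons of
permuted statistics to observed ones use a 1e-12 slack so floating-point
ties do not flip counts. Every random stage draws a child seed by
hashing the stage name into the master seed, so adding or reordering
stages never perturbs the randomness of others. The shared-OTU
percentage is reported against two labelled denominators (union of all
OTUs; sum of per-region richness) because published per-region Venn
percentages are frequently inconsistent with either — only shared-set
percentages against the union are arithmetically stable.

## Problem sizes used by the automated checks

The test suite and acceptance script run the null models on 64-taxon,
12-sample communities (three regions of four), 299 nulls, three
independent simulations per regime — sizes at which the calibration
and recovery rates of interest are stable while a full run stays in
the tens of seconds; calibration of the permutation tests uses 500
replicate datasets at 199 permutations, chosen so the attainable
p-value grid brackets 0.05 tightly. The acceptance script pools the
filtering-recovery rate over six simulations because that rate has the
largest dataset-to-dataset variance (it inherits the variance of the
Brownian trait realization).

## Known limitations

βNTI values of different pairs from one dataset are strongly
correlated (they share one tree, one metacommunity realization), so
per-dataset calibration rates fluctuate more than naive binomial
intervals suggest; conclusions should pool several independent
datasets, as the checks here do. RCbray inherits the usual sensitivity
to the species-pool definition — a whole-lake pool makes
between-region turnover easier to flag as dispersal limitation than a
per-region pool would. The greedy modularity optimizer is deterministic
but not optimal; the suite bounds it by exhaustive search on small
graphs rather than pretending otherwise. Fungal (tree-less) assembly
partitions cannot distinguish selection from drift by construction.
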
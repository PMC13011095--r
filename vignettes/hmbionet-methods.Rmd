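---
title: "Methods: from soil contamination to microbial co-occurrence networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from soil contamination to microbial co-occurrence networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hmbionet)
```

## Scope

`hmbionet` implements the statistical pipeline of a two-area environmental
exposure study: quantifying heavy-metal soil contamination, comparing human
exposure and effect biomarkers between a contaminated area (CA) and an
uncontaminated area (UA), and characterising how the oral bacterial
community's co-occurrence structure differs between the areas. The pipeline
consumes pre-annotated feature abundance tables (taxa or KEGG orthologs per
sample); read QC, assembly and annotation are upstream of this package. A
seeded synthetic-data module generates inputs with the statistical
structure each stage assumes, so every stage is testable without any
sequencing data.

## Soil contamination indices

For each metal the contamination factor is the ratio of measured to
background concentration, `CF = C_metal / C_background`, categorised at the
conventional cut points: low (< 1), moderate (1–3), considerable (3–6),
very high (> 6). The published category definitions use strict
inequalities on both sides of each cut point, leaving the boundaries
undefined; this package assigns a boundary value to the *lower* category
and documents that choice here. The pollution load index is the geometric
mean of the CFs, computed in the log domain; `PLI > 1` flags contamination.

Area-level CFs are computed from the **area median** concentration.
Published area-level values are consistent with median-based CFs (e.g. the
CA cadmium CF equals the CA median over the cadmium background exactly),
and medians are what survey tables report. Per-site CFs and PLIs are also
returned for distribution-style summaries. Two PLI variants are provided —
the PLI of the median-based CFs and the mean of per-site PLIs — because
survey reports are frequently ambiguous about which aggregation they use;
neither is privileged by the package.

Between-area comparisons use the two-sided Mann–Whitney test: exact
enumeration when both groups have at most 12 observations and no ties,
otherwise the normal approximation with tie and continuity corrections.
Within-area metal–metal association uses Spearman correlation (exact
permutation p below n = 10, t-approximation above).

## Biomarkers

The systemic immune-inflammation index is
`SII = neutrophils / lymphocytes × platelets`, reported in the platelet
units; it is undefined at zero lymphocytes and the package refuses to
compute it rather than returning infinity. Urinary analytes can be
corrected for dilution by specific gravity,
`corrected = raw × (SG_ref − 1) / (SG_obs − 1)` with reference 1.020
(configurable), or by creatinine (`raw / creatinine`). The study text
names the specific-gravity correction while its tables print
creatinine-normalised units; both modes exist and neither is asserted as
"the" study computation. Marker comparisons reuse the Mann–Whitney
machinery; the marker–marker matrix is pairwise-complete Pearson
correlation with the three-star significance tiers used on such heat maps.

## SparCC correlation inference

Counts are compositional: closure to relative abundance induces spurious
negative correlation. SparCC estimates correlations between the
unobserved *basis* abundances from pairwise log-ratio variances
`T[i, j] = var(log x_i / x_j)`. Under a sparsity assumption the basis
variances solve a linear system in the row sums of `T`; correlations
follow from `cov_ij = (ω_i + ω_j − T_ij) / 2` and are clamped to
`[−1, 1]`. The most strongly correlated pair above the exclusion
threshold (default 0.1) is removed from the system and the solve is
repeated, up to `features − 4` exclusions — the method's de facto default
knobs, recorded in the result object. Zeros are handled by per-iteration
Dirichlet-posterior resampling of the per-sample fractions (prior 1 per
component); a deterministic +1 pseudocount mode is available. Estimates
are the mean over 20 inner resamples.

Pseudo p-values use the add-one rule
`p = (1 + #{null |ρ*| ≥ |ρ_obs|}) / (B + 1)` with `B = 100` null datasets
by default, so the attainable minimum is `1/(B+1)`. The default null
shuffles each feature's counts across samples independently, which
destroys between-feature association while preserving marginals; under
an exchangeable null these p-values are approximately uniform, which the
test suite verifies by Kolmogorov–Smirnov distance. A column-bootstrap
mode (resampling samples with replacement) is also provided; its
replicates centre on the observed estimate rather than on a null, so it
measures estimator stability and is *not* suitable for significance
testing — this is why it is not the default. Benjamini–Hochberg
adjustment runs over the strict upper triangle (each unordered pair
tested once; the diagonal is never tested).

## RMT threshold selection

The adjacency threshold is chosen from the eigenvalue statistics of the
thresholded correlation matrix. Eigenvalues are unfolded by fitting a
cubic smoothing spline (degrees of freedom ≈ n/10) to the empirical
cumulative spectral density and mapping each eigenvalue through it, which
rescales the nearest-neighbour spacings to mean 1. Ties — common in
heavily thresholded matrices — are broken by a seeded jitter of relative
magnitude 1e-10, with a warning when ties saturate half the spectrum.
Goodness of fit to the Gaussian orthogonal ensemble (Wigner surmise,
`P(s) = (πs/2)·exp(−πs²/4)`) and Poisson (`P(s) = exp(−s)`) laws is a
χ² statistic over 20 equal-probability bins on `s ∈ [0, 3]`. Grid points
whose retained matrix falls below 20 features are flagged unusable.

Two selection rules are implemented. The default `"transition"` rule
picks the first grid threshold at which the Poisson fit overtakes the GOE
fit — the standard noise-to-signal transition in RMT-based network
construction, since uncorrelated noise produces GOE statistics and
genuine modular structure produces Poisson statistics. The study that
motivated this package describes selecting the threshold where the
spacing distribution *best approximates the GOE prediction*, which is the
opposite orientation from common RMT practice; rather than guess the
intent, the `"best_goe"` rule is provided behind a flag and the
discrepancy is surfaced here. The default grid is 0.30–0.90 in steps of
0.02.

## Network construction and topology

An edge survives only if it passes **all** active filters: |ρ| at or
above the RMT threshold, |ρ| strictly above the 0.3 magnitude floor, and
BH-adjusted q strictly below 0.05. Features with no surviving edge are
dropped from the graph but preserved in a retention table. The degree
distribution diagnostic is ordinary least squares of log frequency on log
degree over nonzero-frequency degrees (a CCDF mode exists); this is the
conventional scale-free check for such networks, not a maximum-likelihood
tail fit, and is reported as slope and R².

The topology summary computes average degree, mean local clustering
(nodes of degree < 2 contribute 0), average geodesic distance, geodesic
efficiency and harmonic geodesic distance (`HD = 1/E` by construction,
averaged over connected pairs only, with the count of unreachable pairs
reported), Freeman centralisations of degree, betweenness, eigenvector
and closeness, *unnormalised* stress centralisation (published stress
centralisation values far above 1 indicate no normalisation), density,
modularity, transitivity and Krackhardt's connectedness, efficiency,
hierarchy and lubness. On undirected graphs hierarchy is identically 0
and lubness identically 1; they are reported anyway because the standard
metric table includes them. Modularity comes from the same partition the
role analysis uses, so the two never disagree.

The null model is G(n, m) — uniform random graphs with exactly the
empirical node and edge counts, matching "identical size and density" —
summarised as mean ± SD over 1,000 replicates by default.
Degree-preserving rewiring is deliberately not used. Robustness is
assessed by removing a fraction of nodes uniformly at random and tracking
the largest-component fraction and global efficiency, both normalised to
the intact node count so both responses reach 0 at complete removal.

## Node roles and keystone taxa

Modules come from deterministic greedy modularity agglomeration (the
study names no algorithm; greedy agglomeration is reproducible without a
seed and its partition feeds both the modularity value and the role
analysis). When the greedy partition has non-positive modularity the
trivial single-module partition is returned instead. Within-module
connectivity `Zi` is the z-score of the within-module degree among the
module's members, defined as 0 when the module's within-degree standard
deviation is 0 (including singleton modules) to prevent spurious hubs.
Among-module connectivity is the participation coefficient
`Pi = 1 − Σ_s (k_is / k_i)²`. Roles split at `Zi = 2.5` and `Pi = 0.62`:
peripherals, connectors, module hubs, network hubs; boundary values fall
in the lower category (the published definitions use strict inequalities
on both sides). Connectors and hubs are keystone taxa.

## Community ecology

Observed richness (Sobs), Chao1 and ACE are computed per sample. Chao1
uses the classic `S + F1²/(2 F2)` form, switching to the bias-corrected
`S + F1(F1−1)/(2(F2+1))` only when there are no doubletons; the mode used
is recorded per sample. ACE uses the coverage-based estimator with
rare/abundant cutoff 10; when coverage is degenerate (all rare features
are singletons) the Chao1 value is substituted so the estimate stays
defined. Beta diversity is the binary Jaccard distance,
`1 − shared/union` on presence sets (two empty sets give 0 with a
warning). PCoA double-centres the distance matrix and eigendecomposes;
negative eigenvalues are reported but excluded from the percent-variance
denominator, and no Lingoes/Cailliez correction is applied by default.

ANOSIM ranks all pairwise dissimilarities and computes
`R = (mean between-group rank − mean within-group rank)/(M/2)`; the
permutation p-value uses the add-one rule over 9,999 relabellings by
default. The implementation is independent of vegan's so that tiny
designs can be checked against full enumeration; the test suite verifies
agreement with vegan on the statistic.

Differential features use per-feature two-sided Wilcoxon tests on
relative abundances with BH adjustment over all tested features;
`log2FC` uses a pseudo-value of half the smallest nonzero relative
abundance. Volcano status is `up`/`down` only when both |log2FC| ≥ 1 and
q < 0.05 hold. Taxa–biomarker association uses Spearman correlation by
default (robust on abundances; a Pearson flag exists because the study
does not state the method for that figure), on subjects shared between
the tables, optionally after genus-level aggregation.

## The synthetic-data generator

Abundance tables are drawn from a logistic-normal/multinomial model:
multivariate normal log-basis abundances with a planted block correlation
structure, exponentiated, closed to proportions and sampled as
multinomial counts. This is the generative family under which SparCC's
own assumptions hold, making parameter recovery a fair test of the
inference stage rather than a tautology or an unfair one. Requested
correlation matrices are repaired to positive semi-definiteness by
clipping eigenvalues at 1e-8 and rescaling to unit diagonal; whether the
repair fired is recorded, because a repaired structure is no longer
exactly the one requested. Default group sizes are 26 and 11, the
sequencing sub-cohort sizes of the emulated study. The study does not
report per-sample post-filter depth, so the default depth of 50,000
counts per sample is this package's choice (recommended: at least 10×
the feature count). Soil surveys are log-normal per metal and area, with
default locations at the reference survey's log medians and scales
derived from its interquartile ranges — so generated surveys reproduce
the two areas' medians and spread, including the CA cadmium/lead excess.
Biomarker cohorts are log-normal with planted inter-marker correlation
and multiplicative group shifts, and always include the blood counts from
which SII is computable.

One master seed drives everything; each stage derives a child seed as
`(seed + 7919 × stage_index) mod (2³¹ − 1)` so stages are independently
reproducible. Generators save and restore the caller's RNG state.

What the generator does **not** emulate: sequencing error, assembly and
annotation error, taxonomic mis-assignment, zero-inflation beyond what
the multinomial induces, phylogenetic correlation, and longitudinal
structure. Passing recovery tests on these synthetics therefore shows the
estimators are correct under their own assumptions, not that real buccal
metagenomes satisfy those assumptions.

## Problem sizes and numerical choices

The test suite runs SparCC recovery at 100 samples × 50 features over 20
seeds (planted block correlation 0.7, recovery tolerance ±0.15), null
calibration at 50 samples × 30–50 features, the Erdős–Rényi clustering
check at n = 500, m = 5,000 over 200 replicates, and ANOSIM type-I
calibration over 1,000 null simulations of 12 samples — sizes chosen so
the whole suite completes in about a minute on one CPU while keeping
Monte-Carlo error well inside the stated tolerances. Geometric means are
computed in the log domain; correlation matrices are symmetrised and
clamped after floating-point arithmetic; `HD·E = 1` is exact by
construction and asserted to 1e-9.

## Known limitations

The pipeline reproduces the study's *procedures*; its empirical network
tables (749/7,285 and 427/3,372 node/edge networks, keystone identities,
ANOSIM R = 0.523) depend on the deposited sequencing data and are out of
desk-scale reach — only their arithmetically forced consequences (average
degree, density) and qualitative directions are checked. The stress
centralisation computes all-pairs geodesic counts and is quadratic in
memory, cubic in time; it is practical to a few thousand nodes.
Weighted-graph metric variants, UniFrac/PERMANOVA, and
maximum-likelihood power-law fitting are out of scope.
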
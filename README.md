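# hmbionet

Statistical pipeline for two-area environmental exposure studies that
link **soil heavy-metal contamination**, **human exposure and effect
biomarkers**, and **oral-microbiome community structure**. It is aimed
at environmental-health and microbiome analysts who have per-sample
feature abundance tables (taxa or KEGG orthologs), a soil survey with
regional background values, and a biomarker cohort, and who want the
full analysis chain — contamination indices through co-occurrence
network topology — as tested, reproducible R functions.

## What it computes

**Soil contamination.** Contamination factor
`CF = C_metal / C_background` with the conventional categories (low < 1,
moderate 1–3, considerable 3–6, very high > 6) and the pollution load
index `PLI = (CF₁ × ⋯ × CFₙ)^{1/n}`; area medians, Mann–Whitney
between-area comparisons and within-area Spearman correlation matrices.

**Biomarkers.** The systemic immune-inflammation index
`SII = neutrophils / lymphocytes × platelets`, specific-gravity and
creatinine dilution corrections for urinary analytes, Mann–Whitney group
tables and Pearson correlation matrices with significance tiers.

**SparCC co-occurrence networks.** Compositionally robust correlation
via pairwise log-ratio variances `T_ij = var(log x_i/x_j)` and the
basis-variance linear system, with iterative strong-pair exclusion and
Dirichlet resampling of fractions; permutation pseudo p-values
`p = (1 + #{|ρ*| ≥ |ρ|})/(B + 1)` and Benjamini–Hochberg adjustment over
feature pairs; edges kept only when `|ρ| > 0.3` and `q < 0.05`, with an
optional random-matrix-theory threshold selected from the
nearest-neighbour spacing distribution of the thresholded matrix's
unfolded eigenvalues (Wigner surmise vs Poisson χ² fits).

**Network topology.** The standard molecular-ecology metric suite (avgK,
avgCC, GD, geodesic efficiency and harmonic distance, Freeman
centralisations, stress centralisation, density, modularity,
transitivity, Krackhardt's connectedness/efficiency/hierarchy/lubness),
log–log power-law degree fits, Erdős–Rényi G(n, m) null ensembles
(mean ± SD over replicates), and random node-removal robustness curves.

**Node roles.** Greedy-modularity module detection; within-module degree
z-score (Zi) and participation coefficient (Pi); role classification at
`Zi = 2.5`, `Pi = 0.62`; keystone taxa = connectors and hubs.

**Community ecology.** Sobs/Chao1/ACE richness, binary Jaccard
distances, PCoA, ANOSIM with permutation p, Wilcoxon + BH differential
features with volcano status (`|log2FC| ≥ 1`, `q < 0.05`), and
taxa–biomarker correlation heat-map tables.

**Synthetic data.** Seeded generators for all three input kinds —
logistic-normal/multinomial abundance tables with planted block
correlations, log-normal two-area soil surveys, and correlated biomarker
cohorts — so the whole pipeline runs and is tested without any
sequencing data.

## Worked example

Area-level contamination factors from the packaged reference survey:

```r
library(hmbionet)
ref <- soil_reference()
cf  <- contamination_factor(ref$ca_median, ref$background)
data.frame(metal = ref$metal, cf = round(cf$cf, 2), category = cf$category)
#>   metal    cf     category
#> 1    Mo  0.50          low
#> 2    Sb  1.36     moderate
#> 3    Pb  3.10 considerable
#> 4    Mn  0.44          low
#> 5    Co  0.33          low
#> 6    Cu  1.14     moderate
#> 7    Zn  1.62     moderate
#> 8    Cd 16.36    very_high
pollution_load_index(cf$cf)$pli
#> [1] 1.319023
```

Cadmium is by far the worst contaminant in the contaminated area
(CF 16.36, very high), lead is considerable, and the aggregate PLI of
1.32 > 1 flags the area as contaminated overall.

A synthetic community with two planted correlation blocks, run through
SparCC, the edge filters, and the role analysis:

```r
st  <- correlation_structure(20, list(list(members = 1:6,  rho = 0.8),
                                      list(members = 7:12, rho = 0.8)))
tab <- generate_abundance_table(st, cohort_spec(c(40, 20), depth = 20000,
                                                seed = 1))
res <- sparcc_analysis(tab, n_bootstrap = 200, seed = 1)
nw  <- build_network(res, group = "demo")
nw
#> Co-occurrence network (demo) : 12 nodes, 30 edges
#> positive 100.00%, negative 0.00%
node_roles(nw)$partition
#> Module partition: 2 modules, Q = 0.5 ( fast_greedy )
```

The network recovers exactly the two planted 6-feature blocks
(2 × C(6,2) = 30 edges, no false positives among the 8 unstructured
features), and module detection finds the two blocks with the
closed-form modularity of two equal disconnected cliques, Q = 0.5.
`topology_summary(nw)`, `er_null_ensemble()`, and `robustness_curve()`
then characterise the network against its random-graph null.

An end-to-end run with synthetic inputs, writing all stage outputs and a
JSON summary plus a manifest with checksums and per-stage timings:

```r
mf <- run_pipeline(pipeline_config(out_dir = "demo_run", seed = 1))
```

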
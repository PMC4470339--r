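# meristemr

Consensus clustering and differential expression for developmental
time-course RNA-seq, built around the kind of experiment in which shoot
apical meristems (SAM) of *Arabidopsis thaliana* are sampled daily across
the floral transition (ten stages M1–M10, two biological replicates) and
sequenced in bulk. The package is aimed at analysts who want to move from a
gene × sample matrix of total gene read (TGR) counts to: stage-resolved
differential expression, data-driven groups of co-expressed genes, the
characteristic "transition point" expression patterns, and a quantitative
check of how well an independent replication experiment reproduces the
expression profiles.

## Methods at a glance

- **Normalization.** Median-of-ratios size factors: for sample *j*,
  `s_j = median_g( k_gj / (prod_j' k_gj')^(1/m) )` over genes with
  positive counts everywhere; normalized TGR = counts / `s_j`.
- **Differential expression.** For each pair of consecutive stages, a
  per-gene negative-binomial Wald test on log mean normalized counts with
  method-of-moments dispersion `alpha_g = max(0, (v_g − mu_g)/mu_g²)`
  shared against a robust mean–dispersion trend `a0 + a1/mu`
  (sharing mode "maximum"), referred to a t distribution with moderated
  degrees of freedom, and Benjamini–Hochberg control at FDR 0.05.
- **Profiles.** Replicate-averaged normalized counts per stage, divided by
  each gene's maximum (relative expression in [0, 1]). For a replication
  experiment covering a stage subset, both experiments share a per-gene
  maximum taken over the subset plus the first experiment's remaining
  stages.
- **Consensus clustering (the core).** `R` repeats of k-means on the
  profiles; `N(i,j)` counts how often genes *i*, *j* share a cluster;
  `D = R − N` is the consensus distance; a complete-linkage tree on `D` is
  decomposed by an adaptive (dynamic) cut with minimum cluster size 5,
  leaving diffuse genes unassigned. The same stack applied to mean cluster
  profiles, plus a profile-space consolidation pass, yields super-clusters
  whose mean profiles are averaged over all member genes.
- **Pattern classification.** TYPE_I = pronounced peak at the focus stage
  (M5); TYPE_II = up at M4 and M6 with a dip at M5; margin 0.2 on the
  relative scale.
- **Replication similarity.** `1 − mean_s (p_s − q_s)²` between two
  profiles over shared stages; reported per gene or per super-cluster with
  the summary median.
- **qPCR.** Relative quantification by ddCt: `2^(−ΔΔCt)` against the mean
  of the reference genes and a calibrator sample.

A negative-binomial simulator with planted profile archetypes (spike at
M5, dip at M5, M4/M6-up–M5-down, monotone, late burst, flat; per-sample
library factors; configurable dispersion) provides ground truth for every
stage of the pipeline.

## Worked example

```r
library(meristemr)

arch <- default_archetypes(n_genes_each = 100)[
  c("spike_m5", "m4_m6_up", "mono_up", "mono_down", "late_burst")]
sim <- simulate_counts(simulation_spec(arch, dispersion = 0.05, seed = 1))
res <- run_pipeline(pipeline_config(sim$counts, "demo_out", "desk", seed = 1))
```

prints

```
normalized 500 genes x 20 samples; 500 genes pass the expression filter
DE genes per consecutive stage pair: M1_vs_M2=0, M2_vs_M3=0, M3_vs_M4=0,
  M4_vs_M5=98, M5_vs_M6=107, M6_vs_M7=0, M7_vs_M8=0, M8_vs_M9=83, M9_vs_M10=0
tier 1: 60 clusters (69% of filtered genes); tier 2: 5 super-clusters (66%)
```

The DE series shows the burst of differential expression at the transition
stages (M4–M6) that the spike and double-peak archetypes plant, plus a
late burst at M8–M9. The five recovered super-cluster mean profiles match
the five planted archetypes (`round(res$super$mean_profiles, 2)`):

```
    M1   M2   M3   M4   M5   M6   M7   M8   M9  M10
1 0.28 0.29 0.27 0.29 1.00 0.27 0.24 0.26 0.23 0.23   # spike at M5
2 0.38 0.37 0.48 0.95 0.32 0.89 0.45 0.34 0.32 0.33   # M4/M6 up, M5 down
3 0.11 0.23 0.24 0.23 0.33 0.35 0.52 0.89 0.84 0.93   # monotone up
4 0.94 0.92 0.54 0.35 0.34 0.24 0.25 0.27 0.17 0.08   # monotone down
5 0.06 0.06 0.04 0.03 0.03 0.03 0.04 0.05 0.63 1.00   # late burst
```

and `table(res$patterns)` classifies exactly the planted 100 spike genes
as TYPE_I and the 100 double-peak genes as TYPE_II:

```
  OTHER  TYPE_I TYPE_II
    300     100     100
```

Against the planted labels, the gene-level super-cluster assignment has
adjusted Rand index 1.0 over the assigned genes (66% coverage; the dynamic
cut deliberately leaves diffuse genes unassigned). All output tables
(normalized counts, profiles, DE tables per stage pair, cluster and
super-cluster assignments and mean profiles, a JSON manifest) are written
to the output directory.

A thin command-line wrapper is included at `inst/cli/meristemr`
(subcommands `simulate` and `run-all`, YAML-configurable).

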
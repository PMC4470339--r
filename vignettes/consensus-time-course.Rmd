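---
title: "Consensus clustering of developmental time-course RNA-seq: models and choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Consensus clustering of developmental time-course RNA-seq: models and choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(meristemr)
```

This vignette is the package's account of its methods: the statistical
models, the parameters that matter, the numerical conventions, and the
design decisions that were genuinely open. The running application is a
bulk RNA-seq time course of shoot apical meristem development — ten
morphologically staged samples (M1–M10) in two biological replicates,
with the floral transition bracketed between M4 and M6 — but nothing in
the code is specific to that organism or stage count.

## The count model and the simulator

All synthetic data are negative binomial in the mean–dispersion
parameterization: a count with mean $\mu$ and dispersion $\alpha$ has
variance $\mu + \alpha\mu^2$, so $\alpha = 0$ degenerates cleanly to
Poisson. A simulated gene belongs to one archetype with a shape vector
$f \in [0,1]^{10}$ (maximum exactly 1); its count in replicate $r$ of
stage $j$ is

$$K_{gjr} \sim \mathrm{NB}\big(s_{jr}\, b_g\, f_g[j],\ \alpha\big),$$

with the base mean $b_g$ drawn log-uniformly from the archetype's
`base_mean_range` and the per-sample library factor $s_{jr}$ drawn
log-uniformly from `size_factor_range` (log-uniform because library-size
variation is symmetric in ratio space). Seven default archetypes ship
with the package — flat, spike at M5, dip at M5, M4-up/M5-down/M6-up,
monotone up, monotone down, late burst at M9–M10 — chosen to give the
clustering and the pattern classifier non-trivial, distinguishable
targets. Defaults: dispersion 0.05 and base means of 200–1000 counts at
the profile maximum, plausible for well-expressed genes in a 20M-read
library and chosen for testability rather than as a fit to any particular
data set; size factors in [0.5, 2].

RNG discipline: one user seed; every sample column and every k-means
repeat draws from its own sub-stream derived by hashing the seed with a
string tag (`derive_seed`). Because the stream for a column is keyed by
(stage, replicate) only, a replication experiment over a stage subset
with the same seed reproduces the original columns exactly — a testable
contract — and with a fresh seed gives fresh noise and fresh library
factors for the same genes.

What the generator does **not** emulate: read-level sampling (no
gene-length or GC bias), count correlation between genes, batch effects
beyond library size, and — importantly — the global composition shifts of
real development, where *most* genes change and no archetype is "flat by
majority". Passing tests on this generator therefore demonstrate the
correctness and calibration of the machinery, not biological fidelity.

## Normalization and profiles

Size factors are plain median-of-ratios: the median over zero-free genes
of the ratio of a gene's count to its across-sample geometric mean. Genes
with any zero are excluded from the median (the log of zero is
undefined; this matches standard practice), an even count of usable genes
takes the arithmetic mean of the two central ratios, and a matrix with no
zero-free gene raises an explicit error. One mathematical point deserves
note because it is often mis-stated: multiplying one of $m$ samples by
$c$ multiplies that sample's factor by $c^{1-1/m}$ and the others by
$c^{-1/m}$ — the per-gene geometric mean absorbs $c^{1/m}$ — so factor
*ratios* scale by exactly $c$ and normalized values are invariant only up
to the common factor $c^{1/m}$. The tests assert this exact law rather
than the folklore version. Likewise, factors recomputed on an
already-normalized zero-free matrix all equal the geometric mean of the
original factors (not 1 exactly).

Relative expression divides each gene's replicate-averaged stage means by
the gene's maximum; all-zero genes are passed through as all-zero and
flagged rather than generating NaN. When a replication experiment covers
only a stage subset (e.g. M3–M7), both experiments are scaled by a shared
per-gene maximum taken over the replication's stages plus the first
experiment's non-overlapping stages, which makes cross-experiment
profiles directly comparable; a consequence worth knowing is that a
first-experiment value may exceed 1 at a shared stage if the two
experiments disagree about the size of the maximum.

The expression filter keeps genes with at least 5 normalized counts in
*all* replicates of at least one stage (boundary inclusive). The
threshold is exposed (`filter_threshold`, `--min-normalized-count`); 5 is
the conventional "reliably detected" level for libraries of this depth.
The related notion of a "detected" gene (count > 0 in both replicates of
some stage) is reported descriptively only; no published threshold exists
for it, so the choice is explicit and configurable rather than an
inference of anyone's intent.

## Differential expression

Each consecutive stage pair is tested separately, per gene, on normalized
counts:

- **Dispersion.** Method of moments from the pooled within-condition
  variance, $\hat\alpha_g = \max(0, (v_g - \mu_g)/\mu_g^2)$. With two
  replicates per condition this estimate is extremely noisy, so a robust
  trend $\alpha(\mu) = a_0 + a_1/\mu$ (Huber regression across genes) is
  fitted and each gene uses the *larger* of its own estimate and the
  trend ("maximum" sharing). Underestimating dispersion inflates false
  positives; this one-sided sharing is the conservative classical remedy.
- **Test.** Wald statistic on the difference of log means with
  $\mathrm{SE}^2 = (1/\mu_A + \alpha)/n_A + (1/\mu_B + \alpha)/n_B$.
  The statistic is referred to a t distribution with residual degrees of
  freedom plus a moderation credit of 2 for the information contributed
  by the trended dispersion (df = 4 at 2+2 replicates). The normal
  reference is measurably anticonservative in the far tail at this sample
  size — with 2,000 genes the Benjamini–Hochberg step-up probes p-values
  of order $10^{-5}$, exactly where the log-mean statistic is least
  normal — and the package's global-null calibration study (criterion
  re-run by `scripts/acceptance.R`) is what motivated the correction.
- **Degenerate cases.** Genes all-zero in both conditions are excluded
  from testing and from the BH denominator (untestable hypotheses would
  inflate the correction); their p, q and DE call are NA. If exactly one
  condition mean is zero the fold change is reported as a signed infinity
  and the Wald statistic is formed on the mean scale, keeping p finite.
- **FDR.** BH step-up at 0.05 by default (`fdr`).

Swapping the conditions flips the sign of the log2 fold change and leaves
p-values unchanged; the series over M1–M10 is literally nine independent
pair tests, not a joint time-course model (no spline or likelihood-ratio
testing across all stages — the design tests adjacent transitions).

## The consensus clustering core

The feature space for both tiers is replicate-averaged, max-normalized
relative expression. This was a genuinely open choice — one could cluster
normalized counts directly — but a single consistent [0, 1] feature space
prevents absolute expression magnitude from dominating shape, which is
the quantity of interest; the mean profiles reported at both tiers are
means on this same scale.

1. **Ensemble.** `repeats` independent runs of `stats::kmeans`
   (Hartigan–Wong, Euclidean distance, iteration cap 300) with initial
   centers sampled from distinct rows; an empty-cluster failure is
   retried with fresh centers and, as a last resort, resolved by
   nearest-center assignment. If fewer distinct rows than k exist, the
   distinct rows serve as centers. Per-repeat labels are arbitrary; only
   co-membership matters.
2. **Consensus distance.** $N(i,j)$ = number of repeats in which genes
   $i, j$ share a cluster; $D = R - N$. Integer arithmetic, so the model
   invariants ($N$ symmetric, $N(i,i) = R$, $D = R - N$) hold exactly.
3. **Tree.** Complete linkage on $D$. Complete linkage keeps merge
   heights bounded by $R$, pairing naturally with the bounded consensus
   distance; it is also the default of the statistical environment this
   style of analysis is usually run in.
4. **Dynamic cut.** A hybrid cut using both the tree and the distance
   matrix. The dendrogram is split recursively from the root: a branch
   splits when both sub-branches hold at least `min_size` items (default
   5) *and* the mean between-branch distance exceeds the larger mean
   within-branch distance by more than `min_gap` (default 0 — the deepest
   split). Merge heights themselves are deliberately not used: with k far
   above the number of planted groups, complete-linkage heights saturate
   at $R$ near the top of the tree and carry no signal. Branches too
   small to stand alone drop into a pool; pooled items then re-attach to
   the cluster with the smallest average distance, provided that distance
   does not exceed the cluster's radius (the largest member-average
   within distance), computed against the original cores so the result is
   independent of processing order. Everything else stays unassigned —
   an explicit feature of the method, not a failure mode: diffuse genes
   should not be forced into clusters.

The deep split over-fragments by design: at full scale (k = 1500, 1000
repeats over ~20,000 genes) this regime yields thousands of small
clusters, and that is what the second tier exists for.

5. **Super-clustering.** The identical stack applied to the tier-1 mean
   cluster profiles (`k2`, same repeats, same min size), followed by two
   profile-space passes. The merge pass addresses a structural blind spot
   of consensus distances: k-means with more centers than groups splits a
   tight homogeneous group the *same way in every repeat* (the split
   tracks the group's largest-variance axis, not the initialization), so
   co-occurrence can declare two halves of one group maximally distant.
   The remedy is a separation statistic in the space where "similar
   profile" is defined: project the member genes of two groups onto the
   axis joining their centroids and compute
   $t^2 = (\bar p_1 - \bar p_2)^2 / (v_1 + v_2)$ of the projections.
   Halving one Gaussian cloud gives a universal $t^2 \approx 3.5$
   regardless of scale, while genuinely distinct expression patterns sit
   one to two orders of magnitude higher; groups below the threshold
   `consolidate` (default 20, an order of magnitude above the
   one-cloud constant) merge iteratively, closest pair first. The second
   pass re-attaches tier-1 clusters the cut left loose to their nearest
   super-cluster under the same statistic. Mean super-cluster profiles
   are computed over all member *genes*, not over cluster means, so a
   cluster of 15 genes outweighs a cluster of 5 — the arithmetic the
   reported profiles are defined by.

Determinism: identical (profiles, k, repeats, seed) give bit-identical
tiers; cluster IDs are assigned by smallest member index, and all
tie-breaks (nearest-cluster attachment, merge order) are deterministic.

## Pattern classification and replication similarity

A profile is TYPE_I when its focus-stage value (M5 by default) is the
global maximum and exceeds both neighbors (M4, M6) by at least the margin
$\delta$; TYPE_II when both neighbors exceed the focus value by at least
$\delta$; OTHER otherwise, with TYPE_I taking precedence. $\delta$
defaults to 0.2 on the relative scale — the shape classes are only
qualitative, so the margin is exposed (`margin`, `--margin`) rather than
hidden. Comparisons carry a $10^{-9}$ epsilon so that a margin met
exactly in real arithmetic is not lost to floating point. With
$\delta = 0$ any strict focus-stage argmax is TYPE_I, and raising
$\delta$ can only move genes toward OTHER (monotone strictness).

Cross-experiment similarity is $1 - \frac{1}{S}\sum_s (p_s - q_s)^2$ over
the shared stages of jointly scaled profiles, so it is bounded in [0, 1]
on [0, 1] profiles and equals 1 exactly for identical ones. It can be
computed per gene or per super-cluster; super-clusters are matched across
experiments by gene identity through the first experiment's assignment
(the replication's profile is re-averaged from its own data over the same
member genes), never by re-clustering the replication — both pathways are
available because either could be meant by a "super-cluster similarity",
and matching by gene identity is the one that is well defined.

qPCR quantification is standard ddCt with multiple reference genes
combined by the arithmetic mean of their Ct values — the simplest
defensible multi-reference rule, configurable by passing any reference
set.

## Parameter presets and problem sizes

The `"paper"` preset (k = 1500, 1000 repeats, k2 = 100, min size 5, FDR
0.05) is the full-scale parameterization for a complete ~20,000-gene,
ten-stage transcriptome; the `"desk"` preset (k = 50, 100 repeats,
k2 = 10) is the same code path sized for interactive work. The package's
own studies run at desk scale: planted-structure recovery uses 500 genes
from the five well-separated default archetypes (the flat and M5-dip
shapes are omitted there because each is nearly the other's complement
and they are not mutually well separated), 20 seeds; DE calibration uses
2,000 genes × 100 seeds under the global null and 2,000 genes with 100
planted 8-fold changes for power; replication similarity uses the full
seven-archetype generator over stages M3–M7, 10 seeds. Recovery is scored
by adjusted Rand index over the genes assigned to a super-cluster, with
coverage reported separately — the method defines an explicit unassigned
set, so conflating coverage with accuracy would double-count; at full
scale the corresponding analysis also clustered only about three quarters
of expressed genes.

## Known limitations

- The DE stage is a two-group Wald test per stage pair; it shares
  information across genes (the dispersion trend) but not across stages.
- Consensus clustering costs $O(n^2)$ memory for $N$ and $D$; at 20,000
  genes the matrices are ~3 GB as integers, so full-scale runs need
  memory of that order (or a blocked co-occurrence accumulation, not
  implemented).
- The profile-space consolidation statistic assumes groups that are
  roughly unimodal along the axis joining their centroids; adversarial
  geometries (e.g. concentric groups) could fool it.
- Median-of-ratios normalization assumes a majority of genes unchanged
  between samples; in a developmental series where most genes move, the
  estimated factors absorb some composition shift. The simulator's
  ground-truth factors make this visible in tests; on real data it is an
  intrinsic property of the normalization, not of this implementation.
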
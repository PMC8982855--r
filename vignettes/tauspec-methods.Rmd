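---
title: "Methods: tissue specificity, ectopic expression and peak analytics"
author: "tauspec"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: tissue specificity, ectopic expression and peak analytics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tauspec)
```

# What the package computes

`tauspec` implements the statistical layer of a common experimental
design in chromatin biology: a regulator that normally silences
tissue-restricted genes (testis-specific genes, transposons, repetitive
DNA) is removed, and the transcriptome and the regulator's chromatin
binding profile are read out together. The package covers five
connected analyses:

1. **Tissue-specificity classification** of an expression atlas with
   the τ index.
2. **Count normalization** (GC-content and depth full-quantile
   normalization) feeding a **negative-binomial GLM** with Wald tests,
   BH correction and heavy-tailed-prior LFC shrinkage, plus a
   consistency rule for a 2 genotype × 2 age design.
3. **Ectopic-expression calling**: genes silent in wild type that turn
   on in the mutant, decided on RPKM with rank tests.
4. **Over-representation** of gene sets among fold-change extremes, and
   positional gene-cluster summaries.
5. **Peak-set interval analytics**: mock subtraction, merging,
   TSS-window annotation, promoter density profiles, genome bin
   coverage, and randomization-based overlap enrichment, plus
   IP-vs-mock repeat enrichment anchored on genomic bins.

A seeded synthetic-data generator plants ground truth for every stage,
so the whole pipeline is testable without external data.

# The τ index and gene classification

For a gene with log2(RPKM) values $x_1, \dots, x_n$ across $n$ tissue
groups,

$$\tau = \frac{\sum_{i=1}^{n} (1 - \hat{x}_i)}{n - 1},
\qquad \hat{x}_i = \frac{x_i}{\max_i x_i}.$$

τ is 0 for uniform expression and 1 for single-tissue expression.
`classify_genes()` applies three rules, in order:

* **NotExpressed** — log2(RPKM) ≤ 1 (RPKM ≤ 2) in *every* tissue.
  Zero-RPKM cells are excluded from the log transform and treated as
  below the floor.
* **NotEnriched** — expressed, but τ < 0.70, or no tissue exceeds the
  across-tissue mean by more than 1.5 sample standard deviations.
* **Enriched** — τ ≥ 0.70 with a non-empty enriched-tissue set
  (several tissues may qualify simultaneously).

Numerical choices worth knowing:

* Negative log2(RPKM) values (RPKM < 1) are clipped to 0 before τ so
  that $\hat x_i \in [0,1]$; the index presumes non-negative
  expression and this keeps it bounded without changing the ordering
  of specific versus broad genes.
* The standard deviation uses the $n-1$ denominator.
* With few tissues, a single enriched tissue cannot exceed the 1.5 SD
  cutoff: the largest attainable z of one outlier among $n$ values is
  $(n-1)/\sqrt{n}$, which is exactly 1.5 at $n = 4$. Atlases should
  provide five or more tissue groups for the enrichment rule to be
  able to fire on single-tissue genes.
* Whether "not expressed" should mean *all* tissues below the floor or
  *at least one* is genuinely ambiguous in the source material of this
  kind of classification; the package defaults to the *all* reading
  (the operational definition that matches an "expressed anywhere"
  universe) and exposes the other via
  `tau_config(not_expressed_rule = "any")`.

# Normalization

The count-level normalization follows the EDAseq-style order: low-count
filter → within-lane GC normalization → between-lane depth
normalization → offsets.

* `filter_low_count()` removes features whose mean raw count across all
  samples is ≤ 10 (boundary inclusive: a (10, 10, 10) feature is
  removed).
* `within_lane_gc_fqn()` bins features into 10 equal-occupancy GC
  strata per sample and replaces each stratum's counts by the values at
  matching quantiles of that sample's pooled count distribution.
  Quantile matching interpolates linearly between order statistics and
  averages reference values across ties; the map is monotone within
  strata, and a single stratum is the identity.
* `between_lane_fqn()` maps each sample's sorted counts to the mean of
  the samples' sorted vectors (classic full-quantile depth
  normalization). Depth normalization is conventionally unstratified
  and that is the default; a GC-stratified variant is available through
  the `gc`/`n_strata` arguments for pipelines that keep the strata
  through this step.
* `compute_offsets()` returns `log((raw + 0.1)/(normalized + 0.1))`.
  The pseudocount 0.1 avoids log(0) while staying small relative to
  every threshold in play. Feeding raw counts plus these offsets to the
  GLM reproduces inference on the normalized counts.

# The NB GLM engine

The differential-expression engine is deliberately compact — a
log-link negative-binomial GLM fit by IRLS with fixed per-feature
dispersion, Wald z tests and BH correction — rather than a re-creation
of a full production engine. Exact numerical parity with DESeq2 or
apeglm is a non-goal; the package's contracts are calibration and
parameter recovery, which the test suite checks by simulation.

**Dispersion.** Per feature, a method-of-moments estimate
$\hat\alpha = \max(0, (s^2 - \bar\mu)/\bar\mu^2)$ is computed from
pooled within-group variances of offset-corrected counts. A parametric
mean–dispersion trend $\alpha(\mu) = a_0 + a_1/\mu$ is then fitted
across features by least squares on the mean scale, and the final
dispersion is the geometric mean of $\max(\hat\alpha, \text{trend})$
and the trend. Two aspects of this design matter:

* The trend is fitted on the *mean* scale, not by regressing
  $\log\hat\alpha$ on $\log\mu$. With 2–3 replicates per group the
  moment estimate is extremely noisy and frequently zero; a log-scale
  fit over the positive subset underestimates the dispersion level
  (Jensen's inequality plus selection), which deflates Wald standard
  errors and inflates the type-I error well beyond its nominal level.
  The mean-scale parametric fit is unbiased for the level and restores
  calibration (the suite verifies a null p < 0.05 fraction of
  0.05 ± 0.015 on 2000 features at 3 vs 3).
* Estimates *below* the trend are floored at it before the 50/50
  log-scale shrink. At these degrees of freedom a downward excursion is
  indistinguishable from sampling noise, and propagating it produces
  spuriously small standard errors. Features with exactly zero residual
  variance keep α = 0.

**Shrinkage.** `shrink_lfc()` computes the maximum-a-posteriori LFC
under a zero-centered Cauchy prior on the tested coefficient. The prior
scale is chosen by maximizing the approximate marginal likelihood over
the feature panel (normal likelihood integrated against the prior on a
grid). The estimate never exceeds the MLE in magnitude, never flips
sign, and converges to the MLE as the standard error vanishes — the
properties that matter for ranking low-count features.

**The consistency rule.** For the 2 genotype × 2 age ovary design,
`consistent_de_call()` calls a gene only if (a) the genotype main
effect in the additive model `~ age + genotype` passes FDR < 0.01 and
(b) the per-age genotype contrasts agree in sign. The stricter reading
— additionally dropping genes with a significant genotype × age
interaction — is available via `strict = TRUE` but is not the default:
requiring same-sign replication across ages is the primary contract,
while excluding every gene that responds to age at all would discard
most of a maturing tissue's transcriptome.

**Repeat enrichment.** `repeat_enrichment()` tests repeats for
IP > mock while normalizing against genomic reads: size factors come
from median-of-ratios restricted to genomic-bin features, so a global
IP/mock depth difference cannot masquerade as enrichment (a planted
2× depth confounder yields zero calls in the suite). The full
antibody + replicate + condition design is saturated per sample, so
dispersion is estimated from the condition groups. The BH family is
the repeats only — bins are the normalization anchor, not hypotheses —
and a repeat is reported enriched only when the per-antibody contrasts
agree in sign, excluding effects driven by one antibody or cell
population. FDR 0.05 is the default here, versus 0.01 for gene calls.

# Ectopic-expression calling

`call_ectopic()` works on RPKM computed *without* the low-count filter
(ectopic genes live below it by definition) and applies two gates:

1. **Silent in wild type**: mean WT RPKM < 2 *and* a one-sided exact
   Wilcoxon signed-rank test of the replicate RPKMs against 2.0 at
   p < 0.1. The comparator of this inertness test is ambiguous in the
   field's usage (a two-sample Mann–Whitney needs a second sample, yet
   the criterion references the constant 2.0); the signed-rank reading
   is the default and a WT-below-mutant Mann–Whitney is available via
   `ectopic_config(silent_test = "mann_whitney")`. Note the exact
   signed-rank test cannot reach p < 0.1 with three replicates
   (minimum 1/8); the 2 × 2 ovary design pools both ages' wild-type
   samples (≥ 6 replicates, minimum 1/64), which is the intended use.
2. **Activated in the mutant**: among silent genes,
   fold = (mut + 0.01)/(wt + 0.01) > 2 admits the gene to a one-sided
   Mann–Whitney (mutant > WT) with BH correction over exactly the
   admitted set; adjusted p < 0.25 calls the gene ectopic. Genes
   failing the fold gate get an undefined q and stay outside the BH
   family, which makes the calls invariant to adding non-silent genes
   to the input.

The lenient 0.25 threshold is deliberate: with two replicates per side
the smallest attainable one-sided Mann–Whitney p is 1/C(4,2) ≈ 0.167,
so the threshold remains attainable at minimal replication.

# Set enrichment and cluster summaries

`percentile_enrichment()` ranks the expressed universe (the features
surviving the low-count filter) by *shrunken* LFC and takes the top and
bottom ⌈0.01 N⌉ genes; ranking by fold change rather than p-value
matches how such extremes are displayed and interpreted. Each gene set
is tested in each direction with the upper-tail hypergeometric
(`stats::phyper`), BH-corrected over all set × direction tests of the
run, with ties at the boundary broken by Wald p then gene id.
`cluster_lfc_summary()` reports per-gene and mean LFC of a co-located
cluster plus inter-gene distances (next gene's left-most coordinate
minus the current gene's right-most, regardless of orientation). When
every cluster gene falls below the count filter — the realistic outcome
in a tissue where the cluster is silent — the summary reports them as
missing instead of failing.

# Interval analytics

All coordinates are 0-based half-open internally (GTF input is shifted
on read; the TSS of a − strand gene is `end − 1`). Design points:

* `merge_intervals()` merges book-ended intervals (`bedtools merge`
  distance-0 semantics) and max-aggregates scores.
* `subtract_whole()` defaults to removing *entire* peaks with ≥ 1 bp of
  blacklist overlap (`subtract -A` semantics), the behaviour meant by
  removing IP peaks that co-occur with mock peaks; portion mode trims
  instead.
* `annotate_tss()` calls a gene bound when a peak has a base within
  1 kb of the TSS in either direction, and reports the signed
  strand-aware distance to the nearest peak edge (0 inside a peak,
  negative upstream).
* `density_profile()` anchors on summits by default (midpoints as the
  alternative when summit offsets are absent), bins strand-aware
  positions relative to the TSS, and normalizes frequencies to sum to
  one over the profiled window.
* `bin_coverage()` merges first so overlapping peaks cannot double
  count, and normalizes the final partial bin of each chromosome by its
  true width.
* `randomized_overlap_enrichment()` re-places query intervals uniformly
  at random (lengths preserved, excluded regions avoided by rejection,
  overlaps among placed intervals permitted — no isochore or
  composition matching) and reports observed/expected overlap with an
  add-one empirical p, so p > 0 always. Overlap is summed per query
  interval against the merged reference; with a reference covering the
  whole workspace this identity makes fold = 1 and p = 1 exactly. For a
  single query of length $L$, a reference of length $M$ and one
  chromosome of length $W$, the expected overlap is
  $LM/(W - L + 1)$, which the suite checks against the simulation at
  10,000 draws.

# The synthetic-data generator

The generator emulates the statistical structure the analyses assume,
with planted truth labels for every stage. Its defaults are the study
conditions of the package's target design:

* **Ovary counts**: 2 genotypes × 2 ages × 3 replicates; NB counts
  (variance $\mu + \alpha\mu^2$, α = 0.1) with per-sample depth factors
  (±30%) and a smooth per-sample quadratic GC-bias curve on the log
  scale (amplitude 0.5 log2 units) — smooth and invertible by
  stratified quantile normalization, which is exactly what the
  GC-normalization step targets. 5% of genes carry a ±2 log2 genotype
  effect at both ages, a disjoint 5% carry an age effect, and 2% are
  ectopic (WT RPKM 0.1–0.5 — not exactly zero, so the rank tests are
  exercised — mutant RPKM 5–10).
* **The planted cluster**: 12 adjacent genes on one chromosome, all
  ectopic, with high mutant expression (RPKM 20–60) so they rank among
  the most upregulated genes — the behaviour of the testis-specific
  reporter cluster this emulates, whose responsive core is 11–12 genes.
  Cluster, ectopic and upregulated-DE genes are also the atlas's
  "testis-like" (first-tissue) specific genes, so the derepression
  signature propagates coherently across the simulated assays.
* **The atlas**: 10 tissue groups; background genes log-normal around
  30 RPKM with 0.25 sdlog per-tissue scatter (high enough that
  borderline-expressed genes cannot leak into the Enriched class);
  tissue-specific genes sit on a low baseline (~1.2 RPKM) elevated
  16-fold in one tissue; 10% of genes are silent everywhere (RPKM < 2).
* **ChIP**: 2 antibodies × 2 replicates over a 2 × 2 Mb genome;
  80% of planted peaks have summits 150 bp upstream of a TSS
  (strand-aware, σ = 50 bp jitter), the rest uniform; mocks are a small
  subset of true sites plus noise. Repeat counts use a lower dispersion
  (0.02) than the ovary RNA — IP/mock libraries of the same cell
  population are far less variable than across-genotype tissue RNA —
  and planted repeat enrichment is 1.5-fold, below 2, matching the
  regime where peak callers struggle and count-based testing is the
  point.

What the generator does **not** emulate: mappability and copy-number
structure of real repeats, correlated gene-gene expression, isoform
structure, batch effects beyond smooth GC and depth, and read-level
artifacts. Passing recovery tests on this generator therefore
demonstrates that the statistical machinery is correct and calibrated,
not that any particular biological dataset will behave as cleanly.

# Problem sizes and determinism

The test suite and the acceptance script run at deliberately moderate
sizes — 5000 genes for recovery runs, 2000 features for calibration,
1000 randomization draws (10,000 for the analytic overlap check) —
chosen so the full suite completes in a few minutes while keeping
Monte-Carlo error far from every asserted margin. All generators and
the randomization test consume a single integer seed through R's
default Mersenne-Twister generator; identical seeds reproduce outputs
exactly, and the pipeline drivers record seeds and thresholds in their
JSON manifest.

# Known limitations

* The engine does not implement Cox–Reid adjusted likelihood,
  independent filtering, or outlier handling; very small dispersions at
  very low counts are handled by the trend floor rather than by
  per-feature inference.
* The ectopic inertness test is underpowered below six wild-type
  replicates by construction of the exact signed-rank distribution.
* Randomization enrichment assumes a uniform placement null; genomic
  co-location driven by sequence composition will inflate fold
  estimates relative to a composition-matched null.
* `classify_genes()` requires enough tissue groups (≥ 5) for the
  1.5 SD rule to be attainable for single-tissue genes.
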
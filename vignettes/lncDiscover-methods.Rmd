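---
title: "Methods: discovering interferon-associated lncRNAs by guilt-by-association"
author: "lncDiscover authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: discovering interferon-associated lncRNAs by guilt-by-association}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lncDiscover)
```

# The analysis problem

Long non-coding RNAs (lncRNAs) are abundant in innate-immune
transcriptomes but mostly uncharacterized. When monocytes are stimulated
through TLR4 (e.g. by LPS), hundreds of lncRNAs change expression
alongside the interferon-stimulated genes (ISGs) of the type I IFN
response. `lncDiscover` implements a guilt-by-association pipeline that
turns this observation into concrete candidates:

1. **Modulated lncRNAs.** From a 3-timepoint stimulation time course
   (t0, 1.5 h, 4 h), genes are tested with a negative-binomial
   likelihood-ratio test across timepoints; lncRNAs (biotype neither
   protein-coding nor pseudogene, transcript at least 200 bp) with
   BH-adjusted p < 0.05 are the modulated set.
2. **Kinetics.** Per-timepoint mean profiles of the modulated lncRNAs
   are z-scored and K-means clustered; each cluster centroid is labelled
   *early*, *early-transient* or *late* by a rule on its changes from
   baseline.
3. **IFN/antiviral context.** Up-regulated, expressed protein-coding
   genes (mean FPKM > 2 in at least one condition) are tested for
   gene-set over-representation (one-sided hypergeometric, BH FDR <=
   0.05); terms whose names match IFN/antiviral keywords define the
   relevant protein-coding gene set.
4. **Association plus proximity.** A lncRNA becomes a candidate when at
   least one of those protein-coding genes is both significantly
   Spearman-correlated with it (p <= 0.05) and located in cis, i.e.
   within 150 kb of gene-body gap on the same chromosome.
5. **Cohort replication.** In an independent case/control cohort, a
   candidate replicates when it is up-regulated (log2FC >= 0.58,
   p <= 0.05, Wald test) in at least two case groups, and its expression
   is correlated with a six-gene IFN signature score (IFI27, IFI44L,
   IFIT1, IFIT2, IFIT3, SERPING1).
6. **Target nomination.** Signed weighted co-expression networks are
   built on the time course (power 18) and the cohort (power 13); the
   candidate's module is extracted from each, the two modules are
   intersected, and the common protein-coding genes are the putative
   targets.

Every stage is exposed as a documented function; `runDiscovery()`,
`runCohort()` and `runTargets()` orchestrate them and write tables plus
a JSON run manifest.

# Statistical models

## Negative-binomial testing

Counts are modelled as NB with mean `mu` and variance `mu + alpha*mu^2`.
Normalization uses median-of-ratios size factors; the fallback for
matrices without an all-nonzero gene is total-count ratios (with a
warning). Dispersion is a per-gene method of moments on normalized
counts, `alpha = max(0, (pooled within-group variance - mean)/mean^2)`,
floored at 1e-8.

The raw moment estimator is noisy at typical replicate numbers (three
or four per condition): for many genuinely overdispersed genes it
collapses to the floor, and tests that trust it reject far too often.
The test functions therefore floor each gene's dispersion at the
experiment-wide median (over genes with mean normalized count above 1)
by default. This is not per-gene shrinkage — it is a single shared
safeguard — and with it the null rejection rate of both tests sits near
the nominal 5% (the test suite asserts <= 10%, and <= 15% empirical FDR
at BH-adjusted p < 0.05 on planted-effect simulations).

The Wald test fits the two group means on normalized counts, forms
`log2FC = log2((muB + 0.5)/(muA + 0.5))` (the 0.5 pseudocount keeps
all-zero groups finite) and divides by a delta-method standard error
under the NB variance function. The LRT maximizes the fixed-dispersion
NB likelihood under the full factor (one mean per level, size factors
as offsets) and the nested reduced factor via `stats::glm` with the
`MASS::negative.binomial` family; `2*deltalogL` is referred to a
chi-square with the difference in level counts as degrees of freedom.
No outlier filtering or dispersion shrinkage beyond the median floor is
performed; calibration is enforced by tests rather than model
refinements.

The `vstCounts()` transform is `log2(normalized count + 1)`: a monotone
variance-flattening stand-in sufficient for the rank-based and
correlation-based stages downstream, not a parametric variance
stabilization.

## Kinetic classes

With centroid changes `d1 = c(1.5h) - c(0)` and `d2 = c(4h) - c(0)` in
z-units, the rule is: *early* if `|d1| >= delta` and the change persists
(`|d2| >= 0.75*|d1|`, same sign); *early-transient* if `|d1| >= delta`
but `|d2| < 0.5*|d1|`; *late* if `|d1| < delta <= |d2|`; otherwise
unclassified. `delta` defaults to 0.5 z-units; the 0.75/0.5 persistence
ratios make the three verbal definitions mutually exclusive, leaving a
deliberate "unclassified" band between decay and persistence. The class
is a property of the centroid, not of the cluster identity, so the
number of clusters K only refines the partition. K defaults to 3 in
`kmeansProfiles()` (three kinetic groups), but the discovery pipeline
uses K = 6: up- and down-regulated genes of the same class have opposite
z-profiles, so six archetypes exist and K = 6 lets each get its own
centroid. K-means is Lloyd's algorithm, best of 10 seeded restarts by
within-cluster sum of squares; empty-cluster initializations are
redrawn, and everything is deterministic given the seed.

## Correlation and the cis window

Spearman's rho uses average ranks for ties; p-values come from the
t-approximation with n-2 degrees of freedom (two-sided; p = 0 at
|rho| = 1). The cis relation is measured between gene bodies:
`gap = max(0, max(start_a, start_b) - min(end_a, end_b) - 1)`, zero for
overlapping bodies, strand ignored, inclusive at the 150,000 bp
boundary. Gene-body gap (rather than TSS distance) is the conservative,
exactly testable reading of "within +/-150 kb". Both correlation signs
are kept at selection; the replication filter is up-only.

## IFN signature score

Per sample, each signature gene's expression (on the `vstCounts()`
scale) is standardized against the healthy-control samples
(`(x - HC mean)/HC sd`) and the score is the mean over signature genes.
Healthy controls therefore average to score 0 by construction. Genes
missing from the matrix or with zero HC standard deviation are dropped
with a warning. The formula is a reconstruction of the standard
HC-referenced z-score composite used for ISG panels.

## Co-expression networks

Signed adjacency is `((1 + cor)/2)^beta` with Pearson correlation
(anticorrelation maps to ~0, so modules are sign-coherent), diagonal set
to 0. The topological overlap is
`TOM_ij = (l_ij + a_ij)/(min(k_i, k_j) + 1 - a_ij)` with
`l_ij = sum_u a_iu a_uj`. Modules come from average-linkage hierarchical
clustering of `1 - TOM` with a **static** cut at height 0.995 and a
minimum module size (20 for the time course, 10 for the cohort);
clusters below the minimum get label 0 (unassigned), playing the role
of the conventional grey module. The static cut replaces the dynamic
tree-cut algorithm: at the powers used (18 and 13), between-module TOM
is essentially zero, so unrelated genes join only above dissimilarity
0.995 and a single height separates modules reliably; the acceptance
surface is module *recovery* (adjusted Rand index >= 0.8 on planted
blocks), not label identity. Module counts of a given dataset are
therefore not comparable to tools with different cut rules.

# The synthetic-data generator

The generator is first-class, tested code: it emulates the two study
designs the pipeline targets and emits a ground-truth record
(`GroundTruth`) so every stage's recovery can be measured.

**Genome and annotation.** Genes are placed without overlap on a small
genome (default 4 chromosomes of 30 Mb; 300 protein-coding and 150
noncoding genes). Noncoding biotypes are lincRNA / antisense /
processed_transcript, with 10% pseudogene and 5% sub-200 bp decoys that
the lncRNA filter must reject. Coordinates are 1-based inclusive.

**Planted effects.** 30% of eligible lncRNAs and 25% of protein-coding
genes are modulated with |log2FC| = 2, 70% of them upward, with kinetic
classes drawn at probabilities (0.5, 0.25, 0.25) for early /
early-transient / late. Counts are NB with dispersion 0.1 and
log-uniform library sizes (0.5-1.5 M); the time course has t0 / 1.5 h /
4 h with 4 replicates each. Effect size 2.0, dispersion 0.1 and 4
replicates per condition are the reference recovery conditions the test
suite asserts against (sensitivity >= 0.8, FDR <= 0.15, kinetic class
recovery >= 70%).

**Co-regulation structure.** Half of the modulated lncRNAs are placed
in cis (gene-body gap 5-100 kb) of a dedicated up-modulated
protein-coding partner sharing their kinetic class. One cis-paired
lncRNA is designated NRIR-like: a slowly induced ("late"),
IFN-dependent transcript. Because ISGs cluster genomically (the
NRIR-like locus emulates an ISG-dense neighbourhood), it receives a
second flanking module gene in cis. A 30-gene protein-coding module —
the six signature genes, the NRIR-like gene's two cis partners, plus
random genes — shares the NRIR-like gene's kinetics in the time course.

Planted effects are additionally scaled per sample by a shared
stimulation strength `eta_s ~ Normal(1, 0.25^2)`. This is the
pool-to-pool response variability of real stimulation experiments, and
it is what makes "co-regulated" genes co-fluctuate *across samples*
rather than merely share a mean pattern — the structure the Spearman
stage of the analysis assumes. Without it, correlation between truly
co-regulated genes would rest entirely on the deterministic timepoint
pattern. The value 0.25 (a 25% standard deviation on response strength)
was chosen as realistic for pools of donors and is not a tuning knob.

**Cohort.** Each sample carries a latent IFN activity
`a ~ Normal(shift, 1)` — shift 0 for healthy controls, 2 for case
groups (20 samples per group, the condition at which the replication
filter's Monte-Carlo power is ~95%). Signature genes, module genes and
the NRIR-like lncRNA have their mean multiplied by `2^a` (unit
loading), which builds in both the lncRNA-score correlation and the
co-expression module the network stage must find. All other genes are
unaffected by group, so cohort specificity is honest.

**What the generator does not emulate:** batch effects, donor pairing,
GC/length biases, isoform structure, partially overlapping or
bidirectional transcription, graded per-gene effect sizes, and any
dependence structure among non-planted genes. Passing recovery tests
therefore demonstrates internal consistency of the pipeline under its
own assumptions, not performance on real data, where effect sizes are
heterogeneous and co-expression is confounded.

# Numerical and degenerate-input conventions

* All thresholds are inclusive at the boundary (log2FC >= 0.58,
  p <= 0.05, gap <= 150,000), matching the printed conventions they
  implement; the time-course significance filter is strict
  (padj < 0.05), again as printed.
* All-zero genes: Wald/LRT report log2FC 0, p 1. Constant genes:
  z-profiles become zero rows (flagged), correlations are dropped with
  a warning, network correlations are treated as 0.
* BH adjustment delegates to `stats::p.adjust` with NaN propagation.
* Every stochastic step (generator, K-means restarts) flows from an
  explicit integer seed; two runs with equal config and seed are
  bit-identical, which the test suite asserts end to end.

# Problem sizes used by the test suite

The suite and the acceptance script run the full pipeline on the
default generator (450 genes, 12 time-course samples, 80 cohort
samples), 20 seeds for end-to-end recovery, 3 seeds for calibration and
network-intersection metrics, and networks of 200-400 genes
(significant genes for the time course, top-variance genes plus the
query for the cohort). These sizes give stable rates while keeping a
full run around a minute; they are stated here so results are
reproducible, and they scale linearly (quadratically for networks) if
increased.

# Known limitations

* The NB machinery is deliberately minimal: no per-gene dispersion
  shrinkage, no outlier handling, no covariates or paired designs. For
  real datasets a dedicated DE framework is preferable; the pipeline's
  contribution is the integration logic around the tests.
* Keyword matching is a proxy for a curated IFN/antiviral term list;
  the exact GO vocabulary selected will differ between annotation
  releases.
* The static network cut trades the adaptivity of dynamic tree cutting
  for transparency; very unequal module densities may require adjusting
  `cutHeight`.
* The IFN score formula is a reconstruction (HC-referenced z average),
  not a byte-exact reimplementation of any published score.
* Whether a correlation-magnitude cutoff should supplement the p-value
  at the selection stage is left open; only the p threshold is applied,
  with both signs retained.
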
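---
title: "Methods: miRNA-mRNA co-expression network inference with sproutnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: miRNA-mRNA co-expression network inference with sproutnet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sproutnet)
```

## The model

miRNAs repress their target mRNAs post-transcriptionally, so when a miRNA is
up-regulated between two cellular conditions its functional targets tend to be
down-regulated, and vice versa. Across a two-condition design with replicates,
this repression leaves a footprint in the *correlator*: the Pearson
correlation between a miRNA's and a gene's expression profiles across samples.
`sproutnet` turns that footprint into a signed bipartite regulatory network.
An edge (miRNA, gene) requires four independent pieces of evidence:

1. a **predicted direct interaction** (a TargetScan-style record whose
   weighted context++ score percentile strictly exceeds a class-specific
   cutoff: > 50 for evolutionarily conserved sites, > 90 for non-conserved
   ones — conservation being the field's proxy for functional repression);
2. a **negative correlation** (`r < 0`);
3. **pair significance** (two-sided p below 0.05, analytic by default);
4. **opposite differential expression** of the two endpoints (both features
   modulated, in opposite directions).

Requirement 4 is applied by default but can be relaxed
(`build_network(require_de = FALSE)`), which leaves edges defined by
prediction plus significant negative correlation only. With planted
regulation that is purely up-miRNA → down-gene and down-miRNA → up-gene, the
resulting graph decomposes into sign-homogeneous connected components: one
assembled from up-regulated miRNAs and their down-regulated targets and one
with the opposite polarity. This two-module dichotomy is a structural
invariant that the test suite checks on every synthetic run.

## Stage by stage

### Filtering, normalization, differential expression

Features are kept when their mean raw count across all samples strictly
exceeds 5 (`filter_expressed`; the mean-over-all-samples reading of the
cutoff is a package decision — minimum-over-samples and per-condition-mean
variants are a one-line change via `min_raw`). Normalization is
median-of-ratios: each sample is divided by the median, over features with a
nonzero geometric mean, of count / geometric mean — the standard size-factor
estimator for RNA-seq.

The internal differential-expression stage is deliberately simple: Welch's t
on `log2(x + 1)` of normalized counts, Benjamini–Hochberg FDR across
features, and `log2FC = log2((mean_treated + 1) / (mean_control + 1))`. It is
**not** a count-model DE method — no dispersion shrinkage, no Wald or LRT
tests. Its role is to reproduce the thresholding semantics (modulated iff
`|log2FC| > 0.5` and `FDR < 0.05`, both strict) with a self-contained stage;
`ingest_de_table()` accepts externally computed DE tables (e.g. from a
count-model tool run on real accessions) and recomputes directions from the
same thresholds, so the internal stage can be swapped out without touching
anything downstream. At 3 + 3 replicates the Welch test is the pipeline's
power bottleneck; this is visible in the recovery figures below.

### Correlation and its permutation null

All miRNA × gene Pearson correlations are computed on `log2(normalized + 1)`
values (the scale is configurable; the log scale tames count
heteroscedasticity). The analytic p uses the t transform with n − 2 degrees
of freedom. The null distribution of the correlator is obtained by sample
randomization: per permutation, the sample labels of the miRNA matrix are
shuffled once (preserving the joint null across all pairs) and all pair
correlations are recomputed; 1000 permutations by default. With 6 samples
only 720 distinct orderings exist, so shuffles are drawn with replacement.
Empirical pair p-values use the pooled null with the add-one rule,
`p = (1 + #{null |r| ≥ |r_obs|}) / (1 + N_null)`; pools larger than 2 × 10⁷
are subsampled and flagged.

The repression footprint is quantified by comparing the correlator
distribution of the predicted-conserved stratum against all pairs: a
two-sample Kolmogorov–Smirnov D plus a one-sided p-value for stochastic
ordering toward negative r. The stratum is a subset of the reference
distribution; the comparison is descriptive of the enrichment, which is how
the assay is used here (the planted-data tests calibrate its error rates
directly). The non-conserved stratum, which carries only decoy predictions
in the synthetic design, doubles as a negative control.

### The GSEA engine

Rankings: for a continuous phenotype (e.g. a miRNA profile or a cohort
score), the metric is the Pearson correlation of each gene with the
phenotype; for two classes, the signal-to-noise ratio
`(μ₁ − μ₂)/(σ₁ + σ₂)` with each σ floored at `max(0.2·|μ|, 0.2)` (the floor
keeps near-constant genes from dominating). Ties break lexicographically so
rankings are reproducible.

The enrichment score walks the ranked list: hits add
`|metric|^w / Σ_set |metric|^w` (weight `w = 1` by default), misses subtract
`1/(N − N_hits)`; ES is the signed maximum deviation, and the leading edge
("core enrichment") is the set members at or before the extremum (at or
after, for negative ES). Significance uses geneset permutation by default —
random member sets of equal size — because with 6 samples phenotype
permutation is degenerate; phenotype permutation is implemented for larger
designs. NES divides ES by the mean of the sign-matched null; p-values are
one-sided with the add-one rule (an exact enumeration mode replaces sampling
when the universe is small, dropping add-one since the observed set is one of
the enumerated subsets); FDR q follows the sign-stratified NES-ratio
procedure. The miRNA × gene-set association matrix runs one
continuous-phenotype GSEA per miRNA, masks NES at FDR < 0.05, clusters the
significant rows and columns (Euclidean distance, complete linkage — the
clustering settings are conventional defaults and configurable), and reports
per-row-cluster leading-edge unions. All miRNA columns share one null seed,
so duplicate profiles give identical columns.

### Network topology and the power-law fit

Degree sequences (miRNA out-degree, gene in-degree) are tested against the
scale-free hypothesis with a discrete power-law fit: for each candidate
`xmin`, the exponent maximizes the discrete log-likelihood with Hurwitz-zeta
normalization (a 0.005-step profile grid plus a continuous refinement;
agreement with an independent 0.01-step grid oracle is a tested invariant);
`xmin` minimizes the KS distance between the tail ECDF and the fitted CDF;
and the goodness-of-fit p-value comes from a semi-parametric bootstrap
(synthetic sets drawn from the fitted tail and resampled body, refitted in
full; 1000 replicates by default). Fits are deemed plausible when
`p_gof > 0.1`.

One numerical safeguard deviates from the plain recipe: candidate `xmin`
values must retain at least `max(10, 5% of n)` tail points. Without the
fraction floor, the KS-minimizing scan can land in a narrow far-tail window
(a few dozen points spanning less than a doubling) where *any* smooth
decreasing distribution looks locally power-law-like; the bootstrap then
reproduces the same escape and the test loses essentially all power against
curved alternatives such as geometric tails. With the floor, exponent
recovery on true power-law data is unchanged (and matches igraph's `plfit`
to three decimals on shared draws) while misspecified data is reliably
rejected. The floor is configurable (`tail_fraction`); fits whose chosen
tail falls below `min_tail` carry a `flagged` field.

### Downstream statistics

* `hypergeometric_test(k, K, n, N)` — upper-tail over-representation by
  log-space summation of the exact terms; the universe N is always an
  explicit argument, never inferred.
* `endothelial_score` — per-sample mean of per-gene z-scored expression over
  a signature (the mean-of-z-scores form is a package decision; the
  definition is delegated to a user-supplied signature list, 35 genes in the
  motivating use). Zero-variance genes are excluded with a warning.
* `module_score_correlation` — Pearson correlation between the per-sample
  mean of z-scored module expression and the scores (genes are z-scored
  before averaging so high-variance genes do not dominate).
* `ddct_analysis` — comparative-Ct: per sample, Ct values are normalized by
  the mean Ct of reference assays (global mean when no references are
  given, the default for array cards); ΔCt is replicate-averaged on the Ct
  scale, ΔΔCt = ΔCt_treated − ΔCt_control, Rq = 2^(−ΔΔCt); assays pass only
  when `|ΔΔCt| > 2` strictly; survivors are ordered by hierarchical
  clustering of −ΔΔCt.

## The synthetic-data generator

`generate_experiment()` emulates the statistical structure the analysis
assumes, with a ground-truth key for every recovery test:

* **Counts** are negative binomial with mean μ and variance μ + d·μ²
  (`nb_dispersion = d`, default 0.05; d = 0 gives Poisson), 3 + 3 replicates,
  per-sample library-size factors uniform in ±20%. Baseline log2 means are
  N(9, 1): high enough that biological dispersion, not shot noise, dominates
  — representative of features that survive the count filter.
* **Planted regulation**: 10 up- and 10 down-regulated regulator miRNAs out
  of 40 (the regulator fraction mirrors observed miRNA networks, where
  roughly a quarter of expressed miRNAs join the network); each regulator
  receives an out-degree from a discrete power law (exponent 2.5, lower
  bound 8, truncated at the target-pool size) and draws its targets from a
  direction-specific module pool of 60 genes out of 400, so target sharing
  concentrates regulation the way real miRNA networks do. Regulators shift
  by ±`effect_lfc` (default 2) in the treated condition; their targets shift
  oppositely. Anti-correlation is induced solely through condition means —
  no per-sample coupling — which with 3 + 3 samples already yields the
  strong negative correlations the pipeline must detect.
* **Predictions**: every planted edge appears as a conserved record with
  percentile uniform in (50, 100]. Decoys — uniformly sampled non-planted
  pairs — are added at `decoy_prediction_ratio` × planted count (default 3),
  split evenly between the conserved class (percentile (50, 100]) and the
  non-conserved class (percentile (90, 100]), so the non-conserved stratum
  is a pure negative control. `n_decoy_predictions` overrides the ratio,
  letting a null experiment (no regulators) still carry a conserved stratum.
* **Gene sets**: one set per planted module plus random decoy sets.
* **Streams**: every artifact draws from its own RNG stream split from the
  master seed, so adding one output never perturbs another; identical
  (config, seed) reproduces every output bit for bit.

`generate_cohort()` emulates a tumor cohort with a latent per-sample
endothelial score z ~ N(0, 1): signature genes load on z with coefficient 1,
module genes with coefficient β, responders additionally shift module genes
by `responder_effect`. `generate_ct_card()` emulates a qPCR miRNA card with
planted ΔΔCt offsets; under global-mean normalization a shift s on m of n
assays realizes as s·(1 − m/n) on shifted assays and −s·m/n elsewhere, which
the exactness tests account for.

What the generator does **not** emulate: read-level noise, GC or batch
effects, isomiR complexity, correlated biological replicates, or indirect
(miRNA–miRNA) regulation. Passing tests therefore demonstrate that the
pipeline recovers the structure it models, under its own noise assumptions —
not that those assumptions exhaust real data.

## Problem sizes and measured behavior

The default study conditions are 40 miRNAs × 400 genes, ~300 planted edges,
|log2FC| = 2, NB dispersion 0.05, 3 + 3 replicates, decoy ratio 3. Under
these conditions the bundled checks measure (means over 10 generator seeds):
edge precision ≈ 0.92 and recall ≈ 0.73 against the planted truth. Recovery
is evaluated as a Monte-Carlo mean because single-seed recall is noisy — with
a Welch t at n = 3 per group, one hub regulator missing the FDR cut removes
many edges at once. The per-feature DE call rate at these settings is ~0.9
for regulators and ~0.77 for targets; near-complete (≥ 90%) recovery of
planted features requires a dense-signal design (most genes carrying planted
effects, so the BH threshold adapts upward), which the unit tests exercise
separately. Null calibration (no planted regulation) holds the empirical
false-positive rate of the correlator at 5% ± 2% and the permutation-null
mean within ±0.01 of zero at ≥ 10⁵ pooled draws.

Simulation sizes in the test suite (50 seeds for error-rate calibration,
5000 draws and 1000 bootstrap replicates for the power-law checks, 1000
permutations for GSEA and the correlation null) are chosen to give the
stated tolerances comfortable Monte-Carlo margins.

## Numerical choices and degenerate inputs

* Strict inequalities throughout where a threshold is quoted with ">" or
  "<": percentile cutoffs, |log2FC| > 0.5, FDR < 0.05, mean count > 5,
  |ΔΔCt| > 2.
* Pseudocount 1 in all log transforms and fold changes (boundedness at
  zero counts).
* Zero-variance features: flagged and excluded from correlation; metric 0
  and flagged in rankings; excluded with a warning from signature scores.
  A constant feature across all samples gets log2FC 0, p 1, direction `ns`.
* Identifier comparison is case-sensitive after whitespace stripping; no
  alias resolution.
* Ties: rankings break by feature id; hub lists break lexicographically.
* The hypergeometric summation is done in log space with a max-shift, so
  deep tails (p ~ 10⁻³⁰⁰) remain finite.
* Seeds: every stochastic operation takes an explicit seed, runs in a local
  RNG scope, and splits per-artifact streams deterministically; R's 32-bit
  integer range is respected.

## Known limitations

* The DE stage's Welch t at n = 3 is honest but underpowered; with real
  data, ingest a count-model DE table instead.
* The stratified KS comparison treats the stratum as independent of the
  reference; with overlapping samples the p-value is approximate (the
  calibration tests bound its realized error rates on the null generator).
* Geneset permutation tests the enrichment of a set against random sets of
  genes, not against phenotype exchangeability; with enough samples,
  phenotype permutation is the stricter null and is available.
* The power-law GOF test inherits the usual caveat that failure to reject
  is not proof of a power law, particularly for short degree sequences
  (fits with thin tails are flagged).
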